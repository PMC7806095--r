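#' Derive reproducible child seeds from one master seed
#'
#' One top-level seed expands into independent per-replicate seeds by a fixed
#' derivation (the master seed initializes a temporary RNG stream from which
#' the children are sampled without replacement); the caller's RNG state is
#' left untouched.
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of n distinct seeds in [1, 2^31 - 2].
#' @export
childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Sweep the behavioral parameter space
#'
#' Runs \code{replicates} independent simulations for every combination of
#' the supplied \code{Pu}, \code{knl}, \code{c} and \code{N} values and
#' summarizes the largest tower's final properties per cell (mean, min and
#' max over replicates).  Defaults follow the reference protocol: 10
#' replicates of 500000 steps at L = 100.
#'
#' @param Pu,knl,c,N vectors of parameter values; the grid is their full
#'   cross product.
#' @param L arena side length.
#' @param replicates simulations per cell.
#' @param steps time steps per simulation.
#' @param Psl spontaneous locking probability.
#' @param seed master seed; per-run seeds come from [childSeeds()].
#' @param sampleInterval recording stride.
#' @param verbose print one line per completed cell.
#' @return data.frame with one row per cell: the cell parameters, \code{rho},
#'   and \code{n_agents}/\code{height}/\code{aspect_ratio} each as
#'   \code{*_mean}, \code{*_min}, \code{*_max}.  The per-replicate final
#'   values are attached as \code{attr(, "runs")}.
#' @export
runSweep <- function(Pu = 0.2, knl = 1/26, c = 0, N = 1000, L = 100,
                     replicates = 10, steps = 500000, Psl = 1/20000,
                     seed = 1L, sampleInterval = 250, verbose = FALSE) {
  cells <- expand.grid(Pu = Pu, knl = knl, c = c, N = N,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(childSeeds(seed, nrow(cells) * replicates),
                  nrow = nrow(cells))
  runs <- vector("list", nrow(cells) * replicates)
  for (i in seq_len(nrow(cells))) {
    for (r in seq_len(replicates)) {
      p <- simParams(L = L, N = cells$N[i], Pu = cells$Pu[i],
                     knl = cells$knl[i], Psl = Psl, c = cells$c[i],
                     steps = steps, seed = seeds[i, r],
                     sampleInterval = sampleInterval)
      run <- runSimulation(p)
      fin <- simSeries(run)[nrow(simSeries(run)), ]
      runs[[(i - 1) * replicates + r]] <-
        data.frame(cells[i, , drop = FALSE], replicate = r,
                   seed = seeds[i, r], n_agents = fin$n_agents,
                   height = fin$height, aspect_ratio = fin$aspect_ratio,
                   steady = steadyState(simSeries(run), cells$N[i]),
                   row.names = NULL)
    }
    if (verbose)
      message(sprintf("cell %d/%d done (Pu=%g knl=%g c=%g N=%d)", i,
                      nrow(cells), cells$Pu[i], cells$knl[i], cells$c[i],
                      cells$N[i]))
  }
  runs <- do.call(rbind, runs)
  # rows of `runs` are grouped by cell (cells form the outer loop)
  idx <- rep(seq_len(nrow(cells)), each = replicates)
  stat <- function(v, f) as.numeric(tapply(v, idx, f))
  out <- data.frame(cells,
                    rho = cells$N / L^2,
                    n_agents_mean = stat(runs$n_agents, mean),
                    n_agents_min = stat(runs$n_agents, min),
                    n_agents_max = stat(runs$n_agents, max),
                    height_mean = stat(runs$height, mean),
                    height_min = stat(runs$height, min),
                    height_max = stat(runs$height, max),
                    aspect_mean = stat(runs$aspect_ratio, mean),
                    aspect_min = stat(runs$aspect_ratio, min),
                    aspect_max = stat(runs$aspect_ratio, max),
                    row.names = NULL)
  attr(out, "runs") <- runs
  out
}

#' Critical attraction ratio of a sweep
#'
#' The onset of the aggregation phase transition: the smallest value of the
#' attraction ratio c on the sweep grid for which the mean largest-tower
#' size reaches at least \code{threshold} agents (100 by default).
#'
#' @param sweep data.frame with columns \code{c} and \code{n_agents_mean}
#'   (one density/locking cell of a [runSweep()] result), with \code{c}
#'   sorted increasing.
#' @param threshold onset size in agents.
#' @return the critical c, or NA when no grid value crosses the threshold.
#' @export
criticalAttraction <- function(sweep, threshold = 100) {
  if (is.unsorted(sweep$c, strictly = TRUE))
    stop("sweep must be sorted on a strictly increasing c grid")
  hit <- which(sweep$n_agents_mean >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  sweep$c[hit[1L]]
}

# periodic centroid + footprint of every label in one frame
.frameTowers <- function(labels, L) {
  nlab <- max(labels)
  lapply(seq_len(nlab), function(l) {
    foot <- which(labels == l)
    list(label = l, foot = foot, area = length(foot),
         cx = .periodicMean((foot - 1L) %% L, L),
         cy = .periodicMean((foot - 1L) %/% L, L))
  })
}

#' Track towers through a sequence of height-map frames
#'
#' Towers are labeled per frame and matched frame-to-frame by footprint
#' overlap (fraction of the smaller footprint, > \code{overlapMin}); a tower
#' without an overlap match falls back to the nearest unmatched center
#' within \code{centerMaxDist} pixels (minimal-image distance).  A current
#' tower claimed by two or more previous towers is a merge: the parents'
#' tracks close and a fresh track opens, so no track ever mixes pre- and
#' post-merge motion.  Unmatched new labels open tracks; vanished labels
#' close them.  Centers are unwrapped across the periodic boundary by
#' accumulating minimal-image displacements.
#'
#' @param maps list of height-map matrices (e.g. [heightMaps()] of a run
#'   with \code{recordMaps = TRUE}).
#' @param times sample times of the frames (defaults to 250-step spacing).
#' @return data.frame of trajectories: \code{track}, \code{t}, \code{x},
#'   \code{y} (unwrapped center of area, pixels).
#' @export
trackTowers <- function(maps, times = NULL) {
  if (length(maps) == 0L) return(data.frame(track = integer(), t = numeric(),
                                            x = numeric(), y = numeric()))
  L <- nrow(maps[[1L]])
  if (is.null(times)) times <- 250 * (seq_along(maps) - 1)
  stopifnot(length(times) == length(maps), !is.unsorted(times, strictly = TRUE))
  rows <- list()
  nextId <- 1L
  active <- list()   # per track: id, foot, area, cx, cy (raw), ux, uy
  openTrack <- function(tw, tm) {
    tr <- list(id = nextId, foot = tw$foot, area = tw$area,
               cx = tw$cx, cy = tw$cy, ux = tw$cx, uy = tw$cy)
    nextId <<- nextId + 1L
    rows[[length(rows) + 1L]] <<- data.frame(track = tr$id, t = tm,
                                             x = tr$ux, y = tr$uy)
    tr
  }
  labs <- labelTowers(maps[[1L]])
  for (tw in .frameTowers(labs, L))
    active[[length(active) + 1L]] <- openTrack(tw, times[1L])
  for (f in seq_along(maps)[-1L]) {
    labs <- labelTowers(maps[[f]])
    cur <- .frameTowers(labs, L)
    claim <- rep(NA_integer_, length(active))       # current index per track
    for (a in seq_along(active)) {
      hit <- labs[active[[a]]$foot]
      hit <- hit[hit > 0L]
      if (length(hit) == 0L) next
      ov <- tabulate(hit, nbins = length(cur))
      best <- which.max(ov)
      if (ov[best] / min(active[[a]]$area, cur[[best]]$area) > 0.3)
        claim[a] <- best
    }
    # center fallback for overlap-less tracks, against unclaimed currents
    freeCur <- setdiff(seq_along(cur), claim[!is.na(claim)])
    for (a in which(is.na(claim))) {
      if (length(freeCur) == 0L) break
      d <- vapply(freeCur, function(b) {
        off <- toroidalOffset(c(active[[a]]$cx, active[[a]]$cy),
                              c(cur[[b]]$cx, cur[[b]]$cy), L)
        sqrt(sum(off^2))
      }, numeric(1))
      if (min(d) <= 5) {
        claim[a] <- freeCur[which.min(d)]
        freeCur <- setdiff(freeCur, claim[a])
      }
    }
    merged <- as.integer(names(which(table(claim) >= 2)))
    nxt <- list()
    for (a in seq_along(active)) {
      b <- claim[a]
      if (is.na(b) || b %in% merged) next   # track closes
      tr <- active[[a]]
      off <- toroidalOffset(c(tr$cx, tr$cy), c(cur[[b]]$cx, cur[[b]]$cy), L)
      tr$ux <- tr$ux + off[1]; tr$uy <- tr$uy + off[2]
      tr$cx <- cur[[b]]$cx; tr$cy <- cur[[b]]$cy
      tr$foot <- cur[[b]]$foot; tr$area <- cur[[b]]$area
      rows[[length(rows) + 1L]] <- data.frame(track = tr$id, t = times[f],
                                              x = tr$ux, y = tr$uy)
      nxt[[length(nxt) + 1L]] <- tr
    }
    taken <- claim[!is.na(claim) & !(claim %in% merged)]
    for (b in setdiff(seq_along(cur), taken))      # new + merge children
      nxt[[length(nxt) + 1L]] <- openTrack(cur[[b]], times[f])
    active <- nxt
  }
  out <- do.call(rbind, rows)
  out[order(out$track, out$t), , drop = FALSE]
}

#' Mean squared displacement of a trajectory at one lag
#'
#' Sliding-window average of squared displacements over every valid start
#' time: MSD(lag) = mean over t0 of |x(t0 + lag) - x(t0)|^2, computed on the
#' unwrapped coordinates.  MSD(0) is exactly 0.
#'
#' @param track data.frame with columns \code{t}, \code{x}, \code{y} for one
#'   tower, sampled at a uniform stride.
#' @param lag time lag (a multiple of the sampling stride, smaller than the
#'   trajectory span).
#' @return numeric MSD in pixels^2; vectorized over \code{lag}.
#' @export
towerMSD <- function(track, lag) {
  n <- nrow(track)
  if (n < 2L) stop("trajectory must have at least two samples")
  dt <- diff(track$t)
  stride <- dt[1L]
  if (any(abs(dt - stride) > 1e-9)) stop("trajectory must be uniformly sampled")
  span <- track$t[n] - track$t[1L]
  vapply(lag, function(l) {
    if (l < 0 || l >= span) stop("lag must lie in [0, span)")
    k <- l / stride
    if (abs(k - round(k)) > 1e-9) stop("lag must be a multiple of the stride")
    k <- as.integer(round(k))
    if (k == 0L) return(0)
    i <- seq_len(n - k)
    mean((track$x[i + k] - track$x[i])^2 + (track$y[i + k] - track$y[i])^2)
  }, numeric(1))
}

#' Diffusion coefficient of tower motion
#'
#' Treats each tower's center-of-area motion as a Brownian walk obeying
#' MSD = 2 D t: for every track (truncated to its first \code{truncate}
#' steps) the MSD is evaluated at lags 0, 250, ..., 12500 and fit by
#' unweighted ordinary least squares through all available lag points
#' (including (0, 0)); D is half the slope.  The pooled estimate is the
#' unweighted mean of the per-track D.  Tracks spanning fewer than two lags
#' are excluded and reported.
#'
#' @param tracks data.frame from [trackTowers()] (columns \code{track},
#'   \code{t}, \code{x}, \code{y}).
#' @param lags lag grid in time steps.
#' @param truncate use only each trajectory's first \code{truncate} steps.
#' @return list with \code{D} (mean over tracks), \code{fits} (per-track
#'   data.frame: \code{track}, \code{slope}, \code{intercept}, \code{D},
#'   \code{n_lags}) and \code{excluded} (track ids too short to fit).
#' @export
diffusionCoefficient <- function(tracks, lags = seq(0, 12500, by = 250),
                                 truncate = 37500) {
  ids <- unique(tracks$track)
  fits <- list(); excluded <- integer()
  for (id in ids) {
    tr <- tracks[tracks$track == id, , drop = FALSE]
    tr <- tr[tr$t - tr$t[1L] <= truncate, , drop = FALSE]
    span <- if (nrow(tr) > 1L) tr$t[nrow(tr)] - tr$t[1L] else 0
    use <- lags[lags < span]
    if (nrow(tr) < 2L || length(use) < 2L) {
      excluded <- c(excluded, id)
      next
    }
    m <- towerMSD(tr, use)
    fit <- lm(m ~ use)
    fits[[length(fits) + 1L]] <-
      data.frame(track = id, slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 D = unname(coef(fit)[2L]) / 2, n_lags = length(use))
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(track = integer(), slope = numeric(), intercept = numeric(),
               D = numeric(), n_lags = integer())
  list(D = if (nrow(fits)) mean(fits$D) else NA_real_, fits = fits,
       excluded = excluded)
}
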