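#' Label towers in a height map
#'
#' A tower is an 8-connected component of the nonzero pixels of the height
#' map: any two nonzero pixels sharing a corner or edge carry the same
#' label.  With \code{wrap = TRUE} (the default, consistent with periodic
#' distances) components also merge across the periodic boundary.  Zero
#' pixels are labeled 0; labels are dense from 1 in scan order.
#'
#' @param hm integer L x L height-map matrix (non-negative).
#' @param wrap merge components across the periodic seam?
#' @return integer label matrix of the same shape.
#' @examples
#' hm <- matrix(0L, 5, 5); hm[1, 2] <- 1L; hm[2, 3] <- 2L; hm[5, 5] <- 1L
#' labelTowers(hm)   # diagonal contact joins the first two pixels
#' @export
labelTowers <- function(hm, wrap = TRUE) {
  storage.mode(hm) <- "integer"
  .cpp_label(hm, wrap)
}

# periodic centroid of 0-based coordinates along one axis of length L,
# via the circular mean: robust for footprints straddling the seam
.periodicMean <- function(v, L) {
  th <- 2 * pi * v / L
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m / (2 * pi) * L) %% L
}

#' Per-tower geometric summaries
#'
#' Every agent (any state) is assigned the label of its pixel; free agents
#' standing on unlabeled ground belong to no tower.  For each label the
#' summary reports the agent count, maximum stack height over the footprint,
#' base area (pixels), equivalent diameter 2*sqrt(area/pi) — the diameter of
#' the circle with the same base area —, the aspect ratio height/diameter,
#' and the periodic centroid of the footprint.
#'
#' @param world a [WorldState-class].
#' @param labels optional label matrix (computed from the world's height map
#'   when NULL).
#' @return data.frame with one row per tower: \code{label}, \code{n_agents},
#'   \code{height}, \code{base_area}, \code{eq_diameter},
#'   \code{aspect_ratio}, \code{cx}, \code{cy}.
#' @export
towerSummaries <- function(world, labels = NULL) {
  stopifnot(is(world, "WorldState"))
  hm <- heightMap(world)
  if (is.null(labels)) labels <- labelTowers(hm)
  nlab <- max(labels)
  if (nlab == 0L)
    return(data.frame(label = integer(), n_agents = integer(),
                      height = integer(), base_area = integer(),
                      eq_diameter = numeric(), aspect_ratio = numeric(),
                      cx = numeric(), cy = numeric()))
  L <- nrow(hm)
  ag <- agents(world)
  agLab <- labels[cbind(ag$x + 1L, ag$y + 1L)]
  out <- lapply(seq_len(nlab), function(l) {
    foot <- which(labels == l)
    px <- (foot - 1L) %% L
    py <- (foot - 1L) %/% L
    area <- length(foot)
    eqd <- 2 * sqrt(area / pi)
    h <- max(hm[foot])
    data.frame(label = l, n_agents = sum(agLab == l), height = h,
               base_area = area, eq_diameter = eqd, aspect_ratio = h / eqd,
               cx = .periodicMean(px, L), cy = .periodicMean(py, L))
  })
  do.call(rbind, out)
}

#' Largest tower of a configuration
#'
#' The tower containing the largest number of agents; ties go to the lowest
#' label.  An empty input yields the sentinel summary with
#' \code{n_agents = 0}.
#'
#' @param x a [WorldState-class] or a data.frame of [towerSummaries()].
#' @return one-row data.frame.
#' @export
largestTower <- function(x) {
  if (is(x, "WorldState")) x <- towerSummaries(x)
  if (nrow(x) == 0L)
    return(data.frame(label = NA_integer_, n_agents = 0L, height = 0L,
                      base_area = 0L, eq_diameter = NA_real_,
                      aspect_ratio = NA_real_, cx = NA_real_, cy = NA_real_))
  cand <- which(x$n_agents == max(x$n_agents))
  x[cand[which.min(x$label[cand])], , drop = FALSE]
}

#' Steady-state check on a largest-tower time series
#'
#' TRUE iff the largest tower's size stayed within +/- 5 percent of N (i.e.
#' max - min <= 0.05 N) over at least the trailing \code{window} time steps.
#' A series spanning less than the window is never at steady state.
#'
#' @param series data.frame with columns \code{t} and \code{n_agents} (as
#'   produced by [simSeries()]), sampled uniformly in t.
#' @param N total agent count of the simulation.
#' @param window trailing window length in time steps.
#' @param tolerance allowed range as a fraction of N.
#' @return logical.
#' @export
steadyState <- function(series, N, window = 100000, tolerance = 0.05) {
  if (is(series, "SimRun")) {
    N <- runParams(series)@N
    series <- simSeries(series)
  }
  if (nrow(series) == 0L) stop("empty series")
  tmax <- max(series$t)
  if (tmax - min(series$t) < window) return(FALSE)
  tailN <- series$n_agents[series$t >= tmax - window]
  (max(tailN) - min(tailN)) <= tolerance * N
}
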