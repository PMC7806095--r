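#' Tower cost function
#'
#' f = (1 - N_tower/N_max) + max(0, 1 - h_tower/h_max): zero for a tower
#' that enrolls every agent and reaches at least the prescribed height
#' ceiling, two when no tower forms at all.  A height at or above
#' \code{hMax} zeroes the second term, so taller towers are never
#' penalized.
#'
#' @param nTower agents in the largest tower.
#' @param hTower height of the largest tower.
#' @param nMax total agents in the simulation (> 0).
#' @param hMax prescribed height ceiling (> 0); 14 approximates the tallest
#'   towers the attraction sweep produces.
#' @return cost in [0, 2]; vectorized.
#' @examples
#' towerCost(993, 16, 1000, 14)   # 0.007
#' @export
towerCost <- function(nTower, hTower, nMax, hMax = 14) {
  stopifnot(all(nMax > 0), all(hMax > 0))
  if (any(nTower < 0) || any(nTower > nMax))
    stop("nTower must lie in [0, nMax]")
  if (any(hTower < 0)) stop("hTower must be non-negative")
  (1 - nTower / nMax) + pmax(0, 1 - hTower / hMax)
}

#' Evaluate one behavioral parameter triple
#'
#' Runs \code{trials} independent simulations at (Pu, knl, c) and averages
#' the tower cost of each run's final largest tower.  Deterministic under a
#' fixed \code{seed} (per-trial seeds come from [childSeeds()]).
#'
#' @param Pu,knl,c the candidate behavioral parameters.
#' @param N,L arena population and side (defaults: 1000 agents, 100 x 100).
#' @param trials replicate simulations to average.
#' @param steps steps per trial; the short 50000-step horizon makes the
#'   search favor parameters that build big towers quickly.
#' @param hMax height ceiling of [towerCost()].
#' @param Psl spontaneous locking probability (held fixed during search).
#' @param seed seed for the trial seed schedule.
#' @return list with \code{f} (mean cost), \code{trials} (per-trial
#'   data.frame: \code{N_tower}, \code{h_tower}, \code{f}, \code{seed}),
#'   \code{N_max}, \code{h_max}.
#' @export
evaluateCandidate <- function(Pu, knl, c, N = 1000, L = 100, trials = 3,
                              steps = 50000, hMax = 14, Psl = 1/20000,
                              seed = 1L) {
  seeds <- childSeeds(seed, trials)
  per <- lapply(seq_len(trials), function(k) {
    run <- runSimulation(simParams(L = L, N = N, Pu = Pu, knl = knl,
                                   Psl = Psl, c = c, steps = steps,
                                   seed = seeds[k]))
    fin <- simSeries(run)[nrow(simSeries(run)), ]
    data.frame(N_tower = fin$n_agents, h_tower = fin$height,
               f = towerCost(fin$n_agents, fin$height, N, hMax),
               seed = seeds[k])
  })
  per <- do.call(rbind, per)
  list(f = mean(per$f), trials = per, N_max = N, h_max = hMax)
}

#' Covariance matrix adaptation evolution strategy (minimization)
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation.  Box constraints are handled
#' by evaluating the objective at the clamped point plus a quadratic
#' out-of-bounds penalty.  The best-seen feasible point is bookkept
#' elitistically, so the reported minimum-cost history is nonincreasing.
#'
#' @param fn objective, a function of a numeric vector.
#' @param x0 initial mean.
#' @param sigma0 initial step size.
#' @param lower,upper box bounds (vectors recycled to \code{length(x0)}).
#' @param lambda population size per iteration.
#' @param maxIter iteration budget.
#' @param stopCost stop early once the best cost is at or below this.
#' @param penalty weight of the squared out-of-bounds penalty.
#' @return list with \code{xbest}, \code{fbest}, \code{history} (data.frame
#'   \code{iter}, \code{fmin} of the iteration, \code{fbest} so far) and
#'   \code{iterations}.
#' @examples
#' set.seed(1)
#' cmaES(function(x) sum((x - 0.3)^2), x0 = c(0.8, 0.8), sigma0 = 0.3,
#'       lower = 0, upper = 1, maxIter = 40, stopCost = 1e-10)$xbest
#' @export
cmaES <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                  lambda = 10, maxIter = 30, stopCost = -Inf,
                  penalty = 1000) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  xbest <- NULL; fbest <- Inf
  hist <- list()
  for (iter in seq_len(maxIter)) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    arz <- matrix(rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arxcl <- pmin(pmax(arx, lower), upper)
    fit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      fraw <- fn(arxcl[, k])
      if (!is.finite(fraw)) fraw <- 2 * max(abs(fbest), 1) + 1e6
      fit[k] <- fraw + penalty * sum((arx[, k] - arxcl[, k])^2)
      if (fraw < fbest) { fbest <- fraw; xbest <- arxcl[, k] }
    }
    ord <- order(fit)
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- as.numeric(arx[, sel, drop = FALSE] %*% w)
    ymean <- (xmean - xold) / sigma
    Cinvsqrt <- B %*% ((1 / D) * t(B))
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsqrt %*% ymean)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * iter)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    hist[[iter]] <- data.frame(iter = iter, fmin = min(fit), fbest = fbest)
    if (fbest <= stopCost) break
  }
  list(xbest = xbest, fbest = fbest, history = do.call(rbind, hist),
       iterations = length(hist))
}

#' Search for tower-maximizing behavioral parameters
#'
#' CMA-ES over (Pu, knl, c) minimizing the mean tower cost of
#' [evaluateCandidate()].  The search runs in coordinates normalized by the
#' upper bounds; out-of-bounds samples are clamped with a penalty.  Psl is
#' held fixed.  Stops at \code{stopCost} or after \code{maxIter}
#' iterations, whichever comes first.
#'
#' @param N,L arena population and side.
#' @param lambda candidate parameter sets per iteration.
#' @param maxIter iteration budget.
#' @param trials,steps,hMax,Psl forwarded to [evaluateCandidate()].
#' @param stopCost early-stopping cost threshold.
#' @param seed master seed (drives both CMA-ES sampling and the per-
#'   evaluation trial seeds).
#' @param lower,upper search bounds on (Pu, knl, c).
#' @param x0 initial mean on (Pu, knl, c).
#' @param sigma0 initial step size in normalized coordinates.
#' @return list with \code{best} (named Pu, knl, c), \code{f},
#'   \code{history}, \code{iterations} and \code{log}, the per-evaluation
#'   record (iteration, candidate, mean f).
#' @export
optimizeTower <- function(N = 1000, L = 100, lambda = 10, maxIter = 30,
                          trials = 3, steps = 50000, hMax = 14,
                          Psl = 1/20000, stopCost = 0.02, seed = 1L,
                          lower = c(0, 0, 0), upper = c(1, 1, 4),
                          x0 = c(0.5, 0.5, 2), sigma0 = 0.25) {
  evalLog <- list()
  counter <- 0L
  iterBox <- new.env()
  iterBox$iter <- 0L
  fn <- function(z) {
    theta <- z * upper
    counter <<- counter + 1L
    ev <- evaluateCandidate(theta[1], theta[2], theta[3], N = N, L = L,
                            trials = trials, steps = steps, hMax = hMax,
                            Psl = Psl, seed = childSeeds(seed, counter + 1L)[counter + 1L])
    evalLog[[counter]] <<- data.frame(eval = counter, Pu = theta[1],
                                      knl = theta[2], c = theta[3],
                                      f = ev$f)
    ev$f
  }
  set.seed(seed)
  res <- cmaES(fn, x0 = x0 / upper, sigma0 = sigma0, lower = lower / upper,
               upper = c(1, 1, 1), lambda = lambda, maxIter = maxIter,
               stopCost = stopCost)
  best <- res$xbest * upper
  list(best = setNames(best, c("Pu", "knl", "c")), f = res$fbest,
       history = res$history, iterations = res$iterations,
       log = do.call(rbind, evalLog))
}
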