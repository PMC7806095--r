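# Pure-R invariant checks for a WorldState.  Deliberately independent of the
# C++ audit: same contracts, separate code path, so tests can cross-check.
.validateWorldR <- function(object) {
  msg <- character()
  hm <- object@height
  ag <- object@agents
  L <- nrow(hm)
  if (is.null(L) || ncol(hm) != L) return("height map must be a square matrix")
  if (anyNA(hm) || any(hm < 0)) msg <- c(msg, "heights must be non-negative")
  if (any(hm != round(hm))) msg <- c(msg, "heights must be integers")
  need <- c("state", "x", "y", "z")
  if (!all(need %in% names(ag)))
    return(c(msg, "agents must have columns state, x, y, z"))
  if (length(object@t) != 1L || is.na(object@t) || object@t < 0)
    msg <- c(msg, "t must be a single non-negative number")
  if (nrow(ag) == 0L) {
    if (sum(hm) != 0) msg <- c(msg, "nonzero heights with no agents")
    return(msg)
  }
  if (!all(ag$state %in% c("free", "locked", "covered")))
    return(c(msg, "agent states must be free/locked/covered"))
  if (any(ag$x < 0 | ag$x >= L | ag$y < 0 | ag$y >= L | ag$z < 0))
    return(c(msg, "agent coordinates out of range"))
  pix <- ag$x + L * ag$y
  hat <- hm[cbind(ag$x + 1L, ag$y + 1L)]
  free <- ag$state == "free"
  if (anyDuplicated(pix[free]))
    msg <- c(msg, "more than one free agent on a pixel")
  if (any(ag$z[free] != hat[free]))
    msg <- c(msg, "free agent not at its pixel surface")
  if (sum(hm) != sum(!free))
    msg <- c(msg, "sum(height) differs from locked+covered count")
  freePix <- pix[free]
  for (p in unique(pix[!free])) {
    rows <- which(!free & pix == p)
    h <- hm[p %% L + 1L, p %/% L + 1L]
    zs <- sort(ag$z[rows])
    if (length(zs) != h || !identical(as.integer(zs), seq_len(h) - 1L)) {
      msg <- c(msg, "stack z-indices not contiguous 0..height-1")
      next
    }
    ord <- rows[order(ag$z[rows])]
    if (h > 1L && any(ag$state[ord[-h]] != "covered"))
      msg <- c(msg, "buried agent not tagged covered")
    topCovered <- p %in% freePix
    wantTop <- if (topCovered) "covered" else "locked"
    if (ag$state[ord[h]] != wantTop)
      msg <- c(msg, sprintf("column top should be %s", wantTop))
  }
  unique(msg)
}

#' Construct a world state
#'
#' Low-level constructor with full invariant validation (occupancy, stack
#' contiguity, coverage tags, conservation).
#'
#' @param height integer L x L matrix of locked-stack heights.
#' @param agents data.frame with columns \code{state} ("free", "locked" or
#'   "covered"), \code{x}, \code{y}, \code{z} (0-based).
#' @param t time step of the snapshot.
#' @return a validated [WorldState-class].
#' @seealso [emptyWorld()], [makeFixture()]
#' @export
worldState <- function(height, agents = data.frame(state = character(),
                                                   x = integer(),
                                                   y = integer(),
                                                   z = integer()),
                       t = 0) {
  storage.mode(height) <- "integer"
  agents$state <- as.character(agents$state)
  agents$x <- as.integer(agents$x)
  agents$y <- as.integer(agents$y)
  agents$z <- as.integer(agents$z)
  new("WorldState", height = height, agents = agents, t = as.numeric(t))
}

#' Empty flat world
#'
#' @param L arena side length.
#' @return a [WorldState-class] with no agents and zero height everywhere.
#' @export
emptyWorld <- function(L) {
  worldState(matrix(0L, L, L))
}

.stateCodes <- c("free", "locked", "covered")

# WorldState <-> the flat list the C++ engine consumes
.worldToList <- function(world) {
  ag <- world@agents
  list(height = world@height,
       state = match(ag$state, .stateCodes) - 1L,
       x = ag$x, y = ag$y, z = ag$z, t = world@t)
}

.listToWorld <- function(lst) {
  worldState(lst$height,
             data.frame(state = .stateCodes[lst$state + 1L],
                        x = lst$x, y = lst$y, z = lst$z),
             t = lst$t)
}

#' @rdname anttower-generics
#' @export
setMethod("agents", "WorldState", function(object) object@agents)

#' @rdname heightMap
#' @export
setMethod("heightMap", "WorldState", function(object) object@height)

setMethod("show", "WorldState", function(object) {
  tab <- table(factor(object@agents$state, levels = .stateCodes))
  cat(sprintf("WorldState: %dx%d arena, t=%g, %d agents (%d free, %d locked, %d covered)\n",
              nrow(object@height), ncol(object@height), object@t,
              nrow(object@agents), tab[["free"]], tab[["locked"]],
              tab[["covered"]]))
  cat(sprintf("  max height %d over %d occupied pixels\n",
              max(object@height), sum(object@height > 0)))
})

# deterministic miniature stack: pixel (x, y) holding `h` agents
.stackAgents <- function(x, y, h, covered_top = FALSE) {
  st <- rep("covered", h)
  st[h] <- if (covered_top) "covered" else "locked"
  data.frame(state = st, x = x, y = y, z = seq_len(h) - 1L)
}

#' Deterministic miniature worlds for examples and tests
#'
#' @param name one of \code{"empty-flat"} (12 x 12, no agents),
#'   \code{"single-stack-4"} (one locked column of four agents),
#'   \code{"seam-tower"} (a tower footprint straddling the periodic x
#'   boundary), \code{"dla-seed"} (one locked agent at the arena center plus
#'   a deterministic lattice of free agents), or \code{"two-towers-merge"}
#'   (not a world: a list with \code{maps} — height-map frames in which two
#'   towers drift together and merge — and \code{times}, samples 250 steps
#'   apart).
#' @return a [WorldState-class], except for \code{"two-towers-merge"}.
#' @examples
#' makeFixture("single-stack-4")
#' @export
makeFixture <- function(name) {
  switch(name,
    "empty-flat" = emptyWorld(12L),
    "single-stack-4" = {
      hm <- matrix(0L, 12L, 12L)
      hm[4L, 4L] <- 4L
      worldState(hm, .stackAgents(3L, 3L, 4L))
    },
    "seam-tower" = {
      hm <- matrix(0L, 12L, 12L)
      hm[12L, 6L] <- 2L   # pixel (11, 5)
      hm[1L, 6L] <- 3L    # pixel (0, 5): adjacent across the seam
      worldState(hm, rbind(.stackAgents(11L, 5L, 2L), .stackAgents(0L, 5L, 3L)))
    },
    "dla-seed" = {
      L <- 25L
      hm <- matrix(0L, L, L)
      hm[13L, 13L] <- 1L
      ag <- .stackAgents(12L, 12L, 1L)
      xs <- seq(2L, 22L, by = 5L)
      grid <- expand.grid(x = xs, y = xs)
      grid <- grid[!(grid$x == 12L & grid$y == 12L), ]
      ag <- rbind(ag, data.frame(state = "free", x = grid$x, y = grid$y,
                                 z = 0L))
      worldState(hm, ag)
    },
    "two-towers-merge" = {
      L <- 20L
      mk <- function(xa, xb) {
        hm <- matrix(0L, L, L)
        hm[xa + 1L + 0:1, 10:11] <- 2L
        hm[xb + 1L + 0:1, 10:11] <- 3L
        hm
      }
      xa <- c(4L, 5L, 6L, 7L, 7L)       # left blob marches right, then halts
      xb <- c(12L, 11L, 10L, 9L, 9L)    # right blob marches left to meet it
      list(maps = Map(mk, xa, xb), times = 250 * (0:4))
    },
    stop("unknown fixture name: ", name)
  )
}
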