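#' Wrap horizontal coordinates into the periodic arena
#'
#' Modular reduction of each component into [0, L); idempotent.
#'
#' @param xy integer vector of length 2 (or a 2-column matrix of coordinate
#'   pairs).
#' @param L arena side length (>= 1).
#' @return wrapped coordinates, same shape as \code{xy}.
#' @examples
#' wrapCoord(c(100, -1), 100)   # -> c(0, 99)
#' @export
wrapCoord <- function(xy, L) {
  stopifnot(L >= 1)
  ((xy %% L) + L) %% L
}

#' Minimal-image displacement between two pixels
#'
#' Returns b - a with each component reduced into [-L/2, L/2), i.e. the
#' displacement to the nearest periodic image of \code{b}.
#'
#' @param a,b integer coordinate pairs in [0, L)^2 (or 2-column matrices).
#' @param L arena side length.
#' @return displacement pair (or matrix), antisymmetric up to wrap.
#' @examples
#' toroidalOffset(c(0, 0), c(99, 0), 100)   # -> c(-1, 0)
#' @export
toroidalOffset <- function(a, b, L) {
  d <- (b - a) %% L
  d - L * (d >= L / 2)
}

#' Locking probability of a free agent
#'
#' P_lock = min(Psl + knl * nLocked, 1): a spontaneous baseline plus a linear
#' neighbor-influenced term, clamped to 1 (with up to 26 Moore neighbors the
#' linear form can exceed 1).
#'
#' @param nLocked number of locked/covered agents in the 26-voxel Moore
#'   neighborhood (0..26).
#' @param Psl spontaneous locking probability, or a [SimParams-class] from
#'   which both rates are taken.
#' @param knl locking-probability increase per locked neighbor.
#' @return probability in [0, 1]; vectorized over \code{nLocked}.
#' @examples
#' lockProbability(0, Psl = 1/20000, knl = 1)      # 5e-05
#' lockProbability(6, Psl = 0, knl = 1/12)         # 0.5
#' @export
lockProbability <- function(nLocked, Psl = 1/20000, knl = 1) {
  if (is(Psl, "SimParams")) {
    knl <- Psl@knl
    Psl <- Psl@Psl
  }
  if (any(nLocked < 0))
    stop("nLocked must be non-negative")
  pmin(Psl + knl * nLocked, 1)
}

#' Velocity of a free agent: random walk plus neighbor attraction
#'
#' v = vRandom + (c / n) * sum of horizontal minimal-image displacements to
#' the n occupied neighbor voxels.  The random part is a unit vector at a
#' uniformly random angle, so \code{c} is literally the ratio of attraction
#' magnitude to randomness magnitude.  Vertical components of neighbor
#' offsets are dropped: motion follows 2-D rules along the surface.
#'
#' @param offsets matrix of occupied-neighbor voxel offsets with columns
#'   dx, dy (a dz column, if present, is ignored); zero rows mean no
#'   neighbors and a pure random step.
#' @param c attraction-to-randomness ratio.
#' @param vRandom the unit random vector; drawn uniformly when NULL.
#' @return numeric length-2 velocity.
#' @examples
#' attractionVelocity(rbind(c(1, 0)), c = 2, vRandom = c(0, 1))  # c(2, 1)
#' @export
attractionVelocity <- function(offsets, c = 0, vRandom = NULL) {
  if (is.null(vRandom)) {
    ang <- runif(1, 0, 2 * pi)
    vRandom <- c(cos(ang), sin(ang))
  }
  n <- nrow(offsets)
  if (is.null(n) || n == 0)
    return(vRandom)
  vRandom + (c / n) * colSums(offsets[, 1:2, drop = FALSE])
}

.DIR8 <- cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
               dy = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Quantize a velocity to the best-aligned lattice direction
#'
#' Returns the horizontal unit lattice step (axis or diagonal) maximizing the
#' cosine with \code{v}; ties are broken uniformly at random; a zero vector
#' means stay put, returned as c(0, 0).
#'
#' @param v numeric length-2 velocity (finite).
#' @return integer pair in \{-1, 0, 1\}^2.
#' @examples
#' selectMove(c(3, 0))   # c(1, 0)
#' selectMove(c(2, 1))   # c(1, 1): 26.57 degrees is nearer 45 than 0
#' @export
selectMove <- function(v) {
  if (length(v) != 2 || anyNA(v) || any(!is.finite(v)))
    stop("v must be a finite length-2 vector")
  as.integer(.cpp_select_move(v[1], v[2]))
}

#' Occupied voxels in an agent's 26-voxel Moore neighborhood
#'
#' Scans the 9 voxels above, 9 below and 8 lateral voxels around an agent's
#' position (wrapped horizontally).  \code{n_all} counts agents of any state
#' (the neighbor count entering the attraction rule); \code{n_locked} counts
#' locked plus covered agents (the N_n entering the locking rule).
#'
#' @param world a [WorldState-class].
#' @param agent agent row index (1-based, as in \code{agents(world)}).
#' @return list with \code{n_all}, \code{n_locked} and \code{offsets}, an
#'   integer matrix of (dx, dy, dz) displacements to occupied voxels.
#' @export
neighborhood <- function(world, agent) {
  stopifnot(is(world, "WorldState"))
  .cpp_neighborhood(.worldToList(world), as.integer(agent) - 1L)
}
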