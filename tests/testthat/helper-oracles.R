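# Independent reference implementations used to cross-check the package.

# minimal-image displacement by brute force over the 9 periodic images
bruteToroidalOffset <- function(a, b, L) {
  best <- NULL
  bestd <- Inf
  for (sx in c(-L, 0, L)) for (sy in c(-L, 0, L)) {
    d <- (b + c(sx, sy)) - a
    if (sum(d^2) < bestd) {
      bestd <- sum(d^2)
      best <- d
    }
  }
  best
}

# wrap by repeated +/- L shifts
bruteWrap <- function(xy, L) {
  for (k in 1:2) {
    while (xy[k] < 0) xy[k] <- xy[k] + L
    while (xy[k] >= L) xy[k] <- xy[k] - L
  }
  xy
}

DIR8 <- cbind(dx = c(1, 1, 0, -1, -1, -1, 0, 1),
              dy = c(0, 1, 1, 1, 0, -1, -1, -1))

# all lattice directions maximizing the cosine with v (exhaustive comparison)
bruteBestDirs <- function(v) {
  cs <- apply(DIR8, 1, function(d) sum(v * d) / sqrt(sum(d^2)))
  which(abs(cs - max(cs)) < 1e-9)
}

# wrap-aware 8-connected labeling via igraph components on the adjacency
# graph of nonzero pixels (independent of the union-find in the package)
igraphLabels <- function(hm, wrap = TRUE) {
  L <- nrow(hm)
  nz <- which(hm > 0)
  if (length(nz) == 0L) return(matrix(0L, L, L))
  id <- match(seq_len(L * L), nz)   # pixel -> vertex
  edges <- c()
  for (p in nz) {
    x <- (p - 1L) %% L
    y <- (p - 1L) %/% L
    for (k in 1:8) {
      nx <- x + DIR8[k, 1]; ny <- y + DIR8[k, 2]
      if (wrap) { nx <- nx %% L; ny <- ny %% L }
      else if (nx < 0 || nx >= L || ny < 0 || ny >= L) next
      q <- nx + L * ny + 1L
      if (hm[q] > 0) edges <- c(edges, id[p], id[q])
    }
  }
  g <- igraph::make_graph(edges, n = length(nz), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab <- matrix(0L, L, L)
  lab[nz] <- comp
  # relabel dense in scan order to match the package convention
  first <- tapply(seq_along(lab[nz]), comp, function(i) min(nz[i]))
  remap <- rank(first)
  lab[nz] <- as.integer(remap[comp])
  lab
}

# labeling of the 3x3 periodic tiling restricted to the central copy
tiledLabels <- function(hm) {
  L <- nrow(hm)
  big <- matrix(0L, 3 * L, 3 * L)
  for (i in 0:2) for (j in 0:2)
    big[i * L + 1:L, j * L + 1:L] <- hm
  lb <- labelTowers(big, wrap = FALSE)
  centre <- lb[L + 1:L, L + 1:L]
  # components touching across the seam get equated through shared tiles:
  # relabel by equivalence of labels appearing at the same offset pixel
  # in adjacent copies
  eq <- list()
  for (di in c(-1L, 0L, 1L)) for (dj in c(-1L, 0L, 1L)) {
    if (di == 0L && dj == 0L) next
    other <- lb[(1 + di) * L + 1:L, (1 + dj) * L + 1:L]
    pair <- cbind(as.vector(centre), as.vector(other))
    pair <- pair[pair[, 1] > 0 & pair[, 2] > 0, , drop = FALSE]
    eq[[length(eq) + 1L]] <- pair
  }
  eq <- unique(do.call(rbind, eq))
  lut <- seq_len(max(lb) + 1L)
  find <- function(x) { while (lut[x] != x) x <- lut[x]; x }
  if (nrow(eq)) for (r in seq_len(nrow(eq))) {
    a <- find(eq[r, 1]); b <- find(eq[r, 2])
    if (a != b) lut[max(a, b)] <- min(a, b)
  }
  out <- centre
  nzc <- which(centre > 0)
  roots <- vapply(centre[nzc], find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  # dense in scan order of first pixel
  first <- tapply(nzc, remap, min)
  out[nzc] <- as.integer(rank(first)[remap])
  out
}

# normalize a labeling to a canonical form (label by first-pixel order)
canonLabels <- function(lab) {
  nz <- which(lab > 0)
  if (!length(nz)) return(lab)
  first <- tapply(nz, lab[nz], min)
  remap <- rank(first)
  lab[nz] <- as.integer(remap[as.character(lab[nz])])
  storage.mode(lab) <- "integer"
  lab
}

# small random world built agent-by-agent with valid stacks, for metric tests
randomHeightMap <- function(L, fill = 0.3, hmax = 4) {
  hm <- matrix(0L, L, L)
  n <- round(fill * L * L)
  idx <- sample(L * L, n)
  hm[idx] <- sample.int(hmax, n, replace = TRUE)
  hm
}
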