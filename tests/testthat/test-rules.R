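test_that("wrapCoord maps coordinates into [0, L) and is idempotent", {
  expect_identical(wrapCoord(c(5, 5), 100), c(5, 5))
  expect_identical(wrapCoord(c(100, -1), 100), c(0, 99))
  expect_identical(wrapCoord(c(237, -150), 100), bruteWrap(c(237, -150), 100))
  set.seed(42)
  for (i in 1:50) {
    xy <- sample(-300:300, 2)
    L <- sample(3:40, 1)
    w <- wrapCoord(xy, L)
    expect_identical(w, bruteWrap(xy, L))
    expect_identical(wrapCoord(w, L), w)
  }
})

test_that("toroidalOffset gives the minimal-image displacement", {
  expect_identical(toroidalOffset(c(0, 0), c(99, 0), 100), c(-1, 0))
  expect_identical(toroidalOffset(c(10, 10), c(10, 10), 100), c(0, 0))
  expect_identical(toroidalOffset(c(20, 80), c(70, 10), 100),
                   bruteToroidalOffset(c(20, 80), c(70, 10), 100))
  set.seed(7)
  for (i in 1:100) {
    L <- sample(4:50, 1)
    a <- sample(0:(L - 1), 2, replace = TRUE)
    b <- sample(0:(L - 1), 2, replace = TRUE)
    d <- toroidalOffset(a, b, L)
    expect_true(all(d >= -L / 2 & d < L / 2))
    # same squared distance as the brute-force minimum over 9 images
    expect_equal(sum(d^2), sum(bruteToroidalOffset(a, b, L)^2))
    # antisymmetric up to wrap
    expect_equal(wrapCoord(d + toroidalOffset(b, a, L), L), c(0, 0))
  }
})

test_that("lockProbability is the clamped linear neighbor rule", {
  expect_equal(lockProbability(0, Psl = 1/20000, knl = 1), 5e-5)
  expect_equal(lockProbability(6, Psl = 0, knl = 1/12), 0.5)
  expect_equal(lockProbability(26, Psl = 1/20000, knl = 1/26), 1)  # clamp
  p <- lockProbability(0:26, Psl = 1/20000, knl = 1/13)
  expect_true(all(diff(p) >= 0))       # monotone
  expect_true(all(p >= 0 & p <= 1))    # clamped
  expect_error(lockProbability(-1), "non-negative")
  prm <- simParams(Pu = 0, knl = 1/12, Psl = 0)
  expect_equal(lockProbability(6, prm), 0.5)
})

test_that("attractionVelocity combines random step and neighbor centroid pull", {
  # no neighbors: pure unit random step
  off0 <- matrix(numeric(0), 0, 2)
  set.seed(1)
  v <- attractionVelocity(off0, c = 5)
  expect_equal(sqrt(sum(v^2)), 1)
  # symmetric neighbors cancel
  expect_equal(attractionVelocity(rbind(c(1, 0), c(-1, 0)), c = 3,
                                  vRandom = c(0.6, -0.8)), c(0.6, -0.8))
  # single neighbor, direct evaluation
  expect_equal(attractionVelocity(rbind(c(1, 0)), c = 2, vRandom = c(0, 1)),
               c(2, 1))
  # dz column ignored (horizontal projection)
  expect_equal(attractionVelocity(cbind(1, 0, -1), c = 2, vRandom = c(0, 1)),
               c(2, 1))
})

test_that("selectMove maximizes cosine over the 8 lattice directions", {
  expect_identical(selectMove(c(3, 0)), c(1L, 0L))
  expect_identical(selectMove(c(0, 0)), c(0L, 0L))   # stay
  expect_identical(selectMove(c(2, 1)), c(1L, 1L))   # 26.57deg nearer 45 than 0
  expect_error(selectMove(c(NaN, 1)), "finite")
  set.seed(3)
  for (i in 1:200) {
    v <- stats::rnorm(2)
    d <- selectMove(v)
    k <- which(DIR8[, 1] == d[1] & DIR8[, 2] == d[2])
    expect_true(k %in% bruteBestDirs(v))
  }
})

test_that("selectMove breaks exact ties uniformly at random", {
  v <- c(cos(pi / 8), sin(pi / 8))   # exactly between (1,0) and (1,1)
  expect_setequal(bruteBestDirs(v), c(1, 2))
  set.seed(11)
  picks <- replicate(400, paste(selectMove(v), collapse = ","))
  tab <- table(picks)
  expect_setequal(names(tab), c("1,0", "1,1"))
  expect_gt(min(tab), 120)   # both sides drawn often (p ~ 1e-9 otherwise)
})

test_that("neighborhood scans the 26 Moore voxels with wrap", {
  # isolated free agent on the floor
  w <- worldState(matrix(0L, 8, 8),
                  data.frame(state = "free", x = 3L, y = 3L, z = 0L))
  nb <- neighborhood(w, 1)
  expect_equal(nb$n_all, 0)
  expect_equal(nb$n_locked, 0)
  expect_equal(nrow(nb$offsets), 0)

  # free agent standing on a single locked agent: support is a neighbor below
  hm <- matrix(0L, 8, 8); hm[4, 4] <- 1L
  w <- worldState(hm, data.frame(state = c("covered", "free"),
                                 x = 3L, y = 3L, z = c(0L, 1L)))
  nb <- neighborhood(w, 2)
  expect_gte(nb$n_locked, 1)
  expect_true(any(nb$offsets[, "dx"] == 0 & nb$offsets[, "dy"] == 0 &
                  nb$offsets[, "dz"] == -1))

  # agent fully enclosed by 26 locked agents: saturation
  hm <- matrix(0L, 8, 8)
  hm[3:5, 3:5] <- 3L
  grid <- expand.grid(x = 2:4, y = 2:4)
  ag <- do.call(rbind, Map(function(x, y)
    data.frame(state = c("covered", "covered", "locked"),
               x = as.integer(x), y = as.integer(y), z = 0:2),
    grid$x, grid$y))
  target <- which(ag$x == 3 & ag$y == 3 & ag$z == 1)
  nb <- neighborhood(worldState(hm, ag), target)
  expect_equal(nb$n_all, 26)
  expect_equal(nb$n_locked, 26)
  expect_equal(nrow(nb$offsets), 26)

  # wrap: neighbor across the periodic seam
  hm <- matrix(0L, 8, 8); hm[1, 4] <- 1L
  w <- worldState(hm, rbind(
    data.frame(state = "locked", x = 0L, y = 3L, z = 0L),
    data.frame(state = "free", x = 7L, y = 3L, z = 0L)))
  nb <- neighborhood(w, 2)
  expect_equal(nb$n_all, 1)
  expect_equal(nb$n_locked, 1)
})
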