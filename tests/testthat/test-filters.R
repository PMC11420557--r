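test_that("density filter preserves uniform fields and impulse mass", {
  mask <- array(TRUE, dim = c(9, 9, 9))
  expect_equal(density_filter(array(0.4, dim = dim(mask)), mask,
                              radius = 2.5),
               rep(0.4, sum(mask)))
  # impulse at the centre: kernel sums to 1 and decays with distance
  x <- array(0, dim = dim(mask))
  x[5, 5, 5] <- 1
  xf <- density_filter(x, mask, radius = 2.5)
  expect_equal(sum(xf), 1, tolerance = 1e-12)
  a <- array(xf, dim = dim(mask))
  expect_true(a[5, 5, 5] > a[6, 5, 5])
  expect_true(a[6, 5, 5] > a[7, 5, 5])
  expect_equal(a[8, 5, 5], 0)  # outside the cone support
})

test_that("wider filters smooth an impulse peak more", {
  mask <- array(TRUE, dim = c(11, 11, 11))
  x <- array(0, dim = dim(mask))
  x[6, 6, 6] <- 1
  p1 <- max(density_filter(x, mask, radius = 1.5))
  p2 <- max(density_filter(x, mask, radius = 3))
  expect_lt(p2, p1)
  expect_error(density_filter(x, mask, radius = 0.5), "radius")
})

test_that("tanh projection fixes endpoints, midpoint, and its derivative", {
  expect_equal(heaviside_project(0.5, beta = 7, eta = 0.5), 0.5)
  # at other thresholds the normalised tanh form reaches 0.5 as beta grows
  expect_equal(heaviside_project(0.4, beta = 64, eta = 0.4), 0.5,
               tolerance = 1e-9)
  expect_lt(heaviside_project(0, 32, 0.5), 1e-10)
  expect_gt(heaviside_project(1, 32, 0.5), 1 - 1e-10)
  expect_gt(heaviside_project(0.51, 500, 0.5), 0.999)
  x <- seq(0.05, 0.95, length.out = 10)
  h <- 1e-6
  fd <- (heaviside_project(x + h, 8, 0.5) -
         heaviside_project(x - h, 8, 0.5)) / (2 * h)
  expect_equal(heaviside_project(x, 8, 0.5, deriv = TRUE), fd,
               tolerance = 1e-6)
  expect_true(all(diff(heaviside_project(seq(0, 1, 0.01), 16, 0.3)) > 0))
})

test_that("discreteness measure matches its closed form", {
  expect_equal(discreteness(c(0, 1, 1, 0)), 0)
  expect_equal(discreteness(rep(0.5, 10)), 100)
  expect_equal(discreteness(c(rep(0.25, 5), rep(0.75, 5))), 75)
})

test_that("local volume constraint: uniform fields and p-mean bound", {
  mask <- array(TRUE, dim = c(10, 10, 10))
  v0 <- local_volume_constraint(array(0.35, dim = dim(mask)), mask,
                                radius = 2.5)
  expect_equal(as.numeric(v0), 0, tolerance = 1e-12)
  v1 <- local_volume_constraint(array(0.7, dim = dim(mask)), mask,
                                radius = 2.5)
  expect_equal(as.numeric(v1), 1.0, tolerance = 1e-12)
  # one saturated neighbourhood: p-mean(16) exceeds the plain mean
  x <- array(0.05, dim = dim(mask))
  x[4:6, 4:6, 4:6] <- 1
  H <- spinecage:::neighbourhood_matrix(which(mask), dim(mask), 2.5,
                                        "uniform")
  rb <- as.numeric(H %*% x[mask])
  vpm <- attr(local_volume_constraint(x, mask, radius = 2.5), "pmean")
  expect_gt(vpm, mean(rb))
  expect_lt(vpm, max(rb) + 1e-9)
})

test_that("local volume gradient matches finite differences", {
  mask <- array(TRUE, dim = c(6, 6, 6))
  set.seed(3)
  x <- runif(sum(mask), 0.1, 0.9)
  v <- local_volume_constraint(x, which(mask), dims = dim(mask),
                               radius = 2.5)
  g <- attr(v, "grad")
  h <- 1e-6
  for (i in c(1, 40, 111, 200)) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    fd <- (as.numeric(local_volume_constraint(xp, which(mask),
                                              dims = dim(mask),
                                              radius = 2.5)) -
           as.numeric(local_volume_constraint(xm, which(mask),
                                              dims = dim(mask),
                                              radius = 2.5))) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-6)
  }
  expect_error(local_volume_constraint(x, which(mask), dims = dim(mask),
                                       radius = 10), "radius")
})

test_that("MMA solves a convex quadratic with a linear constraint", {
  # min x1^2 + x2^2  s.t.  1 - x1 - x2 <= 0  ->  x* = (0.5, 0.5)
  x <- c(0.9, 0.2)
  xold1 <- x; xold2 <- x
  low <- c(0, 0); upp <- c(1, 1)
  for (it in 1:40) {
    f0 <- sum(x^2); df0 <- 2 * x
    fv <- 1 - sum(x); dfv <- matrix(-1, 1, 2)
    upd <- spinecage:::mma_update(it, x, c(0, 0), c(1, 1), xold1, xold2,
                                  f0, df0, fv, dfv, low, upp, move = 0.2)
    xold2 <- xold1; xold1 <- x
    x <- upd$x; low <- upd$low; upp <- upd$upp
  }
  expect_equal(x, c(0.5, 0.5), tolerance = 1e-3)
})
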