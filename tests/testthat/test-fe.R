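test_that("hexahedral element stiffness has exactly the rigid-body nullspace", {
  Ke <- element_stiffness(1, 0.3, 1)
  expect_equal(Ke, t(Ke))
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-10), 6)
  expect_true(min(ev[ev > 1e-10]) > 0)
  # rigid translations and rotations produce zero force
  X <- cbind(rep(c(0, 1, 1, 0, 0, 1, 1, 0), each = 1),
             c(0, 0, 1, 1, 0, 0, 1, 1),
             c(0, 0, 0, 0, 1, 1, 1, 1))
  modes <- cbind(
    as.vector(t(cbind(1, 0, 0)[rep(1, 8), ])),
    as.vector(t(cbind(0, 1, 0)[rep(1, 8), ])),
    as.vector(t(cbind(0, 0, 1)[rep(1, 8), ])),
    as.vector(t(cbind(-X[, 2], X[, 1], 0))),
    as.vector(t(cbind(0, -X[, 3], X[, 2]))),
    as.vector(t(cbind(X[, 3], 0, -X[, 1]))))
  expect_lt(max(abs(Ke %*% modes)), 1e-12)
})

test_that("element stiffness scales linearly with E and with h", {
  K1 <- element_stiffness(1000, 0.3, 1)
  expect_equal(element_stiffness(2000, 0.3, 1), 2 * K1)
  expect_equal(element_stiffness(1000, 0.3, 2.5), 2.5 * K1)
  expect_error(element_stiffness(1000, 0.5, 1), "poisson")
})

test_that("affine patch test: boundary-imposed affine field is reproduced", {
  m <- block_model(5)
  fe <- fe_setup(m)
  # strain state exx=1e-3, eyy=-2e-4, ezz=5e-4, gxy=4e-4, gyz=-3e-4, gxz=2e-4
  G <- matrix(c(1e-3, 2e-4, 1e-4,
                2e-4, -2e-4, -1.5e-4,
                1e-4, -1.5e-4, 5e-4), 3, 3)
  u_aff <- fe$node_coord %*% G
  ijk <- fe$node_coord / m$spacing
  boundary <- apply(ijk, 1, function(p) any(p < 0) || any(p > 4.01))
  bn <- which(boundary)
  fixed <- as.vector(rbind(3 * bn - 2, 3 * bn - 1, 3 * bn))
  vals <- as.vector(t(u_aff[bn, ]))
  res <- solve_linear(fe, rep(1000, fe$nelem), 0.3,
                      numeric(fe$ndof), fixed_dofs = fixed,
                      fixed_values = vals)
  target <- c(1e-3, -2e-4, 5e-4, 2 * 2e-4, 2 * -1.5e-4, 2 * 1e-4)
  for (k in 1:6) {
    expect_equal(res$strain[[1]][, k], rep(target[k], fe$nelem),
                 tolerance = 1e-9)
  }
})

test_that("uniaxial block matches the closed-form strain within 2%", {
  sol <- uniaxial_solve(8)
  eps_analytic <- sol$sigma / sol$E
  ezz <- sol$res$strain[[1]][, 3]
  expect_lt(abs(mean(ezz) / eps_analytic - 1), 0.02)
})

test_that("refinement converges monotonically toward the uniaxial solution", {
  # field-level (root-mean-square) deviation of the axial strain from the
  # uniform analytic field shrinks under refinement; the pointwise maximum
  # cannot converge here because the equal-per-node top load acts like a
  # point load at the boundary nodes
  errs <- vapply(c(4, 6, 8, 10), function(n) {
    sol <- uniaxial_solve(n)
    sd(sol$res$strain[[1]][, 3]) / abs(sol$sigma / sol$E)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("principal strains match a generic eigensolver and are frame-invariant", {
  expect_equal(principal_strains(c(0.01, 0.002, -0.005, 0, 0, 0)),
               c(eps_max = 0.01, eps_mid = 0.002, eps_min = -0.005))
  # pure engineering shear: equal magnitude, opposite signs
  ps <- principal_strains(c(0, 0, 0, 0.02, 0, 0))
  expect_equal(unname(ps[1]), 0.01)
  expect_equal(unname(ps[3]), -0.01)
  set.seed(7)
  for (i in 1:20) {
    v <- runif(6, -0.02, 0.02)
    A <- matrix(c(v[1], v[4] / 2, v[6] / 2,
                  v[4] / 2, v[2], v[5] / 2,
                  v[6] / 2, v[5] / 2, v[3]), 3, 3)
    expect_equal(unname(principal_strains(v)),
                 sort(eigen(A, symmetric = TRUE)$values, decreasing = TRUE),
                 tolerance = 1e-12)
    # rotate the tensor by a random rotation: eigenvalues unchanged
    qr_d <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_d)
    B <- R %*% A %*% t(R)
    vb <- c(B[1, 1], B[2, 2], B[3, 3], 2 * B[1, 2], 2 * B[2, 3], 2 * B[1, 3])
    expect_equal(unname(principal_strains(vb)),
                 unname(principal_strains(v)), tolerance = 1e-12)
  }
})

test_that("load distribution closes force and moment resultants exactly", {
  fe <- fe_setup(toy_model(6, 6))
  resultants <- function(f) {
    idx <- seq(1, fe$ndof, 3)
    fx <- f[idx]; fy <- f[idx + 1]; fz <- f[idx + 2]
    nodes <- fe$node_coord
    rigid <- fe$elem_label == voxel_labels()[["rigid"]]
    ref <- c(colMeans(fe$elem_ijk[rigid, 1:2, drop = FALSE]) - 1, 0) *
      fe$h + c(fe$model$origin[1:2], max(nodes[fe$top_nodes, 3]))
    r <- sweep(nodes, 2, ref)
    c(sum(fx), sum(fy), sum(fz),
      sum(r[, 2] * fz - r[, 3] * fy),
      sum(r[, 3] * fx - r[, 1] * fz),
      sum(r[, 1] * fy - r[, 2] * fx))
  }
  for (case in reference_load_set(64)$cases) {
    f <- distribute_load(case, fe)
    expect_equal(resultants(f), c(case$force, case$moment),
                 tolerance = 1e-9, info = case$name)
  }
})

test_that("pure axial force is distributed uniformly over the top nodes", {
  fe <- fe_setup(toy_model(6, 6))
  f <- distribute_load(load_case("comp", force = c(0, 0, -177)), fe)
  fz <- f[3 * fe$top_nodes]
  expect_equal(fz, rep(-177 / length(fe$top_nodes), length(fe$top_nodes)),
               tolerance = 1e-9)
  expect_error(load_case("null"), "nonzero")
})

test_that("load-set magnitudes scale with patient weight", {
  ls51 <- reference_load_set(51)
  ls102 <- reference_load_set(102)
  expect_equal(ls51$cases[[1]]$force[3], -177)
  expect_equal(ls102$cases[[1]]$force[3], -354)
  expect_equal(ls51$cases[[6]]$moment[3], 700)  # 0.7 Nm in Nmm
})

test_that("solution is linear in load and energy-consistent", {
  m <- toy_model()
  fe <- fe_setup(m)
  E <- rep(500, fe$nelem)
  f <- distribute_load(load_case("c", force = c(0, 0, -50)), fe)
  r1 <- solve_linear(fe, E, 0.3, f)
  r2 <- solve_linear(fe, E, 0.3, 2 * f)
  expect_equal(r2$u, 2 * r1$u, tolerance = 1e-12)
  expect_equal(r2$strain[[1]], 2 * r1$strain[[1]], tolerance = 1e-12)
  expect_equal(r2$compliance, 4 * r1$compliance, tolerance = 1e-12)
  # equilibrium: K u = f on free dofs to 1e-9 relative
  K <- assemble_K(fe, E, 0.3)
  res <- (K %*% r1$u[, 1] - f)[fe$free_dofs]
  expect_lt(sqrt(sum(res^2)) / sqrt(sum(f^2)), 1e-9)
  # energy identity: u'Ku equals compliance
  expect_equal(as.numeric(t(r1$u[, 1]) %*% K %*% r1$u[, 1]),
               r1$compliance, tolerance = 1e-9)
})

test_that("rigid-surrogate layers strain by under 1% of the bone mean", {
  n <- 6
  lbl <- voxel_labels()
  lab <- array(lbl[["bone"]], dim = c(n, n, n))
  lab[, , 4:6] <- lbl[["rigid"]]
  m <- voxel_model(lab, array(0.3, dim = dim(lab)), spacing = 1)
  fe <- fe_setup(m)
  E_bone <- 1000
  E <- ifelse(fe$elem_label == lbl[["rigid"]], 1000 * E_bone, E_bone)
  f <- distribute_load(load_case("c", force = c(0, 0, -100)), fe)
  res <- solve_linear(fe, E, 0.3, f)
  mag <- sqrt(rowSums(res$strain[[1]]^2))
  rigid <- fe$elem_label == lbl[["rigid"]]
  expect_lt(mean(mag[rigid]), 0.01 * mean(mag[!rigid]))
})

test_that("a floating region is reported as a solver error", {
  lbl <- voxel_labels()
  lab <- array(lbl[["void"]], dim = c(4, 4, 7))
  lab[, , 1:2] <- lbl[["bone"]]
  lab[, , 5:7] <- lbl[["bone"]]  # disconnected from the supported block
  m <- voxel_model(lab, array(0.3, dim = dim(lab)), spacing = 1)
  fe <- fe_setup(m)
  f <- numeric(fe$ndof)
  f[3 * fe$top_nodes] <- -1
  expect_error(solve_linear(fe, rep(1000, fe$nelem), 0.3, f),
               "disconnected|singular")
})
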