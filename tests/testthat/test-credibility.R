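test_that("percent difference follows the (current-previous)/previous form", {
  expect_equal(percent_diff(105, 100), 5)
  expect_equal(percent_diff(100, 100), 0)
  expect_equal(percent_diff(17.65, 10), 76.5)
  expect_equal(percent_diff(95, 100), -5)
  expect_error(percent_diff(1, 0), "baseline")
})

test_that("spearman matches a brute-force rank computation", {
  expect_equal(spearman(1:3, c(10, 20, 30))$r, 1)
  expect_equal(spearman(1:3, c(30, 20, 10))$r, -1)
  brute <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  set.seed(9)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(spearman(x, y)$r, brute(x, y), tolerance = 1e-12)
  # ties: average ranks
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  expect_equal(spearman(xt, yt)$r, brute(xt, yt), tolerance = 1e-12)
  expect_error(spearman(1:3, 1:4), "mismatch")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("mann-whitney U matches pairwise counting, exact p for small n", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.05)
  brute_u <- function(a, b) {
    sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  brute_p <- function(a, b) {
    # exact two-sided p by enumerating group reassignments (tie-free)
    pool <- c(a, b)
    na <- length(a)
    obs <- brute_u(a, b)
    combs <- utils::combn(length(pool), na)
    us <- apply(combs, 2, function(ix) brute_u(pool[ix], pool[-ix]))
    mu <- na * length(b) / 2
    # both tails at least as extreme as the observed U (the null is
    # symmetric about mu, so this equals the doubled one-tail probability)
    min(1, mean(abs(us - mu) >= abs(obs - mu) - 1e-9))
  }
  set.seed(21)
  for (i in 1:20) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pool <- sample(1000, na + nb)  # tie-free across both samples
    a <- pool[1:na]; b <- pool[-(1:na)]
    got <- mann_whitney(a, b)
    expect_equal(got$U, brute_u(a, b))
    expect_equal(got$p, brute_p(a, b), tolerance = 1e-9)
  }
  # ties: the half-count U still matches
  a <- c(1, 2, 2, 3); b <- c(2, 3, 4)
  expect_equal(mann_whitney(a, b)$U, brute_u(a, b))
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("mesh convergence study reports diffs against the 5% threshold", {
  build <- function(h) {
    n <- max(12, round(21.6 / h))
    m <- small_phantom(grid_n = n, trab_mean = 0.3, domain_mm = 21.6,
                       radii_mm = c(8.5, 6.7), gap_mm = 5, dish_mm = 2.2,
                       slab_vox = 2)
    list(model = insert_design(m, conforming_implant(m)))
  }
  st <- mesh_convergence_study(build, edge_lengths = c(1.44, 1.2, 1.08),
                               threshold = 5, homogeneous_modulus = 350)
  expect_equal(nrow(st), 3)
  expect_equal(st$percent_diff[1], 0)
  expect_true(all(is.finite(st$max_ffr)))
  expect_error(mesh_convergence_study(build, c(1, 2)), "decreasing")
  expect_error(mesh_convergence_study(build, 1.8), "two edge")
  # degenerate: identical models at both resolutions -> diff 0, converged
  same <- function(h) build(1.44)
  st0 <- mesh_convergence_study(same, c(2, 1))
  expect_equal(st0$percent_diff[2], 0)
  expect_true(st0$converged[2])
})

test_that("sensitivity studies behave linearly in the elastic regime", {
  m <- small_phantom(grid_n = 16, trab_mean = 0.45)
  prob <- list(model = insert_design(m, conforming_implant(m)))
  sc <- sensitivity_study(prob, "constitutive")
  expect_equal(attr(sc, "max_abs_diff"), 0, tolerance = 1e-9)
  sl <- sensitivity_study(prob, "load_magnitude")
  applied <- c(-25, -2.5, 2.5, 25)
  expect_equal(sl$percent_diff[-1], applied, tolerance = 1e-6)
  expect_lte(max(abs(sl$percent_diff[2:3 + 1])), 2.5 + 1e-9)
  sd_law <- sensitivity_study(prob, "density_law")
  expect_equal(sd_law$setting, c("baseline", "keller", "morgan"))
  expect_true(all(is.finite(sd_law$max_ffr)))
})

test_that("past yield the constitutive model matters", {
  m <- small_phantom(grid_n = 16, trab_mean = 0.18)
  prob <- list(model = insert_design(m, conforming_implant(m)),
               patient_weight = 300,
               cfg = assess_config(load_increments = 4))
  sc <- sensitivity_study(prob, "constitutive")
  expect_gt(abs(attr(sc, "max_abs_diff")), 0)
})

test_that("cohort report computes medians, reductions and p-values", {
  res <- data.frame(patient = rep(1:5, 2),
                    group = rep(c("A", "B"), each = 5),
                    max_ffr = c(2, 4, 6, 8, 10, 1, 2, 3, 4, 5))
  cr <- cohort_report(res)
  expect_equal(cr$groups$median_max_ffr[cr$groups$group == "A"], 6)
  pw <- cr$pairwise
  expect_equal(pw$median_reduction_pct[pw$group1 == "A"], 50)
  same <- res
  same$max_ffr[same$group == "B"] <- same$max_ffr[same$group == "A"]
  cr2 <- cohort_report(same)
  expect_equal(cr2$pairwise$median_reduction_pct, 0)
  expect_gt(cr2$pairwise$p, 0.05)
  expect_error(cohort_report(res[res$group == "A", ]), "two implant")
  # vBMD correlation block
  res$vbmd <- rep(c(0.5, 0.4, 0.3, 0.2, 0.1), 2)
  cr3 <- cohort_report(res)
  expect_equal(cr3$vbmd_correlation$r, c(-1, -1))
})

test_that("V&V40 template embeds quantitative studies as documentation", {
  st <- data.frame(setting = "baseline", max_ffr = 1, percent_diff = 0)
  path <- tempfile(fileext = ".md")
  vv40_template(list(`mesh convergence` = st), path)
  txt <- readLines(path)
  expect_true(any(grepl("mesh convergence", txt)))
  expect_true(any(grepl("Model risk", txt)))
})
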