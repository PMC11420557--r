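test_that("iso-surface of a voxel cube recovers its area and topology", {
  f <- array(0, dim = c(16, 16, 16))
  f[3:14, 3:14, 3:14] <- 1
  mesh <- extract_surface(f, iso = 0.5, spacing = 1)
  expect_gt(mesh$n_triangles, 0)
  # contour at 0.5 lies halfway between voxel centres: cube of side 12
  expect_lt(abs(mesh_area(mesh) / (6 * 12^2) - 1), 0.05)
  topo <- spinecage:::mesh_topology(mesh)
  expect_equal(topo$euler, 2)
  expect_true(topo$watertight)
})

test_that("surface vertices land in physical coordinates", {
  f <- array(0, dim = c(8, 8, 8))
  f[3:6, 3:6, 3:6] <- 1
  mesh <- extract_surface(f, spacing = 2, origin = c(10, 0, 0))
  # centre of the solid block: voxel indices 3..6 -> x centre 10 + 3.5*2
  expect_equal(mean(range(mesh$vertices[, 1])), 10 + 3.5 * 2)
  expect_equal(diff(range(mesh$vertices[, 2])), 8)  # 4 voxels * 2 mm
})

test_that("empty fields give an empty mesh with a warning, not a failure", {
  expect_warning(mesh <- extract_surface(array(0, dim = c(4, 4, 4))),
                 "empty")
  expect_equal(mesh$n_triangles, 0L)
})

test_that("porosity is the void fraction of the reference region", {
  reg <- array(TRUE, dim = c(4, 4, 4))
  expect_equal(porosity(array(1, dim = c(4, 4, 4)), reg), 0)
  expect_equal(porosity(array(0, dim = c(4, 4, 4)), reg), 1)
  cb <- array((slice.index(reg, 1) + slice.index(reg, 2) +
               slice.index(reg, 3)) %% 2, dim = dim(reg))
  expect_equal(porosity(cb, reg), 0.5)
  x <- array(runif(64), dim = dim(reg))
  expect_equal(porosity(x >= 0.5, reg) + sum(x >= 0.5) / 64, 1)
  expect_error(porosity(x, array(FALSE, dim = dim(reg))), "empty")
})

test_that("local-thickness pore diameter matches constructed pores", {
  n <- 20
  ijk <- arrayInd(seq_len(n^3), c(n, n, n))
  ctr <- (n + 1) / 2
  sol <- array(1, dim = c(n, n, n))
  sol[sqrt(rowSums((ijk - ctr)^2)) <= 5] <- 0
  pd <- mean_pore_diameter(sol, spacing = 1)
  expect_lt(abs(pd$mean / 10 - 1), 0.10)
  # two disjoint pores of diameter 4 and 8: volume-weighted mean in between
  sol2 <- array(1, dim = c(24, 16, 16))
  ijk2 <- arrayInd(seq_len(24 * 16 * 16), c(24, 16, 16))
  sol2[sqrt(rowSums(sweep(ijk2, 2, c(6.5, 8.5, 8.5))^2)) <= 2] <- 0
  sol2[sqrt(rowSums(sweep(ijk2, 2, c(17.5, 8.5, 8.5))^2)) <= 4] <- 0
  pd2 <- mean_pore_diameter(sol2, spacing = 1)
  expect_gt(pd2$mean, 4)
  expect_lt(pd2$mean, 8)
  # fully void cube of side s: diameter bounded by s
  pd3 <- mean_pore_diameter(array(0, dim = c(9, 9, 9)), spacing = 2)
  expect_lte(pd3$mean, 18)
  expect_warning(pd4 <- mean_pore_diameter(array(1, dim = c(5, 5, 5))),
                 "no void")
  expect_equal(pd4$mean, 0)
})

test_that("binary STL round-trips triangle count and vertices", {
  f <- array(0, dim = c(8, 8, 8))
  f[3:6, 3:6, 3:6] <- 1
  mesh <- extract_surface(f, spacing = 0.9)
  path <- tempfile(fileext = ".stl")
  write_stl(mesh, path)
  # independent check of the header triangle count
  con <- file(path, "rb")
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  close(con)
  expect_equal(nt, mesh$n_triangles)
  expect_equal(file.size(path), 84 + 50 * mesh$n_triangles)
  back <- read_stl(path)
  expect_equal(back$n_triangles, mesh$n_triangles)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
  # degenerate empty mesh round-trips too
  p2 <- tempfile(fileext = ".stl")
  suppressWarnings(write_stl(extract_surface(array(0, dim = c(3, 3, 3))),
                             p2))
  expect_equal(read_stl(p2)$n_triangles, 0L)
})

test_that("voxel models and fields round-trip through NIfTI and VTI", {
  m <- small_phantom(grid_n = 16)
  stem <- tempfile()
  write_voxel_model(m, stem)
  back <- read_voxel_model(stem)
  expect_identical(back$labels, m$labels)
  expect_equal(back$density, m$density, tolerance = 1e-7)
  expect_equal(back$spacing, m$spacing)
  fld <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  vp <- tempfile(fileext = ".vti")
  write_vti(fld, vp, spacing = 0.45, origin = c(1, 2, 3), name = "design")
  rb <- read_vti(vp)
  expect_equal(rb$field, fld, tolerance = 1e-6)
  expect_equal(rb$spacing, 0.45)
  expect_equal(rb$origin, c(1, 2, 3))
  expect_equal(rb$name, "design")
})

test_that("morphology report on a synthetic porous design is consistent", {
  set.seed(5)
  n <- 16
  reg <- array(FALSE, dim = c(n, n, n))
  reg[3:14, 3:14, 5:12] <- TRUE
  x <- array(0, dim = c(n, n, n))
  x[reg] <- runif(sum(reg)) < 0.4
  mo <- implant_morphology(x, region = which(reg), spacing = 1)
  expect_equal(mo$porosity, 1 - sum(x[reg]) / sum(reg))
  expect_true(mo$mean_pore_diameter > 0)
  expect_true(mo$surface_triangle_count > 0)
})
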