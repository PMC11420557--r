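test_that("density-to-modulus laws evaluate their published forms", {
  expect_equal(modulus_from_density(density_law("ouyang_baseline"), 1.0),
               2383)
  expect_equal(modulus_from_density(density_law("morgan"), 1.0), 4730)
  # linear reading of the Keller relationship: 2100 * 1.0 - 80
  expect_equal(modulus_from_density(density_law("keller"), 1.0), 2020)
  expect_equal(modulus_from_density(density_law("ouyang_baseline"), 0.5),
               2383 * 0.5^1.88)
})

test_that("modulus floor clamps low-density bone to 25 MPa", {
  expect_equal(modulus_from_density(density_law(), 0, floor = TRUE), 25)
  # Keller law is negative below ~0.038 g/cm^3; the floor removes that
  expect_equal(modulus_from_density(density_law("keller"), 0.01,
                                    floor = TRUE), 25)
  expect_lt(modulus_from_density(density_law("keller"), 0.01), 0)
})

test_that("laws are finite, non-negative (floored) and non-decreasing", {
  rho <- seq(0, 2, length.out = 101)
  for (id in c("ouyang_baseline", "keller", "morgan")) {
    E <- modulus_from_density(density_law(id), rho, floor = TRUE)
    expect_true(all(is.finite(E)) && all(E >= 0))
    expect_true(all(diff(E) >= 0), info = id)
  }
  expect_error(modulus_from_density(density_law(), -0.1), "non-negative")
  expect_error(density_law("carter"), "one of")
})

test_that("SIMP interpolation hits its endpoints and is monotone", {
  ti <- implant_material("titanium")
  expect_equal(simp_modulus(1, ti, 3, 0.11), 110000)
  expect_equal(simp_modulus(0, implant_material("peek"), 3, 0.3), 0.3)
  expect_equal(simp_modulus(0.5, ti, 3, 0), 0.5^3 * 110000)
  x <- seq(0, 1, length.out = 50)
  expect_true(all(diff(simp_modulus(x, ti)) > 0))
  expect_error(simp_modulus(1.2, ti), "outside")
})

test_that("implant materials carry the published constants", {
  ti <- implant_material("titanium")
  pk <- implant_material("peek")
  expect_equal(ti$E, 110000)
  expect_equal(pk$E, 3000)
  expect_equal(ti$poisson, 0.3)
  expect_equal(pk$poisson, 0.43)
  expect_true(ti$yield_strain < ti$ultimate_strain)
  expect_true(pk$yield_strain < pk$ultimate_strain)
})

test_that("bilinear bone law: elastic inside, 5% tangent outside", {
  bc <- bone_constitutive()
  expect_equal(bone_stress(bc, 1000, 0.005), 5.0)
  expect_equal(bone_stress(bc, 1000, 0.0173),
               1000 * 0.0073 + 50 * (0.0173 - 0.0073))
  expect_equal(bone_stress(bone_constitutive("linear"), 1000, 0.0173), 17.3)
  # derivative by central differences at sampled strains
  eps <- seq(-0.03, 0.03, length.out = 20)
  h <- 1e-7
  slopes <- (bone_stress(bc, 1000, eps + h) -
             bone_stress(bc, 1000, eps - h)) / (2 * h)
  inside <- eps > bc$compressive_yield_strain + 2 * h &
            eps < bc$tensile_yield_strain - 2 * h
  expect_equal(slopes[inside], rep(1000, sum(inside)), tolerance = 1e-6)
  outside <- eps < bc$compressive_yield_strain - 2 * h |
             eps > bc$tensile_yield_strain + 2 * h
  expect_equal(slopes[outside], rep(50, sum(outside)), tolerance = 1e-6)
  # continuity across the yield points
  for (ey in c(bc$tensile_yield_strain, bc$compressive_yield_strain)) {
    expect_equal(bone_stress(bc, 1000, ey - 1e-10),
                 bone_stress(bc, 1000, ey + 1e-10), tolerance = 1e-6)
  }
})

test_that("linear and asymmetric modes agree exactly inside the yield interval", {
  bc_a <- bone_constitutive()
  bc_l <- bone_constitutive("linear")
  eps <- seq(-0.0103, 0.0072, length.out = 41)
  expect_identical(bone_stress(bc_a, 1234, eps), bone_stress(bc_l, 1234, eps))
})

test_that("symmetric mode yields at the tensile magnitude on both sides", {
  bc_s <- bone_constitutive("elastoplastic_symmetric")
  expect_equal(bone_stress(bc_s, 1000, -0.009),
               1000 * -0.0073 + 50 * (-0.009 + 0.0073))
  expect_equal(bone_stress(bc_s, 1000, -0.007), -7)
})

test_that("JSON and YAML config files populate parameter objects", {
  pj <- tempfile(fileext = ".json")
  writeLines('{"local_volume_fraction": 0.4, "max_iters": 12}', pj)
  cfg <- do.call(topopt_config, read_config(pj))
  expect_equal(cfg$local_volume_fraction, 0.4)
  expect_equal(cfg$max_iters, 12)
  py <- tempfile(fileext = ".yaml")
  writeLines(c("base_follower_load: 310", "load_increments: 5"), py)
  ac <- do.call(assess_config, read_config(py))
  expect_equal(ac$load_increments, 5)
  expect_error(read_config(tempfile(fileext = ".toml")), "unsupported")
})

test_that("load sets build from config files with declared units", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("patient_weight: 102", "reference_weight: 51", "cases:",
               "  - name: axial_compression", "    force_N: [0, 0, -177]",
               "  - name: axial_rotation", "    moment_Nm: [0, 0, 0.7]"), p)
  ls <- load_set_from_config(p)
  expect_equal(ls$cases[[1]]$force, c(0, 0, -354))
  expect_equal(ls$cases[[2]]$moment, c(0, 0, 1400))  # Nm -> Nmm, x2 weight
})
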