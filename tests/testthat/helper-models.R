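# Shared fixtures: all models are generated in code at test time.

# Minimal layered bone-design-bone model with rigid caps: full cross-section
# columns so every layer is load-bearing.  Small enough for finite-difference
# gradient checks.
toy_model <- function(nx = 4, ny = 4) {
  lab <- array(0L, dim = c(nx, ny, 6))
  lbl <- voxel_labels()
  lab[, , 1] <- lbl[["rigid"]]
  lab[, , 6] <- lbl[["rigid"]]
  lab[, , 2] <- lbl[["bone"]]
  lab[, , 5] <- lbl[["bone"]]
  lab[, , 3] <- lbl[["implant_design"]]
  lab[, , 4] <- lbl[["implant_design"]]
  den <- array(0, dim = dim(lab))
  den[lab == lbl[["bone"]]] <- 0.3
  voxel_model(lab, den, spacing = 1)
}

# Homogeneous bone block (no design domain) for analytic FE oracles.
block_model <- function(n = 8, density = 0.5, spacing = 1) {
  lab <- array(voxel_labels()[["bone"]], dim = c(n, n, n))
  den <- array(density, dim = c(n, n, n))
  voxel_model(lab, den, spacing = spacing)
}

small_phantom <- function(grid_n = 24, trab_mean = 0.25, seed = 1, ...) {
  generate_phantom(phantom_spec(grid_n = grid_n, trab_mean = trab_mean,
                                seed = seed, ...))
}

# Uniaxial compression of a homogeneous block with roller supports: bottom
# fixed in z only (plus minimal lateral restraints), uniform top load.
uniaxial_solve <- function(n = 8, E = 1000, nu = 0.3, Fz = -100) {
  m <- block_model(n)
  fe <- fe_setup(m)
  f <- distribute_load(load_case("comp", force = c(0, 0, Fz)), fe)
  bot <- fe$bottom_nodes
  fixed <- 3 * bot  # z of all bottom nodes
  # pin rigid-body modes: x,y at one corner, y at another
  fixed <- c(fixed, 3 * bot[1] - 2, 3 * bot[1] - 1, 3 * bot[2] - 1)
  res <- solve_linear(fe, rep(E, fe$nelem), nu, f, fixed_dofs = fixed)
  list(fe = fe, res = res, area = (n * m$spacing)^2,
       sigma = Fz / (n * m$spacing)^2, E = E)
}
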