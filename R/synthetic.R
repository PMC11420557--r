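#' Specification of a synthetic functional-spinal-unit phantom
#'
#' Parameter set for the seeded phantom generator: two vertebra-like bodies
#' with a denser cortical shell and endplates, a correlated-random trabecular
#' core, an inter-body gap forming the implant design domain, and rigid
#' embedding slabs at the top and bottom of the grid (z superior).
#'
#' The default desk-scale grid is 48^3 voxels over a 43.2 mm cube
#' (0.9 mm spacing); other grid sizes keep the same physical geometry.
#'
#' @param grid_n Grid size per axis (voxels).
#' @param domain_mm Physical edge length of the cubic domain (mm).
#' @param radii_mm Elliptical vertebral-body cross-section semi-axes (x, y),
#'   mm.
#' @param gap_mm Nominal inter-body gap height (mm) at the periphery; the
#'   implant design domain.
#' @param dish_mm Endplate dishing depth (mm): spherical-cap concavity of
#'   both endplates, deepest at the body centre, so conforming and flat
#'   implant interfaces are geometrically distinguishable.
#' @param shell_mm Cortical shell / endplate thickness (mm).
#' @param shell_density_factor Cortical-to-trabecular density ratio (> 1).
#'   The trabecular core mean is lowered so that the *integral* vBMD of each
#'   vertebra (shell included) matches `trab_mean`.
#' @param trab_mean Target integral vBMD of each vertebra (g/cm^3); the
#'   cohort range of interest is roughly 0.15-0.54.
#' @param trab_cv Coefficient of variation of the trabecular density field.
#' @param corr_len_vox Correlation length of the trabecular noise (voxels).
#' @param slab_vox Rigid slab thickness (voxels) at top and bottom.
#' @param posterior_margin_vox Posterior (-y) dilation of the design-domain
#'   footprint beyond the vertebral ellipse (voxels).
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_n = 48, domain_mm = 43.2,
                         radii_mm = c(17, 13.5), gap_mm = 9,
                         dish_mm = 2.7, shell_mm = 1.0,
                         shell_density_factor = 2.0,
                         trab_mean = 0.25, trab_cv = 0.2,
                         corr_len_vox = 1.5, slab_vox = 3,
                         posterior_margin_vox = 1, seed = 1) {
  spacing <- domain_mm / grid_n
  gap_vox <- round(gap_mm / spacing)
  need <- 2 * slab_vox + gap_vox + 6  # at least 3 bone layers per vertebra
  if (grid_n < need) {
    stop(sprintf("grid too small: need >= %d layers in z, have %d",
                 need, grid_n), call. = FALSE)
  }
  if (any(radii_mm * 2 > domain_mm)) {
    stop("vertebra radii exceed the domain extent", call. = FALSE)
  }
  stopifnot(trab_mean >= 0, shell_density_factor > 1, gap_mm > 0)
  structure(list(grid_n = as.integer(grid_n), domain_mm = domain_mm,
                 spacing = spacing, radii_mm = radii_mm, gap_mm = gap_mm,
                 dish_mm = dish_mm, shell_mm = shell_mm,
                 shell_density_factor = shell_density_factor,
                 trab_mean = trab_mean,
                 trab_cv = trab_cv, corr_len_vox = corr_len_vox,
                 slab_vox = as.integer(slab_vox),
                 posterior_margin_vox = as.integer(posterior_margin_vox),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Periodic Gaussian smoothing of a 3-D array (FFT-based), unit variance out.
smooth_noise <- function(a, sd_vox) {
  d <- dim(a)
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    w <- exp(-x^2 / (2 * sd_vox^2))
    w / sum(w)
  }
  Kf <- outer(outer(fft(k1(d[1])), fft(k1(d[2]))), fft(k1(d[3])))
  sm <- Re(fft(fft(a) * array(Kf, d), inverse = TRUE)) / prod(d)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic functional-spinal-unit phantom
#'
#' Builds a [voxel_model()] from a [phantom_spec()]: rigid slabs at top and
#' bottom, two elliptical vertebral bodies partially embedded in the slabs,
#' concave (dished) endplates bounding the inter-body gap, a cortical shell
#' and endplates at elevated density, a correlated Gaussian random trabecular
#' density field (clipped at zero, rescaled to the requested mean), and the
#' gap (plus a small posterior margin) labelled as the implant design domain.
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_model()] with attributes `masks` (linear voxel indices of
#'   `lower_vertebra`, `upper_vertebra`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_n
  h <- spec$spacing
  lab <- array(LBL_VOID, dim = c(n, n, n))
  den <- array(0, dim = c(n, n, n))

  # normalised elliptical radius of every column centre
  cx <- (n + 1) / 2
  xs <- ((1:n) - cx) * h
  rn <- sqrt(outer((xs / spec$radii_mm[1])^2, (xs / spec$radii_mm[2])^2, `+`))
  inside <- rn <= 1

  zc <- (n + 1) / 2
  gap_half <- spec$gap_mm / 2 / h
  dish_vox <- spec$dish_mm / h
  # endplate surfaces per column (voxel z units, fractional)
  dish <- dish_vox * pmax(0, 1 - rn^2)
  z_bot <- zc - gap_half - dish   # top of lower vertebra
  z_top <- zc + gap_half + dish   # bottom of upper vertebra

  sl <- spec$slab_vox
  zidx <- slice.index(lab, 3)
  inside3 <- array(inside, dim = c(n, n, n))
  zb3 <- array(z_bot, dim = c(n, n, n))
  zt3 <- array(z_top, dim = c(n, n, n))
  lower <- inside3 & zidx <= zb3 & zidx > sl
  upper <- inside3 & zidx >= zt3 & zidx <= n - sl
  lab[lower | upper] <- LBL_BONE

  # design domain: gap between the endplates, plus posterior margin columns
  foot <- inside
  if (spec$posterior_margin_vox > 0) {
    for (s in seq_len(spec$posterior_margin_vox)) {
      foot[, 1:(n - s)] <- foot[, 1:(n - s)] | inside[, (1 + s):n]
    }
  }
  foot3 <- array(foot, dim = c(n, n, n))
  gap_lo <- ifelse(inside3, zb3, zc - gap_half)
  gap_hi <- ifelse(inside3, zt3, zc + gap_half)
  design <- foot3 & zidx > gap_lo & zidx < gap_hi & lab == LBL_VOID
  lab[design] <- LBL_DESIGN

  # rigid embedding slabs: potting blocks covering the vertebra footprint
  # (plus a 2-voxel rim), absorbing the embedded bone ends
  rn_emb <- sqrt(outer((xs / (spec$radii_mm[1] + 2 * h))^2,
                       (xs / (spec$radii_mm[2] + 2 * h))^2, `+`))
  emb3 <- array(rn_emb <= 1, dim = c(n, n, n))
  slabs <- emb3 & (zidx <= sl | zidx > n - sl)
  lab[slabs] <- LBL_RIGID
  den[slabs] <- 0

  # cortical shell: lateral rim + endplate layers
  shell_rn <- 1 - spec$shell_mm / mean(spec$radii_mm)
  rim3 <- array(rn >= shell_rn, dim = c(n, n, n))
  shell_vox <- spec$shell_mm / h
  plate <- (zidx > zb3 - shell_vox & zidx <= zb3) |
           (zidx < zt3 + shell_vox & zidx >= zt3)
  bone <- lab == LBL_BONE
  cortical <- bone & (rim3 | plate)

  # trabecular core: correlated Gaussian field, clipped, with the core mean
  # chosen so the integral vBMD (shell included) matches the target
  set.seed(spec$seed)
  noise <- smooth_noise(array(rnorm(n^3), dim = c(n, n, n)),
                        spec$corr_len_vox)
  trab <- bone & !cortical
  s_shell <- sum(cortical) / max(1, sum(bone))
  fac <- spec$shell_density_factor
  core_mean <- spec$trab_mean / (1 - s_shell + s_shell * fac)
  f <- core_mean * (1 + spec$trab_cv * noise)
  f <- pmax(f, 0.01)
  if (any(trab)) f <- f * (core_mean / mean(f[trab]))
  den[trab] <- f[trab]
  den[cortical] <- fac * core_mean

  model <- voxel_model(lab, den, spacing = h, origin = c(h, h, h) * 0)
  attr(model, "masks") <- list(lower_vertebra = which(lower & bone),
                               upper_vertebra = which(upper & bone))
  attr(model, "spec") <- spec
  model
}

#' Integral volumetric bone mineral density over a vertebra mask
#'
#' Mean calibrated apparent density over all voxels of the mask (including
#' endplates and cortical shell), in g/cm^3.
#'
#' @param model A [voxel_model()].
#' @param mask Linear voxel indices (e.g. from the phantom's `masks`
#'   attribute) or a logical array.
#' @return Scalar vBMD in g/cm^3.
#' @export
compute_vbmd <- function(model, mask) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("empty vertebra mask", call. = FALSE)
  mean(model$density[mask])
}

#' Synthetic patient descriptor
#' @param id Identifier.
#' @param weight Body weight (kg), > 0.
#' @param target_vbmd Target trabecular vBMD (g/cm^3) in \[0.05, 1\].
#' @param level Spinal level label.
#' @return A `patient` object.
#' @export
patient <- function(id, weight, target_vbmd, level = "L4-L5") {
  stopifnot(weight > 0, target_vbmd >= 0.05, target_vbmd <= 1.0)
  structure(list(id = id, weight = weight, target_vbmd = target_vbmd,
                 level = level), class = "patient")
}

#' Generate a synthetic patient cohort
#'
#' Deterministic, seeded cohort: trabecular vBMD targets spread uniformly
#' (and strictly increasing) across `vbmd_range`, body weights drawn
#' uniformly in `weight_range`, one phantom per patient.
#'
#' @param n Number of patients (>= 1; `n = 1` uses the range midpoints).
#' @param vbmd_range Trabecular density target range (g/cm^3).
#' @param weight_range Body weight range (kg).
#' @param seed Integer seed.
#' @param grid_n Phantom grid size (voxels per axis).
#' @param ... Further arguments to [phantom_spec()].
#' @return List of `n` elements, each `list(patient, model)`.
#' @export
generate_cohort <- function(n = 7, vbmd_range = c(0.15, 0.54),
                            weight_range = c(51, 100), seed = 1,
                            grid_n = 48, ...) {
  stopifnot(n >= 1, diff(range(vbmd_range)) >= 0, diff(range(weight_range)) >= 0)
  if (diff(range(vbmd_range)) == 0 && n > 1) {
    stop("empty vBMD range for n > 1", call. = FALSE)
  }
  targets <- if (n == 1) mean(vbmd_range) else
    seq(vbmd_range[1], vbmd_range[2], length.out = n)
  set.seed(seed)
  weights <- round(runif(n, weight_range[1], weight_range[2]), 1)
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(grid_n = grid_n, trab_mean = targets[i],
                       seed = seed + i, ...)
    list(patient = patient(id = i, weight = weights[i],
                           target_vbmd = targets[i]),
         model = generate_phantom(sp))
  })
}

#' Reference implant geometries for a phantom
#'
#' `conforming_implant` fills the entire design domain (an endplate-matched,
#' anatomically conforming spacer).  `flat_implant` fills only the flat
#' axial slab that fits inside the gap everywhere (a generic flat-faced
#' cage): it contacts the dished endplates only near the periphery, the
#' behaviour that drives endplate overloading for off-the-shelf cages.
#'
#' @param model A phantom [voxel_model()].
#' @return Logical 3-D array: solid implant voxels (subset of the design
#'   domain).
#' @export
conforming_implant <- function(model) {
  model$labels == LBL_DESIGN
}

#' @rdname conforming_implant
#' @export
flat_implant <- function(model) {
  d <- model$dims
  des <- model$labels == LBL_DESIGN
  bone <- model$labels == LBL_BONE
  zmid <- mean(which(apply(des, 3, any)))
  # flat slab limits from columns bounded by bone above and below, so the
  # slab rests on (at least) the peripheral endplate rim
  bone_below <- apply(bone & slice.index(bone, 3) < zmid, c(1, 2), any)
  bone_above <- apply(bone & slice.index(bone, 3) > zmid, c(1, 2), any)
  bounded <- bone_below & bone_above
  zmin <- suppressWarnings(apply(des, c(1, 2),
                                 function(v) if (any(v)) min(which(v))
                                 else NA))
  zmax <- suppressWarnings(apply(des, c(1, 2),
                                 function(v) if (any(v)) max(which(v))
                                 else NA))
  zlo <- max(zmin[bounded], na.rm = TRUE)
  zhi <- min(zmax[bounded], na.rm = TRUE)
  if (zlo > zhi) stop("no flat slab fits inside the gap", call. = FALSE)
  out <- array(FALSE, dim = d)
  zidx <- slice.index(out, 3)
  out[des & zidx >= zlo & zidx <= zhi] <- TRUE
  out
}

#' Insert a binarised implant design into a phantom
#'
#' Design-domain voxels with `design >= threshold` become implant voxels
#' (label `implant_design`, carried as the implant phase in the assessment);
#' the rest of the design domain becomes void.
#'
#' @param model A phantom [voxel_model()].
#' @param design Numeric or logical 3-D array over the grid (values in
#'   \[0, 1\]; only design-domain voxels are read).
#' @param threshold Binarisation threshold (default 0.5, the iso-surface
#'   threshold).
#' @return A new [voxel_model()].
#' @export
insert_design <- function(model, design, threshold = 0.5) {
  stopifnot(identical(dim(design), model$dims))
  lab <- model$labels
  des <- lab == LBL_DESIGN
  solid <- des & (design >= threshold)
  lab[des] <- LBL_VOID
  lab[solid] <- LBL_DESIGN
  out <- voxel_model(lab, model$density, spacing = model$spacing,
                     origin = model$origin)
  attr(out, "masks") <- attr(model, "masks")
  out
}

#' Voxels not connected to the rigid slabs
#'
#' Flood-fill over face-adjacent non-void voxels starting from the rigid
#' domain; returns linear indices of active voxels left unreached (floating
#' regions make the FE system singular).
#'
#' @param model A [voxel_model()].
#' @return Integer vector of unreachable active voxel indices (empty if the
#'   model is well-posed).
#' @export
floating_voxels <- function(model) {
  act <- model$labels != LBL_VOID
  reach <- model$labels == LBL_RIGID
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-dim(reach)[1], , ]
    grown[-dim(reach)[1], , ] <- grown[-dim(reach)[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -dim(reach)[2], ]
    grown[, -dim(reach)[2], ] <- grown[, -dim(reach)[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -dim(reach)[3]]
    grown[, , -dim(reach)[3]] <- grown[, , -dim(reach)[3]] | reach[, , -1]
    grown <- grown & act
    if (identical(grown, reach)) break
    reach <- grown
  }
  which(act & !reach)
}
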