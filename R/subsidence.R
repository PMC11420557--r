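#' Subsidence assessment configuration
#'
#' Parameters of the hyper-physiological follower-load assessment: a
#' compressive follower load of 310 N at the 51 kg reference body weight
#' (scaled linearly with patient weight), factor-of-fracture-risk strain
#' limits of +1.5% (tension) and -2.0% (compression), incremental load
#' application and a strain-driven secant iteration per increment.
#'
#' @param base_follower_load Follower load at the reference weight (N).
#' @param reference_weight Reference body weight (kg).
#' @param tensile_ffr_limit Tensile principal-strain limit (default 0.015).
#' @param compressive_ffr_limit Compressive limit (default -0.020).
#' @param load_increments Number of equal load increments.
#' @param max_newton_iters Secant iterations allowed per increment.
#' @param secant_tol Convergence tolerance on the secant factors.
#' @param relaxation Under-relaxation of the secant update in (0, 1\]; 1 is
#'   the plain fixed point, smaller values stabilise deep post-yield states.
#' @return An `assess_config` object.
#' @export
assess_config <- function(base_follower_load = 310, reference_weight = 51,
                          tensile_ffr_limit = 0.015,
                          compressive_ffr_limit = -0.020,
                          load_increments = 10, max_newton_iters = 100,
                          secant_tol = 1e-3, relaxation = 0.6) {
  stopifnot(base_follower_load > 0, tensile_ffr_limit > 0,
            compressive_ffr_limit < 0, load_increments >= 1)
  structure(as.list(environment()), class = "assess_config")
}

#' Body-weight-scaled follower load
#'
#' `FL = base * weight / reference`: 310 N at the 51 kg reference.
#'
#' @param patient_weight Body weight in kg (> 0).
#' @param cfg An [assess_config()].
#' @return Follower load magnitude in N (applied compressively along -z).
#' @export
follower_load <- function(patient_weight, cfg = assess_config()) {
  if (any(patient_weight <= 0)) stop("patient weight must be positive",
                                     call. = FALSE)
  cfg$base_follower_load * patient_weight / cfg$reference_weight
}

#' Factor of fracture risk from principal strains
#'
#' `FFR = max(eps_max / tensile_limit, eps_min / compressive_limit)` per
#' element; a value above 1 indicates mechanical overloading of the bone.
#'
#' @param eps_max,eps_min Maximum/minimum principal strains (vectorised).
#' @param cfg An [assess_config()] carrying the limits.
#' @return FFR values (dimensionless).
#' @export
ffr <- function(eps_max, eps_min, cfg = assess_config()) {
  pmax(eps_max / cfg$tensile_ffr_limit,
       eps_min / cfg$compressive_ffr_limit)
}

# Per-element secant factor given principal strains: the most softening
# branch over the principal directions (Poisson coupling kept elastic).
element_secant <- function(pr, constitutive) {
  pmin(secant_factor(constitutive, pr[, 1]),
       secant_factor(constitutive, pr[, 2]),
       secant_factor(constitutive, pr[, 3]))
}

implant_secant <- function(pr, mat) {
  amax <- pmax(abs(pr[, 1]), abs(pr[, 3]))
  ifelse(amax > mat$yield_strain, mat$yield_strain / amax, 1)
}

#' In-silico subsidence risk assessment
#'
#' Applies the body-weight-scaled compressive follower load to the top of
#' the model (transmitted through the rigid embedding to the superior
#' endplate of the superior vertebra) in equal increments, solving each
#' increment quasi-statically with a strain-driven secant-stiffness
#' iteration: bone follows the bilinear tension-compression-asymmetric law
#' per principal direction, the implant is elastic-perfectly-plastic.  The
#' factor of fracture risk is evaluated per bone element from the converged
#' principal strains.  Below yield the result coincides with a single
#' linear solve.
#'
#' @param model A [voxel_model()] with the binarised implant inserted (see
#'   [insert_design()]); implant-labelled voxels are the implant phase.
#' @param mat An [implant_material()].
#' @param constitutive A [bone_constitutive()].
#' @param patient_weight Body weight in kg.
#' @param cfg An [assess_config()].
#' @param law A [density_law()] mapping bone density to modulus (floored).
#' @return An `ffr_field`: list with `ffr` (per bone element), `max_ffr`,
#'   `overloaded_volume` (mm^3), `eps_max`/`eps_min`, `bone_lin` (voxel
#'   indices), `follower_load` (N), `implant_failure` flag, `fe`.
#' @export
assess <- function(model, mat, constitutive = bone_constitutive(),
                   patient_weight = 51, cfg = assess_config(),
                   law = density_law()) {
  fe <- fe_setup(model)
  bone <- which(fe$elem_label == LBL_BONE)
  imp <- which(fe$elem_label == LBL_DESIGN)
  if (length(bone) == 0) stop("model has no bone domain", call. = FALSE)
  E0 <- numeric(fe$nelem)
  E0[bone] <- modulus_from_density(law, fe$elem_density[bone], floor = TRUE,
                                   floor_value = constitutive$modulus_floor)
  E0[imp] <- mat$E
  rigid <- which(fe$elem_label == LBL_RIGID)
  E0[rigid] <- 1000 * max(E0)
  nu <- rep(constitutive$poisson, fe$nelem)
  nu[imp] <- mat$poisson
  FL <- follower_load(patient_weight, cfg)
  f_full <- distribute_load(load_case("follower", force = c(0, 0, -FL)), fe)

  s <- rep(1, fe$nelem)  # secant factors
  E_assembled <- NULL
  ch <- NULL
  template <- NULL
  u <- NULL
  for (inc in seq_len(cfg$load_increments)) {
    f <- f_full * (inc / cfg$load_increments)
    converged <- FALSE
    for (it in seq_len(cfg$max_newton_iters)) {
      E_eff <- E0 * s
      if (is.null(E_assembled) ||
          max(abs(E_eff - E_assembled) / E0) > 1e-12) {
        K <- assemble_K(fe, E_eff, nu)
        ch <- fe_factor(fe, K, template = template)
        if (is.null(template)) template <- ch
        E_assembled <- E_eff
      }
      u <- fe_displacement(fe, ch, f)[, 1]
      str <- fe_strains(fe, u)
      pr_bone <- principal_strains(str[bone, , drop = FALSE])
      s_new <- s
      s_new[bone] <- element_secant(pr_bone, constitutive)
      if (length(imp)) {
        pr_imp <- principal_strains(str[imp, , drop = FALSE])
        s_new[imp] <- implant_secant(pr_imp, mat)
      }
      delta <- max(abs(s_new - s))
      if (delta < cfg$secant_tol) { s <- s_new; converged <- TRUE; break }
      s <- s + cfg$relaxation * (s_new - s)
    }
    gc(FALSE)  # stale stiffness factors are large; collect per increment
    if (!converged) {
      stop(sprintf(paste0("assessment did not converge at load fraction ",
                          "%.2f (last converged %.2f): interpreted as ",
                          "collapse onset"),
                   inc / cfg$load_increments,
                   (inc - 1) / cfg$load_increments), call. = FALSE)
    }
  }
  str <- fe_strains(fe, u)
  pr_bone <- principal_strains(str[bone, , drop = FALSE])
  f_el <- ffr(pr_bone[, 1], pr_bone[, 3], cfg)
  implant_failure <- FALSE
  if (length(imp)) {
    pr_imp <- principal_strains(str[imp, , drop = FALSE])
    implant_failure <- any(pmax(abs(pr_imp[, 1]), abs(pr_imp[, 3])) >
                             mat$ultimate_strain)
  }
  structure(list(ffr = f_el, max_ffr = max(f_el),
                 overloaded_volume = sum(f_el > 1) * fe$h^3,
                 eps_max = pr_bone[, 1], eps_min = pr_bone[, 3],
                 bone_lin = fe$elem_lin[bone],
                 follower_load = FL, implant_failure = implant_failure,
                 cfg = cfg, h = fe$h, dims = fe$dims),
            class = "ffr_field")
}

#' @exportS3Method base::print
print.ffr_field <- function(x, ...) {
  cat(sprintf(paste0("<ffr_field> max FFR %.3f, overloaded volume ",
                     "%.2f mm^3, FL %.1f N%s\n"),
              x$max_ffr, x$overloaded_volume, x$follower_load,
              if (x$implant_failure) " [implant ultimate strain exceeded]"
              else ""))
  invisible(x)
}

#' Overloaded bone volume
#'
#' Volume (mm^3) of bone elements whose factor of fracture risk exceeds 1.
#'
#' @param field An `ffr_field` from [assess()].
#' @param threshold Overload threshold (default 1).
#' @return Volume in mm^3.
#' @export
overloaded_volume <- function(field, threshold = 1) {
  stopifnot(inherits(field, "ffr_field"))
  sum(field$ffr > threshold) * field$h^3
}

#' Embed the FFR field into the full voxel grid
#' @param field An `ffr_field`.
#' @return 3-D array (NA outside bone).
#' @export
ffr_field_array <- function(field) {
  a <- array(NA_real_, dim = field$dims)
  a[field$bone_lin] <- field$ffr
  a
}
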