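#' Density-to-modulus laws for vertebral bone
#'
#' QCT-calibrated apparent density is mapped to an isotropic Young's modulus
#' through one of three published empirical relationships.  The baseline is
#' the Ouyang power law `E = 2383 * rho^1.88`; the alternatives used in the
#' density-law sensitivity study are the Keller relationship, read here as the
#' linear map `E = 2100 * rho - 80` (the printed form is typographically
#' ambiguous between a linear and a negative-exponent power law; the linear
#' reading is adopted and negative values are removed by the modulus floor),
#' and the Morgan power law `E = 4730 * rho^1.56`.  Densities are apparent
#' densities in g/cm^3 and moduli are in MPa throughout.
#'
#' @param law_id One of `"ouyang_baseline"` (default), `"keller"`, `"morgan"`.
#' @return An object of class `density_law` with elements `law_id`, `type`
#'   (`"power"` or `"linear"`) and the law parameters.
#' @examples
#' modulus_from_density(density_law("ouyang_baseline"), 1.0)  # 2383
#' modulus_from_density(density_law("morgan"), 1.0)           # 4730
#' @export
density_law <- function(law_id = c("ouyang_baseline", "keller", "morgan")) {
  law_id <- match.arg(law_id)
  law <- switch(law_id,
    ouyang_baseline = list(type = "power",  coef = 2383, exponent = 1.88),
    keller          = list(type = "linear", slope = 2100, intercept = -80),
    morgan          = list(type = "power",  coef = 4730, exponent = 1.56))
  structure(c(list(law_id = law_id), law), class = "density_law")
}

#' @exportS3Method base::print
print.density_law <- function(x, ...) {
  form <- if (x$type == "power") {
    sprintf("E = %g * rho^%g MPa", x$coef, x$exponent)
  } else {
    sprintf("E = %g * rho %+g MPa", x$slope, x$intercept)
  }
  cat("<density_law> ", x$law_id, ": ", form, "\n", sep = "")
  invisible(x)
}

#' Evaluate a density-to-modulus law
#'
#' @param law A [density_law()] object (or a law id string).
#' @param rho Apparent density in g/cm^3; vectorised, must be non-negative.
#' @param floor If `TRUE`, clamp the result up to `floor_value` (the bone
#'   modulus floor, applied after whichever law is selected).
#' @param floor_value Modulus floor in MPa (default 25).
#' @return Young's modulus in MPa, same length as `rho`.
#' @export
modulus_from_density <- function(law, rho, floor = FALSE, floor_value = 25) {
  if (is.character(law)) law <- density_law(law)
  if (!inherits(law, "density_law")) {
    stop("`law` must be a density_law object or law id", call. = FALSE)
  }
  if (any(rho < 0)) stop("density must be non-negative", call. = FALSE)
  E <- if (law$type == "power") {
    law$coef * rho^law$exponent
  } else {
    law$slope * rho + law$intercept
  }
  if (floor) E <- pmax(E, floor_value)
  E
}

#' Solid implant materials
#'
#' Elastic and failure parameters of the two implant materials considered:
#' titanium (E = 110 GPa, nu = 0.3, yield strain 0.7%, ultimate strain 10%)
#' and PEEK (E = 3 GPa, nu = 0.43, yield strain 1.3%, ultimate strain 45%).
#' In the subsidence assessment the implant is treated as elastic up to the
#' yield strain and perfectly plastic beyond, with a failure flag at the
#' ultimate strain.
#'
#' @param name `"titanium"` or `"peek"` (case-insensitive; `"ti"` accepted).
#' @return An `implant_material` object with `name`, `E` (MPa), `poisson`,
#'   `yield_strain`, `ultimate_strain`.
#' @export
implant_material <- function(name = c("titanium", "peek", "ti")) {
  name <- match.arg(tolower(name), c("titanium", "peek", "ti"))
  if (name == "ti") name <- "titanium"
  m <- switch(name,
    titanium = list(name = "titanium", E = 110000, poisson = 0.30,
                    yield_strain = 0.007, ultimate_strain = 0.10),
    peek     = list(name = "peek",     E = 3000,   poisson = 0.43,
                    yield_strain = 0.013, ultimate_strain = 0.45))
  structure(m, class = "implant_material")
}

#' Penalised (SIMP) stiffness interpolation
#'
#' Maps a physical design variable in \[0, 1\] to an element Young's modulus
#' `E_min + xphys^penalty * (E - E_min)`.  The small positive `E_min` keeps
#' the global stiffness matrix non-singular in void regions.
#'
#' @param xphys Physical (projected) design variable(s) in \[0, 1\].
#' @param mat An [implant_material()] (or a scalar solid modulus in MPa).
#' @param penalty Penalisation exponent, >= 1 (default 3).
#' @param E_min Void stiffness in MPa (default `1e-6 * E`).
#' @return Interpolated modulus in MPa, monotone increasing in `xphys`.
#' @export
simp_modulus <- function(xphys, mat, penalty = 3, E_min = NULL) {
  E <- if (inherits(mat, "implant_material")) mat$E else as.numeric(mat)
  if (is.null(E_min)) E_min <- 1e-6 * E
  if (any(xphys < -1e-12 | xphys > 1 + 1e-12)) {
    stop("design variable outside [0, 1]", call. = FALSE)
  }
  if (penalty < 1) stop("penalty must be >= 1", call. = FALSE)
  xphys <- pmin(pmax(xphys, 0), 1)
  E_min + xphys^penalty * (E - E_min)
}

#' Bone constitutive model (bilinear, tension-compression asymmetric)
#'
#' Uniaxial bilinear elasto-plastic response for bone: elastic slope `E` up to
#' the yield strains, post-yield slope `0.05 * E`.  Yield strains are +0.73%
#' in tension and -1.04% in compression (asymmetric mode).  Two variant modes
#' support the constitutive-model sensitivity study: `"linear"` (elastic at
#' all strains) and `"elastoplastic_symmetric"` (both yields at the tensile
#' magnitude).
#'
#' @param mode `"elastoplastic_asymmetric"` (default), `"linear"`, or
#'   `"elastoplastic_symmetric"`.
#' @param tensile_yield_strain,compressive_yield_strain Yield strains
#'   (dimensionless); defaults 0.0073 and -0.0104.
#' @param post_yield_modulus_fraction Post-yield tangent as a fraction of the
#'   elastic modulus (default 0.05).
#' @param poisson Poisson's ratio (default 0.3).
#' @param modulus_floor Minimum bone Young's modulus in MPa (default 25).
#' @return A `bone_constitutive` object.
#' @export
bone_constitutive <- function(mode = c("elastoplastic_asymmetric", "linear",
                                       "elastoplastic_symmetric"),
                              tensile_yield_strain = 0.0073,
                              compressive_yield_strain = -0.0104,
                              post_yield_modulus_fraction = 0.05,
                              poisson = 0.3,
                              modulus_floor = 25) {
  mode <- match.arg(mode)
  stopifnot(tensile_yield_strain > 0, compressive_yield_strain < 0,
            post_yield_modulus_fraction > 0, post_yield_modulus_fraction < 1)
  structure(list(mode = mode,
                 tensile_yield_strain = tensile_yield_strain,
                 compressive_yield_strain = compressive_yield_strain,
                 post_yield_modulus_fraction = post_yield_modulus_fraction,
                 poisson = poisson,
                 modulus_floor = modulus_floor),
            class = "bone_constitutive")
}

#' Uniaxial bone stress from strain
#'
#' Evaluates the bilinear uniaxial law of a [bone_constitutive()] model:
#' stress `E * eps` inside the yield interval, continued with slope
#' `0.05 * E` beyond either yield strain.  `linear` mode returns `E * eps`
#' at all strains.
#'
#' @param constitutive A [bone_constitutive()] object.
#' @param E Elastic Young's modulus in MPa (scalar or vector).
#' @param strain Uniaxial strain(s), dimensionless.
#' @return Stress in MPa (vectorised over `strain`/`E`).
#' @export
bone_stress <- function(constitutive, E, strain) {
  stopifnot(inherits(constitutive, "bone_constitutive"), all(E > 0))
  if (constitutive$mode == "linear") return(E * strain)
  eyT <- constitutive$tensile_yield_strain
  eyC <- if (constitutive$mode == "elastoplastic_symmetric") -eyT else
    constitutive$compressive_yield_strain
  Ep <- constitutive$post_yield_modulus_fraction * E
  s <- E * strain
  above <- strain > eyT
  below <- strain < eyC
  s[above] <- (E * eyT + Ep * (strain - eyT))[above]
  s[below] <- (E * eyC + Ep * (strain - eyC))[below]
  s
}

#' Secant modulus factor of the bone law
#'
#' Ratio `sigma(eps) / (E * eps)` of the bilinear law; equals 1 inside the
#' yield interval and decreases monotonically beyond.  Used by the
#' strain-driven secant iteration of the subsidence assessment.
#'
#' @inheritParams bone_stress
#' @return Dimensionless factor in (0, 1].
#' @keywords internal
secant_factor <- function(constitutive, strain) {
  if (constitutive$mode == "linear") return(rep(1, length(strain)))
  s <- bone_stress(constitutive, 1, strain)  # stress at unit modulus
  f <- ifelse(abs(strain) < 1e-300, 1, s / strain)
  pmin(f, 1)
}
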