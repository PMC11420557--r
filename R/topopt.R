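#' Topology optimisation configuration
#'
#' Parameters of the robust three-field compliance minimisation.  Defaults
#' follow the porous-infill formulation: local volume fraction 0.35 over a
#' 3.5-element neighbourhood aggregated with a p-mean of 16, bone maximum
#' principal strain limited to 0.73% (aggregated with exponent
#' `strain_agg_exponent`), tanh projection at thresholds (0.7, 0.5, 0.3) for
#' the eroded/nominal/dilated designs, and a converged design required to
#' reach a discreteness measure below 3%.
#'
#' @param local_volume_fraction Upper bound on neighbourhood solid fraction.
#' @param local_radius Local-volume neighbourhood radius (element edges).
#' @param pmean_penalty p-mean exponent of the local volume constraint.
#' @param strain_limit Bone maximum-principal-strain limit (dimensionless).
#' @param strain_agg_exponent p-mean exponent aggregating normalised bone
#'   strains.
#' @param density_filter_radius Density-filter radius (element edges).
#' @param beta_schedule Increasing projection sharpness values.
#' @param beta_every Iterations between sharpness increments.
#' @param eta Projection thresholds `(eroded, nominal, dilated)`, decreasing.
#' @param max_iters Iteration cap.
#' @param move_limit MMA move limit per iteration.
#' @param discreteness_target Convergence bar on the nominal design (%).
#' @param simp_penalty SIMP penalisation exponent.
#' @param tol Constraint feasibility tolerance at convergence.
#' @param min_strain_constraint Also constrain the (compressive) minimum
#'   principal strain (off by default: it is inactive because endplate load
#'   transfer is shear-dominated and the tensile limit is reached first).
#' @return A `topopt_config` object.
#' @export
topopt_config <- function(local_volume_fraction = 0.35,
                          local_radius = 3.5,
                          pmean_penalty = 16,
                          strain_limit = 0.0073,
                          strain_agg_exponent = 8,
                          density_filter_radius = 2.5,
                          beta_schedule = c(2, 8, 32),
                          beta_every = 20,
                          eta = c(eroded = 0.7, nominal = 0.5,
                                  dilated = 0.3),
                          max_iters = 80,
                          move_limit = 0.2,
                          discreteness_target = 3,
                          simp_penalty = 3,
                          tol = 1e-3,
                          min_strain_constraint = FALSE) {
  stopifnot(local_volume_fraction > 0, local_volume_fraction < 1,
            pmean_penalty >= 1, strain_agg_exponent >= 1,
            eta[1] > eta[2], eta[2] > eta[3],
            all(diff(beta_schedule) > 0))
  structure(as.list(environment()), class = "topopt_config")
}

#' Assemble a reusable topology-optimisation problem
#'
#' Precomputes the FE discretisation, load vectors for all cases, filter
#' matrices, element matrices and the static (bone + rigid) part of the
#' stiffness matrix, returning a problem object whose [evaluate_topopt()]
#' computes objective, constraints and gradients for a design vector.
#'
#' @param model A phantom [voxel_model()] with a nonempty implant design
#'   domain and bone domain.
#' @param loads A [reference_load_set()] (first case must be the axial
#'   compression case, used by the strain constraint).
#' @param mat An [implant_material()].
#' @param cfg A [topopt_config()].
#' @param law A [density_law()] for bone moduli (floored at 25 MPa).
#' @param constitutive A [bone_constitutive()] (Poisson ratio and floor).
#' @return A `topopt_problem` environment.
#' @export
make_topopt_problem <- function(model, loads, mat, cfg = topopt_config(),
                                law = density_law(),
                                constitutive = bone_constitutive()) {
  fe <- fe_setup(model)
  des <- which(fe$elem_label == LBL_DESIGN)
  bone <- which(fe$elem_label == LBL_BONE)
  if (length(des) == 0) stop("model has no implant design domain",
                             call. = FALSE)
  if (length(bone) == 0) stop("model has no bone domain", call. = FALSE)
  p <- new.env(parent = emptyenv())
  p$fe <- fe; p$des <- des; p$bone <- bone
  p$cfg <- cfg; p$mat <- mat; p$loads <- loads
  p$ndes <- length(des)
  # element moduli of the static phases
  E_bone <- modulus_from_density(law, fe$elem_density[bone], floor = TRUE,
                                 floor_value = constitutive$modulus_floor)
  p$E_bone <- E_bone
  p$E_rigid <- 1000 * max(E_bone, mat$E)
  p$nu_bone <- constitutive$poisson
  Evec <- rep(1, fe$nelem)
  Evec[bone] <- E_bone
  Evec[fe$elem_label == LBL_RIGID] <- p$E_rigid
  nu_all <- ifelse(fe$elem_label == LBL_RIGID, 0.3, p$nu_bone)
  nu_all[des] <- mat$poisson
  # sparsity pattern of the reduced system (upper triangle, permuted free
  # dofs); per-iteration updates write the value slot of this matrix in
  # place, so no sparse matrix is ever rebuilt inside the loop
  Kpat <- assemble_K(fe, Evec, nu_all)
  fp <- fe$free_perm
  p$Kff <- Matrix::forceSymmetric(Kpat[fp, fp], uplo = "U")
  nf <- length(fp)
  pat_cols <- rep(seq_len(nf), diff(p$Kff@p))
  pat_keys <- (pat_cols - 1) * nf + (p$Kff@i + 1)
  pos <- integer(fe$ndof)
  pos[fp] <- seq_len(nf)
  # map element triplets (upper half only) to CSC value slots
  ii <- rep(1:24, times = 24); jj <- rep(1:24, each = 24)
  slot_map <- function(elems) {
    ti <- pos[as.vector(fe$edofs[elems, ii, drop = FALSE])]
    tj <- pos[as.vector(fe$edofs[elems, jj, drop = FALSE])]
    keep <- which(ti > 0 & tj > 0 & ti <= tj)
    key <- (tj[keep] - 1) * nf + ti[keep]
    slot <- match(key, pat_keys)
    o <- order(slot)
    keep <- keep[o]; slot <- slot[o]
    grp_end <- c(which(diff(slot) > 0), length(slot))
    list(keep = keep, target = slot[grp_end],
         grp = rep.int(seq_along(grp_end),
                       diff(c(0L, grp_end))))
  }
  # static (bone + rigid) contribution accumulated once
  p$xstat <- numeric(length(p$Kff@x))
  for (nuv in unique(nu_all[-des])) {
    el <- setdiff(which(nu_all == nuv), des)
    if (!length(el)) next
    sm <- slot_map(el)
    kev <- as.vector(element_stiffness(1, nuv, fe$h))
    vals <- as.vector(outer(Evec[el], kev))[sm$keep]
    p$xstat[sm$target] <- p$xstat[sm$target] +
      as.numeric(rowsum(vals, sm$grp))
  }
  # implant element matrix (unit modulus) and design slot map
  p$Ke_imp <- element_stiffness(1, mat$poisson, fe$h)
  p$kev <- as.vector(p$Ke_imp)
  p$des_slots <- slot_map(des)
  # filters over the design domain
  p$des_lin <- fe$elem_lin[des]
  p$H  <- neighbourhood_matrix(p$des_lin, fe$dims,
                               cfg$density_filter_radius, "cone")
  p$Hlv <- neighbourhood_matrix(p$des_lin, fe$dims, cfg$local_radius,
                                "uniform")
  p$F <- distribute_load_set(loads, fe)
  p$comp_case <- 1L
  p$Emin <- 1e-6 * mat$E
  p$chol_template <- NULL
  p$c_scale <- NA_real_
  class(p) <- c("topopt_problem", "environment")
  p
}

# Factorise the system for a vector of design-element moduli, updating the
# preassembled pattern's value slot in place.
factor_design <- function(p, E_des) {
  sm <- p$des_slots
  vals <- as.vector(outer(E_des, p$kev))[sm$keep]
  x <- p$xstat
  x[sm$target] <- x[sm$target] + as.numeric(rowsum(vals, sm$grp))
  p$Kff@x <- x
  if (is.null(p$chol_template)) {
    p$chol_template <- Matrix::Cholesky(p$Kff, LDL = FALSE, super = TRUE,
                                        perm = FALSE)
    update(p$chol_template, p$Kff)
  } else {
    update(p$chol_template, p$Kff)
  }
}

#' p-mean aggregation of normalised bone strains
#'
#' `g = (mean_i (eps_i / limit)^P)^(1/P) - 1`, the aggregated maximum
#' principal strain constraint over the bone domain: `g <= 0` bounds the
#' p-mean of normalised strains by the limit.
#'
#' @param eps_max Per-bone-element maximum principal strains.
#' @param limit Strain limit (default 0.0073).
#' @param exponent Aggregation exponent P.
#' @return Scalar `g` with attribute `weights` = dg/d(eps_max).
#' @export
strain_aggregate <- function(eps_max, limit = 0.0073, exponent = 8) {
  if (length(eps_max) == 0) stop("empty bone domain", call. = FALSE)
  t <- eps_max / limit
  pm <- mean(t^exponent)^(1 / exponent)
  w <- pm^(1 - exponent) * t^(exponent - 1) / (length(t) * limit)
  structure(pm - 1, weights = w)
}

#' Local volume constraint (p-mean-aggregated neighbourhood solid fraction)
#'
#' Per-voxel neighbourhood solid-fraction averages of the dilated design,
#' aggregated with a p-mean and normalised by the allowed fraction:
#' `v = pmean(rho_bar) / fraction - 1 <= 0` produces porous infill.
#'
#' @param x_dilated Dilated design values over the design domain (vector
#'   over `mask`, or 3-D array).
#' @param mask Design-domain voxels (linear indices or logical array); not
#'   needed when `H` is supplied.
#' @param dims Grid dims (when `mask` is indices).
#' @param radius Neighbourhood radius in element edges (default 3.5).
#' @param fraction Local volume fraction bound (default 0.35).
#' @param pmean Aggregation exponent (default 16).
#' @param H Optional precomputed uniform neighbourhood matrix.
#' @return Scalar `v` with attributes `grad` (dv/dx_dilated) and `pmean`
#'   (the aggregated neighbourhood fraction itself).
#' @export
local_volume_constraint <- function(x_dilated, mask = NULL, dims = NULL,
                                    radius = 3.5, fraction = 0.35,
                                    pmean = 16, H = NULL) {
  if (is.null(H)) {
    if (is.logical(mask)) { dims <- dim(mask); mask <- which(mask) }
    if (is.array(x_dilated)) { dims <- dim(x_dilated)
                               x_dilated <- x_dilated[mask] }
    H <- neighbourhood_matrix(mask, dims, radius, "uniform")
  }
  rb <- as.numeric(H %*% x_dilated)
  n <- length(rb)
  pm <- mean(rb^pmean)^(1 / pmean)
  drb <- pm^(1 - pmean) * rb^(pmean - 1) / n
  grad <- as.numeric(Matrix::crossprod(H, drb)) / fraction
  structure(pm / fraction - 1, grad = grad, pmean = pm)
}

#' Evaluate objective, constraints and gradients for a design vector
#'
#' Computes the three projected fields, solves all load cases on the eroded
#' design and the compression case on the dilated design, and returns the
#' multi-case compliance objective, the aggregated bone strain constraint
#' `g1`, the local volume constraint `v`, and their gradients with respect
#' to the raw design variables (chained through projection and filter).
#'
#' @param p A [make_topopt_problem()] object.
#' @param x Raw design vector over the design domain, values in \[0, 1\].
#' @param beta Projection sharpness.
#' @param gradients If `FALSE`, skip adjoint/gradient computation.
#' @return List with `compliance`, `dc`, `g1`, `dg1`, `v`, `dv`, `fields`
#'   (xt and the three projections), `discreteness` (of the nominal field),
#'   and `strain_pmean_pct` (aggregated bone strain as % strain).
#' @export
evaluate_topopt <- function(p, x, beta, gradients = TRUE) {
  cfg <- p$cfg
  xt <- as.numeric(p$H %*% x)
  xe <- heaviside_project(xt, beta, cfg$eta[[1]])
  xn <- heaviside_project(xt, beta, cfg$eta[[2]])
  xd <- heaviside_project(xt, beta, cfg$eta[[3]])
  pen <- cfg$simp_penalty
  Ee <- simp_modulus(xe, p$mat, pen, p$Emin)
  Ed <- simp_modulus(xd, p$mat, pen, p$Emin)

  # eroded solves (all cases) -> compliance
  ch_e <- factor_design(p, Ee)
  U <- fe_displacement(p$fe, ch_e, p$F)
  compliance <- sum(colSums(p$F * U))

  # dilated solve (compression case) -> strain constraint
  ch_d <- factor_design(p, Ed)
  uc <- fe_displacement(p$fe, ch_d, p$F[, p$comp_case, drop = FALSE])[, 1]
  sb <- fe_strains(p$fe, uc)[p$bone, , drop = FALSE]
  pr <- principal_strains(sb, directions = TRUE)
  eps_use <- pr[, 1]
  if (isTRUE(cfg$min_strain_constraint)) {
    # optional research flag: fold the compressive limit into the same
    # aggregate via the FFR-style normalisation
    eps_use <- pmax(pr[, 1], pr[, 3] * (cfg$strain_limit / -0.0104))
  }
  g1s <- strain_aggregate(eps_use, cfg$strain_limit, cfg$strain_agg_exponent)
  g1 <- as.numeric(g1s)

  # local volume on the dilated design
  vs <- local_volume_constraint(xd, H = p$Hlv,
                                fraction = cfg$local_volume_fraction,
                                pmean = cfg$pmean_penalty)
  v <- as.numeric(vs)

  out <- list(compliance = compliance, g1 = g1, v = v,
              strain_pmean_pct = (g1 + 1) * cfg$strain_limit * 100,
              local_volume_pmean = attr(vs, "pmean"),
              discreteness = discreteness(xn),
              fields = list(xt = xt, eroded = xe, nominal = xn,
                            dilated = xd))
  if (!gradients) return(out)

  dE_e <- pen * xe^(pen - 1) * (p$mat$E - p$Emin)
  dE_d <- pen * xd^(pen - 1) * (p$mat$E - p$Emin)
  Ue <- array(0, dim = c(p$ndes, 24))
  dc_dxe <- numeric(p$ndes)
  edes <- p$fe$edofs[p$des, , drop = FALSE]
  for (k in seq_len(ncol(U))) {
    Uk <- matrix(U[edes, k], ncol = 24)
    dc_dxe <- dc_dxe - rowSums((Uk %*% p$Ke_imp) * Uk) * dE_e
  }

  # adjoint of the strain constraint (dilated system)
  w <- attr(g1s, "weights")
  nd <- attr(pr, "max_dir")
  mvec <- cbind(nd[, 1]^2, nd[, 2]^2, nd[, 3]^2,
                nd[, 1] * nd[, 2], nd[, 2] * nd[, 3], nd[, 1] * nd[, 3])
  if (isTRUE(cfg$min_strain_constraint)) {
    # where the compressive branch governs, differentiate through eps_min
    use_min <- eps_use > pr[, 1]
    if (any(use_min)) {
      prm <- principal_strains(-sb[use_min, , drop = FALSE],
                               directions = TRUE)
      ndm <- attr(prm, "max_dir")
      scl <- cfg$strain_limit / -0.0104
      mvec[use_min, ] <- -scl * cbind(ndm[, 1]^2, ndm[, 2]^2, ndm[, 3]^2,
                                      ndm[, 1] * ndm[, 2],
                                      ndm[, 2] * ndm[, 3],
                                      ndm[, 1] * ndm[, 3])
    }
  }
  contrib <- (w * mvec) %*% p$fe$B0  # nbone x 24
  rhs <- numeric(p$fe$ndof)
  ebone <- p$fe$edofs[p$bone, , drop = FALSE]
  acc <- rowsum(as.vector(contrib), as.vector(ebone))
  rhs[as.integer(rownames(acc))] <- acc[, 1]
  lam <- fe_displacement(p$fe, ch_d, rhs)[, 1]
  Le <- matrix(lam[edes], ncol = 24)
  Uc <- matrix(uc[edes], ncol = 24)
  dg1_dxd <- -rowSums((Le %*% p$Ke_imp) * Uc) * dE_d

  dv_dxd <- attr(vs, "grad")

  dproj <- function(eta) heaviside_project(xt, beta, eta, deriv = TRUE)
  chain <- function(g_phys, eta) {
    as.numeric(Matrix::crossprod(p$H, g_phys * dproj(eta)))
  }
  out$dc <- chain(dc_dxe, cfg$eta[[1]])
  out$dg1 <- chain(dg1_dxd, cfg$eta[[3]])
  out$dv <- chain(dv_dxd, cfg$eta[[3]])
  out
}

#' Robust topology optimisation of the implant design domain
#'
#' MMA-driven loop minimising the summed compliance of all load cases
#' (evaluated on the eroded design) subject to the aggregated bone
#' maximum-principal-strain constraint and the local volume constraint (both
#' evaluated on the dilated design), with projection-sharpness (beta)
#' continuation.  Terminates when, at the final sharpness, the design change
#' stagnates and the constraints and the discreteness bar are met, or at
#' `max_iters`.
#'
#' @inheritParams make_topopt_problem
#' @param seed Integer seed (the algorithm is deterministic; the seed is
#'   recorded and seeds the deterministic initial design perturbation, zero
#'   by default).
#' @param verbose Print a one-line summary per iteration.
#' @return A `design_field` object: raw/filtered/projected fields (vectors
#'   over the design domain plus full 3-D arrays via
#'   [design_field_array()]), per-iteration `history` data frame, the final
#'   constraint values and convergence flag.
#' @export
optimize_cage <- function(model, loads, mat, cfg = topopt_config(),
                          law = density_law(),
                          constitutive = bone_constitutive(),
                          seed = 1, verbose = FALSE) {
  p <- make_topopt_problem(model, loads, mat, cfg, law, constitutive)
  n <- p$ndes
  x <- rep(cfg$local_volume_fraction, n)
  xold1 <- x; xold2 <- x
  low <- rep(0, n); upp <- rep(1, n)
  hist <- vector("list", cfg$max_iters)
  nb <- length(cfg$beta_schedule)
  converged <- FALSE
  ev <- NULL
  ok_run <- 0L
  c_prev <- NA_real_
  for (iter in seq_len(cfg$max_iters)) {
    bi <- min(nb, 1 + (iter - 1) %/% cfg$beta_every)
    beta <- cfg$beta_schedule[bi]
    ev <- evaluate_topopt(p, x, beta)
    if (iter == 1) {
      if (ev$g1 > 0) {
        evs <- evaluate_topopt(p, rep(1, n), beta, gradients = FALSE)
        if (evs$g1 > 0) {
          stop(sprintf(paste0("infeasible: strain constraint violated even ",
                              "at full solid (g1 = %.3g)"), evs$g1),
               call. = FALSE)
        }
      }
      p$c_scale <- abs(ev$compliance)
    }
    f0 <- ev$compliance / p$c_scale
    df0 <- ev$dc / p$c_scale
    fval <- c(ev$g1, ev$v)
    dfdx <- rbind(ev$dg1, ev$dv)
    upd <- mma_update(iter, x, rep(0, n), rep(1, n), xold1, xold2,
                      f0, df0, fval, dfdx, low, upp,
                      move = cfg$move_limit)
    xold2 <- xold1; xold1 <- x
    change <- max(abs(upd$x - x))
    x <- upd$x
    low <- upd$low; upp <- upd$upp
    # factor objects are large external allocations: collect eagerly so
    # long runs keep a bounded footprint
    gc(FALSE)
    hist[[iter]] <- data.frame(iter = iter, beta = beta,
                               compliance = ev$compliance, g1 = ev$g1,
                               v = ev$v, discreteness = ev$discreteness,
                               change = change)
    if (verbose) {
      message(sprintf(
        "it %3d beta %4.3g c %.4e g1 %+ .3e v %+ .3e Mnd %5.2f%% ch %.3f",
        iter, beta, ev$compliance, ev$g1, ev$v, ev$discreteness, change))
    }
    at_final <- bi == nb && iter > (nb - 1) * cfg$beta_every + 3
    feasible <- ev$g1 <= cfg$tol && ev$v <= cfg$tol &&
      ev$discreteness < cfg$discreteness_target
    stagnant <- change < 0.02 ||
      (!is.na(c_prev) && abs(ev$compliance - c_prev) < 1e-3 * abs(c_prev))
    c_prev <- ev$compliance
    ok_run <- if (at_final && feasible && stagnant) ok_run + 1L else 0L
    if (ok_run >= 3L) {
      converged <- TRUE
      break
    }
  }
  final_beta <- cfg$beta_schedule[min(nb, 1 + (iter - 1) %/% cfg$beta_every)]
  ev <- evaluate_topopt(p, x, final_beta, gradients = FALSE)
  structure(list(x = x, x_filtered = ev$fields$xt,
                 x_eroded = ev$fields$eroded,
                 x_nominal = ev$fields$nominal,
                 x_dilated = ev$fields$dilated,
                 des_lin = p$des_lin, dims = p$fe$dims,
                 beta = final_beta, cfg = cfg, seed = seed,
                 converged = converged, iterations = iter,
                 g1 = ev$g1, v = ev$v,
                 strain_pmean_pct = ev$strain_pmean_pct,
                 local_volume_pmean = ev$local_volume_pmean,
                 discreteness = ev$discreteness,
                 compliance = ev$compliance,
                 history = do.call(rbind, hist[!vapply(hist, is.null,
                                                       TRUE)])),
            class = "design_field")
}

#' @exportS3Method base::print
print.design_field <- function(x, ...) {
  cat(sprintf(paste0("<design_field> %d design voxels, %d iterations",
                     " (%sconverged)\n"),
              length(x$x), x$iterations, if (x$converged) "" else "NOT "))
  cat(sprintf("  M_nd %.2f%%  g1 %+.3e  v %+.3e  compliance %.4e\n",
              x$discreteness, x$g1, x$v, x$compliance))
  invisible(x)
}

#' Embed a design field into the full voxel grid
#'
#' @param design A `design_field` from [optimize_cage()].
#' @param which One of `"nominal"`, `"eroded"`, `"dilated"`, `"filtered"`,
#'   `"raw"`.
#' @return 3-D array over the grid (zero outside the design domain).
#' @export
design_field_array <- function(design, which = c("nominal", "eroded",
                                                 "dilated", "filtered",
                                                 "raw")) {
  which <- match.arg(which)
  v <- switch(which, nominal = design$x_nominal, eroded = design$x_eroded,
              dilated = design$x_dilated, filtered = design$x_filtered,
              raw = design$x)
  a <- array(0, dim = design$dims)
  a[design$des_lin] <- v
  a
}
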