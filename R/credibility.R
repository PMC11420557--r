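# Quantitative credibility activities and cohort statistics ---------------

#' Signed percentage difference
#'
#' `(current - previous) / previous * 100`, the convention used both for
#' successive mesh refinements and for sensitivity variants against a
#' baseline.
#'
#' @param current,previous Values; `previous` must be nonzero.
#' @return Signed percentage.
#' @export
percent_diff <- function(current, previous) {
  if (any(previous == 0)) stop("undefined baseline: previous value is zero",
                               call. = FALSE)
  (current - previous) / previous * 100
}

#' Mesh convergence study of the subsidence assessment
#'
#' Re-runs the assessment over a sequence of decreasing element edge
#' lengths, reporting the maximum FFR per resolution and the successive
#' percentage difference; the first resolution whose difference falls below
#' the threshold is flagged as converged.  Optionally replaces the
#' density-mapped bone moduli by a homogeneous 350 MPa modulus, the
#' variant used to decouple mesh effects from the density field.
#'
#' @param build_problem Function taking an element edge length (mm) and
#'   returning a list with `model` (implant inserted), and optionally
#'   `mat`, `constitutive`, `patient_weight`, `cfg`, `law` (defaults:
#'   titanium, asymmetric bone law, 51 kg, [assess_config()]).
#' @param edge_lengths Strictly decreasing element edge lengths (mm).
#' @param threshold Convergence threshold on |percentage difference| (%).
#' @param homogeneous_modulus If non-`NULL` (e.g. 350), assign this bone
#'   modulus (MPa) uniformly instead of the density law.
#' @return A `study_result` data frame with columns `setting`, `max_ffr`,
#'   `percent_diff`, `converged`.
#' @export
mesh_convergence_study <- function(build_problem, edge_lengths,
                                   threshold = 5,
                                   homogeneous_modulus = NULL) {
  if (length(edge_lengths) < 2) stop("need at least two edge lengths",
                                     call. = FALSE)
  if (any(diff(edge_lengths) >= 0)) {
    stop("edge lengths must be strictly decreasing", call. = FALSE)
  }
  law <- NULL
  rows <- lapply(edge_lengths, function(h) {
    prob <- build_problem(h)
    law_h <- prob$law %||% density_law()
    if (!is.null(homogeneous_modulus)) {
      law_h <- structure(list(law_id = "homogeneous", type = "linear",
                              slope = 0, intercept = homogeneous_modulus),
                         class = "density_law")
    }
    res <- assess(prob$model,
                  mat = prob$mat %||% implant_material("titanium"),
                  constitutive = prob$constitutive %||% bone_constitutive(),
                  patient_weight = prob$patient_weight %||% 51,
                  cfg = prob$cfg %||% assess_config(),
                  law = law_h)
    data.frame(setting = sprintf("h=%g mm", h), edge_length = h,
               max_ffr = res$max_ffr)
  })
  out <- do.call(rbind, rows)
  out$percent_diff <- c(0, percent_diff(out$max_ffr[-1],
                                        out$max_ffr[-nrow(out)]))
  out$converged <- c(FALSE, abs(out$percent_diff[-1]) < threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("study_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sensitivity studies of the maximum FFR
#'
#' Re-runs the baseline assessment under variations along one axis and
#' reports the signed percentage difference of the maximum FFR per variant,
#' plus the maximum difference by magnitude:
#' \describe{
#'   \item{`load_magnitude`}{follower load scaled by +/-2.5% and +/-25%.}
#'   \item{`density_law`}{Keller and Morgan density-to-modulus laws against
#'     the baseline law.}
#'   \item{`constitutive`}{linear and symmetric post-yield bone models
#'     against the asymmetric elasto-plastic baseline.}
#' }
#'
#' @param problem List with `model` (implant inserted) and optionally
#'   `mat`, `constitutive`, `patient_weight`, `cfg`, `law`.
#' @param axis One of `"load_magnitude"`, `"density_law"`,
#'   `"constitutive"`.
#' @param load_variations Fractional load variations (default
#'   `c(0.025, 0.25)`, applied with both signs).
#' @return A `study_result` data frame (`setting`, `max_ffr`,
#'   `percent_diff`) with attribute `max_abs_diff` (signed value of the
#'   largest-magnitude difference); non-converging variants are recorded as
#'   `collapse = TRUE` with `max_ffr = NA`.
#' @export
sensitivity_study <- function(problem,
                              axis = c("load_magnitude", "density_law",
                                       "constitutive"),
                              load_variations = c(0.025, 0.25)) {
  axis <- match.arg(axis)
  base_args <- list(model = problem$model,
                    mat = problem$mat %||% implant_material("titanium"),
                    constitutive = problem$constitutive %||%
                      bone_constitutive(),
                    patient_weight = problem$patient_weight %||% 51,
                    cfg = problem$cfg %||% assess_config(),
                    law = problem$law %||% density_law())
  run <- function(args) {
    tryCatch(do.call(assess, args)$max_ffr, error = function(e) NA_real_)
  }
  base_ffr <- do.call(assess, base_args)$max_ffr
  variants <- switch(axis,
    load_magnitude = {
      v <- sort(c(load_variations, -load_variations))
      lapply(v, function(dv) {
        a <- base_args
        a$cfg$base_follower_load <- base_args$cfg$base_follower_load *
          (1 + dv)
        list(name = sprintf("load %+.1f%%", 100 * dv), args = a)
      })
    },
    density_law = lapply(c("keller", "morgan"), function(l) {
      a <- base_args
      a$law <- density_law(l)
      list(name = l, args = a)
    }),
    constitutive = lapply(c("linear", "elastoplastic_symmetric"),
                          function(md) {
      a <- base_args
      a$constitutive <- bone_constitutive(
        mode = md,
        tensile_yield_strain = base_args$constitutive$tensile_yield_strain,
        compressive_yield_strain =
          base_args$constitutive$compressive_yield_strain,
        post_yield_modulus_fraction =
          base_args$constitutive$post_yield_modulus_fraction,
        poisson = base_args$constitutive$poisson,
        modulus_floor = base_args$constitutive$modulus_floor)
      list(name = md, args = a)
    }))
  rows <- lapply(variants, function(vr) {
    mf <- run(vr$args)
    data.frame(setting = vr$name, max_ffr = mf,
               percent_diff = if (is.na(mf)) NA_real_ else
                 percent_diff(mf, base_ffr),
               collapse = is.na(mf))
  })
  out <- rbind(data.frame(setting = "baseline", max_ffr = base_ffr,
                          percent_diff = 0, collapse = FALSE),
               do.call(rbind, rows))
  pd <- out$percent_diff[-1]
  pd_ok <- pd[!is.na(pd)]
  attr(out, "max_abs_diff") <- if (length(pd_ok))
    pd_ok[which.max(abs(pd_ok))] else NA_real_
  attr(out, "axis") <- axis
  class(out) <- c("study_result", class(out))
  out
}

#' Spearman rank correlation
#'
#' Rank correlation coefficient (average ranks for ties) with the p-value of
#' the standard null distribution, via [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List `r`, `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  # Pearson correlation of average ranks (exact under ties; cor.test's
  # estimate matches it for tie-free data)
  list(r = stats::cor(x, y, method = "spearman"), p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' U statistic for `a` versus `b` (pairwise comparisons; ties count 1/2)
#' and the two-sided p-value, exact for small tie-free samples, normal
#' approximation otherwise, via [stats::wilcox.test()].
#'
#' @param a,b Nonempty numeric samples.
#' @return List `U`, `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact =
    (length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b)))))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Cohort comparison report
#'
#' Summarises per-patient maximum FFR results across implant variants:
#' per-group medians, pairwise median percentage reductions with
#' Mann-Whitney p-values, and the Spearman correlation of maximum FFR with
#' vBMD within each group.
#'
#' @param results Data frame with columns `patient`, `group` (implant
#'   type/material label), `max_ffr`, and optionally `vbmd`.
#' @return A `cohort_report` list: `groups` (median per group),
#'   `pairwise` (group1, group2, median_reduction_pct, U, p),
#'   `vbmd_correlation` (per group r, p; NULL without vBMD).
#' @export
cohort_report <- function(results) {
  stopifnot(all(c("patient", "group", "max_ffr") %in% names(results)))
  groups <- unique(results$group)
  if (length(groups) < 2) stop("need at least two implant variants",
                               call. = FALSE)
  med <- vapply(groups, function(g)
    stats::median(results$max_ffr[results$group == g]), 0)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    a <- results[results$group == pr[1], c("patient", "max_ffr")]
    b <- results[results$group == pr[2], c("patient", "max_ffr")]
    common <- intersect(a$patient, b$patient)
    if (length(common) == 0) {
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        median_reduction_pct = NA_real_, U = NA_real_,
                        p = NA_real_, n = 0L))
    }
    av <- a$max_ffr[match(common, a$patient)]
    bv <- b$max_ffr[match(common, b$patient)]
    mw <- mann_whitney(av, bv)
    data.frame(group1 = pr[1], group2 = pr[2],
               median_reduction_pct =
                 100 * (1 - stats::median(bv / av)),
               U = mw$U, p = mw$p, n = length(common))
  })
  vc <- NULL
  if ("vbmd" %in% names(results)) {
    vc <- do.call(rbind, lapply(groups, function(g) {
      sub <- results[results$group == g, ]
      if (nrow(sub) < 3) return(NULL)
      sr <- spearman(sub$vbmd, sub$max_ffr)
      data.frame(group = g, r = sr$r, p = sr$p)
    }))
  }
  structure(list(groups = data.frame(group = groups, median_max_ffr = med,
                                     row.names = NULL),
                 pairwise = do.call(rbind, pw),
                 vbmd_correlation = vc),
            class = "cohort_report")
}

#' @exportS3Method base::print
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\nGroup medians:\n")
  print(x$groups, row.names = FALSE)
  cat("Pairwise (median reduction group1 -> group2):\n")
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$vbmd_correlation)) {
    cat("Max FFR vs vBMD (Spearman):\n")
    print(x$vbmd_correlation, row.names = FALSE)
  }
  invisible(x)
}

#' ASME V&V40-style credibility documentation template
#'
#' Emits the qualitative credibility-table skeleton (question of interest,
#' context of use, model risk, credibility factors) alongside the
#' quantitative study results; the judgement columns are intentionally left
#' to the analyst — no scoring logic is applied.
#'
#' @param studies Named list of `study_result` objects to embed.
#' @param path Optional file to write (markdown); otherwise the text is
#'   returned invisibly.
#' @return Character vector of the report lines, invisibly.
#' @export
vv40_template <- function(studies = list(), path = NULL) {
  ln <- c(
    "# Computational model credibility report (ASME V&V40 style)",
    "",
    "## Question of interest",
    "_state the clinical question the model informs_",
    "",
    "## Context of use",
    "_state the model scope, inputs, and how outputs inform the decision_",
    "",
    "## Model risk",
    "| Model influence | Decision consequence | Model risk |",
    "|---|---|---|",
    "| _to assess_ | _to assess_ | _to assess_ |",
    "",
    "## Quantitative credibility activities")
  for (nm in names(studies)) {
    s <- studies[[nm]]
    ln <- c(ln, "", sprintf("### %s", nm),
            paste(utils::capture.output(print.data.frame(s)),
                  collapse = "\n"))
  }
  ln <- c(ln, "",
          "## Credibility factors (rigour selected / achieved)",
          "_qualitative assessment per ASME V&V40; judgement is out of",
          "computational scope_")
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}
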