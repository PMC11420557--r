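#' @import Matrix
NULL

# Local corner offsets of the 8-node hexahedron (unit cube), standard order.
HEX_LOC <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0,
                    0, 0, 1,  1, 0, 1,  1, 1, 1,  0, 1, 1),
                  ncol = 3, byrow = TRUE)

# Isotropic elasticity matrix (6x6, engineering shear convention), MPa.
iso_D <- function(E, nu) {
  if (nu >= 0.5 || nu <= 0) stop("poisson ratio must be in (0, 0.5)",
                                 call. = FALSE)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Strain-displacement matrix (6x24) of the trilinear hexahedron at natural
# coordinates (xi, eta, zeta) in [-1,1]^3, element edge length h.
hex_B <- function(xi, eta, zeta, h) {
  s <- 2 * HEX_LOC - 1
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- s[a, 1] * (1 + eta * s[a, 2]) * (1 + zeta * s[a, 3]) / 8
    dN[a, 2] <- (1 + xi * s[a, 1]) * s[a, 2] * (1 + zeta * s[a, 3]) / 8
    dN[a, 3] <- (1 + xi * s[a, 1]) * (1 + eta * s[a, 2]) * s[a, 3] / 8
  }
  dN <- dN * (2 / h)  # d/dx = d/dxi * dxi/dx
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    cx <- 3 * a - 2; cy <- 3 * a - 1; cz <- 3 * a
    B[1, cx] <- dN[a, 1]
    B[2, cy] <- dN[a, 2]
    B[3, cz] <- dN[a, 3]
    B[4, cx] <- dN[a, 2]; B[4, cy] <- dN[a, 1]
    B[5, cy] <- dN[a, 3]; B[5, cz] <- dN[a, 2]
    B[6, cx] <- dN[a, 3]; B[6, cz] <- dN[a, 1]
  }
  B
}

#' Stiffness matrix of a trilinear hexahedral element
#'
#' 24 x 24 stiffness matrix of an 8-node cube element with isotropic linear
#' elasticity, integrated with 2x2x2 Gauss quadrature.  Scales linearly with
#' `E` and with `h`.  The matrix is symmetric positive semi-definite with
#' exactly six rigid-body zero-energy modes.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio in (0, 0.5).
#' @param h Element edge length (mm).
#' @return 24 x 24 numeric matrix (dof order x1,y1,z1,...,x8,y8,z8).
#' @export
element_stiffness <- function(E, nu, h) {
  stopifnot(E > 0, h > 0)
  D <- iso_D(E, nu)
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    B <- hex_B(xi, eta, zeta, h)
    Ke <- Ke + crossprod(B, D %*% B) * detJ
  }
  (Ke + t(Ke)) / 2
}

#' Finite element discretisation of a voxel model
#'
#' One trilinear hexahedral element per non-void voxel, shared (tied) nodes
#' throughout.  Precomputes element-node connectivity, node coordinates, the
#' centroid strain-displacement operator, and the bottom-face support node
#' set (fixed in all directions).
#'
#' @param model A [voxel_model()].
#' @return An `fe_grid` object.
#' @export
fe_setup <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  d <- model$dims
  h <- model$spacing
  active <- which(model$labels != LBL_VOID)
  if (length(active) == 0) stop("model has no non-void voxels", call. = FALSE)
  ijk <- arrayInd(active, d)  # 1-based voxel indices
  nxy <- (d[1] + 1) * (d[2] + 1)
  nid <- function(ix, iy, iz) 1 + ix + (d[1] + 1) * iy + nxy * iz  # 0-based
  enodes_grid <- matrix(0L, length(active), 8)
  for (a in 1:8) {
    enodes_grid[, a] <- nid(ijk[, 1] - 1 + HEX_LOC[a, 1],
                            ijk[, 2] - 1 + HEX_LOC[a, 2],
                            ijk[, 3] - 1 + HEX_LOC[a, 3])
  }
  used <- sort(unique(as.vector(enodes_grid)))
  map <- integer(nxy * (d[3] + 1))
  map[used] <- seq_along(used)
  enodes <- matrix(map[enodes_grid], ncol = 8)
  edofs <- matrix(0L, length(active), 24)
  for (a in 1:8) {
    edofs[, (3 * a - 2):(3 * a)] <- cbind(3L * enodes[, a] - 2L,
                                          3L * enodes[, a] - 1L,
                                          3L * enodes[, a])
  }
  g0 <- used - 1L
  niz <- g0 %/% nxy
  rem <- g0 %% nxy
  niy <- rem %/% (d[1] + 1)
  nix <- rem %% (d[1] + 1)
  node_coord <- cbind(model$origin[1] + (nix - 0.5) * h,
                      model$origin[2] + (niy - 0.5) * h,
                      model$origin[3] + (niz - 0.5) * h)
  bottom <- which(niz == 0L)
  top <- which(niz == d[3])
  fixed_dofs <- as.vector(rbind(3L * bottom - 2L, 3L * bottom - 1L,
                                3L * bottom))
  ndof <- 3L * length(used)
  free_dofs <- setdiff(seq_len(ndof), sort(fixed_dofs))
  # geometric nested-dissection fill-reducing ordering of the free nodes
  free_nodes <- unique((free_dofs - 1L) %/% 3L + 1L)
  pn <- free_nodes[nd_order(node_coord[free_nodes, , drop = FALSE])]
  free_perm <- as.vector(rbind(3L * pn - 2L, 3L * pn - 1L, 3L * pn))
  structure(list(model = model, h = h, dims = d,
                 elem_lin = active, elem_ijk = ijk,
                 elem_label = model$labels[active],
                 elem_density = model$density[active],
                 nelem = length(active), edofs = edofs,
                 node_coord = node_coord, n_nodes = length(used),
                 ndof = ndof, top_nodes = top, bottom_nodes = bottom,
                 fixed_dofs = sort(fixed_dofs),
                 free_dofs = free_dofs, free_perm = free_perm,
                 B0 = hex_B(0, 0, 0, h)),
            class = "fe_grid")
}

#' @exportS3Method base::print
print.fe_grid <- function(x, ...) {
  cat(sprintf("<fe_grid> %d elements, %d nodes, %d dofs (%d fixed)\n",
              x$nelem, x$n_nodes, x$ndof, length(x$fixed_dofs)))
  invisible(x)
}

#' Assemble the global stiffness matrix
#'
#' @param fe An [fe_setup()] grid.
#' @param E Per-element Young's modulus vector (MPa, length `fe$nelem`).
#' @param nu Per-element Poisson's ratio (scalar or vector).
#' @param subset Optional element index subset to assemble (others skipped);
#'   used for incremental reassembly of the design domain.
#' @return Sparse symmetric `ndof x ndof` matrix (class `dgCMatrix`).
#' @export
assemble_K <- function(fe, E, nu, subset = NULL) {
  if (length(nu) == 1) nu <- rep(nu, fe$nelem)
  sel <- if (is.null(subset)) seq_len(fe$nelem) else subset
  ii <- rep(1:24, times = 24)
  jj <- rep(1:24, each = 24)
  tr_i <- list(); tr_j <- list(); tr_x <- list()
  for (nuv in unique(nu[sel])) {
    idx <- sel[nu[sel] == nuv]
    kev <- as.vector(element_stiffness(1, nuv, fe$h))
    tr_i[[length(tr_i) + 1L]] <- as.vector(fe$edofs[idx, ii, drop = FALSE])
    tr_j[[length(tr_j) + 1L]] <- as.vector(fe$edofs[idx, jj, drop = FALSE])
    tr_x[[length(tr_x) + 1L]] <- as.vector(outer(E[idx], kev))
  }
  Matrix::sparseMatrix(i = unlist(tr_i), j = unlist(tr_j), x = unlist(tr_x),
                       dims = c(fe$ndof, fe$ndof))
}

# Geometric nested-dissection ordering of a point set (returns a permutation
# of 1..nrow(coord)).  Recursively bisects along the longest axis; separator
# points are numbered last.  Near-optimal fill for regular 3-D grids, where
# CHOLMOD's default minimum-degree ordering performs poorly.
nd_order <- function(coord, leaf = 24) {
  n <- nrow(coord)
  out <- integer(n)
  pos <- 0L
  rec <- function(idx) {
    if (length(idx) <= leaf) {
      out[pos + seq_along(idx)] <<- idx
      pos <<- pos + length(idx)
      return(invisible())
    }
    sub <- coord[idx, , drop = FALSE]
    rng <- apply(sub, 2, function(v) diff(range(v)))
    v <- sub[, which.max(rng)]
    med <- stats::median(v)
    sep <- idx[abs(v - med) < 1e-9]
    lo <- idx[v < med - 1e-9]
    hi <- idx[v > med + 1e-9]
    if (length(sep) == 0 || length(lo) == 0 || length(hi) == 0) {
      o <- idx[order(v)]
      k <- length(o) %/% 2
      lo <- o[1:k]; hi <- o[(k + 1):length(o)]; sep <- integer(0)
    }
    rec(lo); rec(hi)
    if (length(sep)) {
      out[pos + seq_along(sep)] <<- sep
      pos <<- pos + length(sep)
    }
    invisible()
  }
  rec(seq_len(n))
  out
}

# Factorise the reduced (free-dof) system in the precomputed fill-reducing
# order; reuses a symbolic factorisation template when supplied (the
# sparsity pattern is constant across design iterations).
fe_factor <- function(fe, K, template = NULL) {
  fp <- fe$free_perm
  Kff <- Matrix::forceSymmetric(K[fp, fp], uplo = "U")
  if (is.null(template)) {
    chol_or_singular(Kff)
  } else {
    update(template, Kff)
  }
}

# Cholesky that treats CHOLMOD's not-positive-definite warning (a floating,
# unsupported region) as an error rather than silently returning garbage.
# The warning is only recorded here and raised after the factorisation call
# has returned: jumping out of the backend mid-factorisation leaves its
# internal state corrupted.
chol_or_singular <- function(Kff) {
  npd <- FALSE
  ch <- withCallingHandlers(
    tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE, perm = FALSE),
             error = function(e) {
               stop("singular stiffness matrix (disconnected or ",
                    "unsupported region?): ", conditionMessage(e),
                    call. = FALSE)
             }),
    warning = function(w) {
      if (grepl("positive definite", conditionMessage(w))) npd <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (npd) {
    stop("singular stiffness matrix (disconnected or unsupported region?)",
         call. = FALSE)
  }
  ch
}

# Solve for displacements given a factor and one or more load vectors.
fe_displacement <- function(fe, ch, loads) {
  loads <- as.matrix(loads)
  uf <- as.matrix(Matrix::solve(ch, loads[fe$free_perm, , drop = FALSE]))
  u <- matrix(0, fe$ndof, ncol(loads))
  u[fe$free_perm, ] <- uf
  u
}

# Element-centroid strains (nelem x 6 Voigt, engineering shears).
fe_strains <- function(fe, u) {
  Ue <- matrix(u[fe$edofs], ncol = 24)
  Ue %*% t(fe$B0)
}

#' Principal strains of symmetric strain tensors
#'
#' Eigenvalues (and the direction of the largest) of 3x3 symmetric strain
#' tensors given in Voigt form `(exx, eyy, ezz, gxy, gyz, gxz)` with
#' engineering shear components.  Results are sorted descending
#' (`eps_max >= eps_mid >= eps_min`) and are invariant under coordinate
#' rotation.
#'
#' @param voigt Length-6 vector or `n x 6` matrix of strain tensors.
#' @param directions If `TRUE`, also return unit eigenvectors of the largest
#'   principal strain (`n x 3`).
#' @return `n x 3` matrix of principal strains (single vector input returns a
#'   length-3 vector), with attribute `max_dir` when requested.
#' @export
principal_strains <- function(voigt, directions = FALSE) {
  single <- is.null(dim(voigt))
  if (single) voigt <- matrix(voigt, nrow = 1)
  stopifnot(ncol(voigt) == 6, all(is.finite(voigt)))
  res <- principal_strains_batch(voigt, directions)
  vals <- res$values
  colnames(vals) <- c("eps_max", "eps_mid", "eps_min")
  if (directions) attr(vals, "max_dir") <- res$max_dir
  if (single && !directions) return(drop(vals))
  vals
}

#' Linear elastostatic solve on a voxel grid
#'
#' Assembles and solves the tied-node hexahedral system `K u = f` with the
#' bottom face fixed in all directions, and recovers element-centroid strain
#' tensors, principal strains and per-case compliance.
#'
#' @param fe An [fe_setup()] grid (or a [voxel_model()], which is set up
#'   on the fly).
#' @param E Per-element Young's modulus (MPa).
#' @param nu Per-element (or scalar) Poisson's ratio.
#' @param loads Nodal load vector (`ndof`) or matrix (`ndof x n_cases`), N.
#' @param fixed_dofs Constrained dof indices; defaults to all dofs of the
#'   bottom-face nodes.
#' @param fixed_values Prescribed displacements at `fixed_dofs` (mm); default
#'   zero.  Non-zero values allow affine patch tests.
#' @return An `fe_result`: list with `u` (ndof x cases), `strain` (list of
#'   nelem x 6 matrices), `principal` (list of nelem x 3), `compliance`
#'   (per-case, Nmm).
#' @export
solve_linear <- function(fe, E, nu, loads, fixed_dofs = NULL,
                         fixed_values = NULL) {
  if (inherits(fe, "voxel_model")) fe <- fe_setup(fe)
  loads <- as.matrix(loads)
  stopifnot(nrow(loads) == fe$ndof)
  K <- assemble_K(fe, E, nu)
  if (is.null(fixed_dofs)) {
    if (!any(loads != 0)) stop("no loads applied", call. = FALSE)
    ch <- fe_factor(fe, K)
    u <- fe_displacement(fe, ch, loads)
  } else {
    fixed_dofs <- sort(unique(as.integer(fixed_dofs)))
    if (is.null(fixed_values)) fixed_values <- numeric(length(fixed_dofs))
    free <- setdiff(seq_len(fe$ndof), fixed_dofs)
    Kff <- Matrix::forceSymmetric(K[free, free], uplo = "U")
    rhs <- loads[free, , drop = FALSE] -
      as.matrix(K[free, fixed_dofs, drop = FALSE] %*% fixed_values)
    ch <- chol_or_singular(Kff)
    u <- matrix(0, fe$ndof, ncol(loads))
    u[free, ] <- as.matrix(Matrix::solve(ch, rhs))
    u[fixed_dofs, ] <- fixed_values
  }
  res <- list(u = u, strain = list(), principal = list(),
              compliance = numeric(ncol(loads)))
  for (k in seq_len(ncol(loads))) {
    s <- fe_strains(fe, u[, k])
    res$strain[[k]] <- s
    res$principal[[k]] <- principal_strains(s)
    res$compliance[k] <- sum(loads[, k] * u[, k])
  }
  class(res) <- "fe_result"
  res
}

#' Spinal load cases (daily-living resultants)
#'
#' @param name Case label.
#' @param force Length-3 force resultant `(Fx, Fy, Fz)` in N.
#' @param moment Length-3 moment resultant `(Mx, My, Mz)` in Nmm.
#' @return A `load_case` object.
#' @export
load_case <- function(name, force = c(0, 0, 0), moment = c(0, 0, 0)) {
  force <- as.numeric(force); moment <- as.numeric(moment)
  stopifnot(length(force) == 3, length(moment) == 3)
  if (all(force == 0) && all(moment == 0)) {
    stop("load case must have a nonzero force or moment", call. = FALSE)
  }
  structure(list(name = name, force = force, moment = moment),
            class = "load_case")
}

#' Reference daily-living load set (six cases), body-weight scaled
#'
#' The six spinal load cases applied in the optimisation: axial compression
#' Fz = -177 N, posterior-anterior shear Fy = 27 N, lateral shear Fx = 5 N,
#' flexion Mx = 0.4 Nm, lateral bending My = 0.5 Nm, axial rotation
#' Mz = 0.7 Nm (moments converted to Nmm on construction).  All magnitudes
#' scale linearly by `patient_weight / reference_weight` (reference 51 kg).
#'
#' @param patient_weight Patient body weight in kg.
#' @param reference_weight Reference body weight in kg (default 51).
#' @return A `load_set`: list of six [load_case()] objects plus the weights.
#' @export
reference_load_set <- function(patient_weight = 51, reference_weight = 51) {
  stopifnot(patient_weight > 0, reference_weight > 0)
  s <- patient_weight / reference_weight
  cases <- list(
    load_case("axial_compression",      force = c(0, 0, -177) * s),
    load_case("posterior_anterior_shear", force = c(0, 27, 0) * s),
    load_case("lateral_shear",          force = c(5, 0, 0) * s),
    load_case("flexion",                moment = c(400, 0, 0) * s),
    load_case("lateral_bending",        moment = c(0, 500, 0) * s),
    load_case("axial_rotation",         moment = c(0, 0, 700) * s))
  structure(list(cases = cases, patient_weight = patient_weight,
                 reference_weight = reference_weight),
            class = "load_set")
}

#' Distribute a load case over the top-face nodes
#'
#' Computes nodal forces on the top-face node set whose resultant force and
#' resultant moment (about the reference point, the xy-centre of the rigid
#' domain at the top face) equal the case resultants exactly.  Among all such
#' distributions the minimum-norm solution of the 6-row resultant system is
#' returned.
#'
#' @param case A [load_case()].
#' @param fe An [fe_setup()] grid.
#' @return Nodal load vector of length `fe$ndof` (N).
#' @export
distribute_load <- function(case, fe) {
  stopifnot(inherits(case, "load_case"), inherits(fe, "fe_grid"))
  nodes <- fe$top_nodes
  if (length(nodes) == 0) stop("empty top-face node set", call. = FALSE)
  xy <- fe$node_coord[nodes, 1:2, drop = FALSE]
  rigid <- fe$elem_label == LBL_RIGID
  ref_xy <- if (any(rigid)) {
    ij <- fe$elem_ijk[rigid, 1:2, drop = FALSE]
    fe$model$origin[1:2] + (colMeans(ij) - 1) * fe$h
  } else colMeans(xy)
  ref <- c(ref_xy, max(fe$node_coord[nodes, 3]))
  r <- sweep(fe$node_coord[nodes, , drop = FALSE], 2, ref, `-`)
  n <- length(nodes)
  if (any(case$moment != 0)) {
    # need a genuinely 2-D node cloud for moment equilibrium
    if (n < 3 || qr(cbind(1, xy))$rank < 3) {
      stop("moment requested but top-face nodes are (nearly) collinear",
           call. = FALSE)
    }
  }
  A <- matrix(0, 6, 3 * n)
  cx <- seq(1, 3 * n, by = 3)
  A[1, cx] <- 1; A[2, cx + 1] <- 1; A[3, cx + 2] <- 1
  # moment rows: r x f
  A[4, cx + 1] <- -r[, 3]; A[4, cx + 2] <- r[, 2]
  A[5, cx] <- r[, 3];      A[5, cx + 2] <- -r[, 1]
  A[6, cx] <- -r[, 2];     A[6, cx + 1] <- r[, 1]
  b <- c(case$force, case$moment)
  f <- crossprod(A, solve(A %*% t(A), b))
  out <- numeric(fe$ndof)
  dofs <- as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))
  out[dofs] <- f
  out
}

#' Nodal load matrix for a whole load set
#'
#' @param loads A [reference_load_set()].
#' @param fe An [fe_setup()] grid.
#' @return `ndof x n_cases` matrix; column names are the case names.
#' @export
distribute_load_set <- function(loads, fe) {
  stopifnot(inherits(loads, "load_set"))
  F <- vapply(loads$cases, distribute_load, numeric(fe$ndof), fe = fe)
  colnames(F) <- vapply(loads$cases, `[[`, "", "name")
  F
}
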