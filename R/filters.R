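# Neighbourhood filter matrices on the design domain ----------------------

# Sparse row-normalised neighbourhood matrix over a set of voxels (linear
# indices into a grid of dims d).  weight = "cone" (r - dist) or "uniform".
# Radius in element edge lengths.
neighbourhood_matrix <- function(lin, dims, radius, weight = c("cone",
                                                               "uniform")) {
  weight <- match.arg(weight)
  if (radius < 1) stop("filter radius must be at least one element",
                       call. = FALSE)
  idmap <- array(0L, dim = dims)
  idmap[lin] <- seq_along(lin)
  ijk <- arrayInd(lin, dims)
  ext <- apply(ijk, 2, function(v) diff(range(v))) + 1
  if (radius > max(ext)) {
    stop("filter radius exceeds the design-domain extent", call. = FALSE)
  }
  r <- floor(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  dist <- sqrt(offs$dx^2 + offs$dy^2 + offs$dz^2)
  keep <- dist <= radius
  offs <- offs[keep, ]
  w_off <- if (weight == "cone") radius - dist[keep] else rep(1, sum(keep))
  ii <- list(); jj <- list(); xx <- list()
  for (q in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs$dx[q]
    nj <- ijk[, 2] + offs$dy[q]
    nk <- ijk[, 3] + offs$dz[q]
    ok <- ni >= 1 & ni <= dims[1] & nj >= 1 & nj <= dims[2] &
          nk >= 1 & nk <= dims[3]
    if (!any(ok)) next
    nid <- idmap[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nid > 0L
    if (!any(hit)) next
    ii[[length(ii) + 1L]] <- which(ok)[hit]
    jj[[length(jj) + 1L]] <- nid[hit]
    xx[[length(xx) + 1L]] <- rep(w_off[q], sum(hit))
  }
  H <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(length(lin), length(lin)))
  Matrix::Diagonal(x = 1 / Matrix::rowSums(H)) %*% H
}

#' Density filter (cone-weighted neighbourhood average)
#'
#' Standard linear density filter supporting the robust three-field scheme:
#' each design variable is replaced by the cone-weighted (`radius - dist`)
#' average over its neighbourhood, with weights renormalised per voxel so
#' that uniform fields are preserved exactly.
#'
#' @param x Design values: a vector over the voxel set `mask`, or a 3-D
#'   array (read at `mask`).
#' @param mask Linear voxel indices of the design domain (or logical array).
#' @param dims Grid dims (taken from `mask` when it is an array).
#' @param radius Filter radius in element edge lengths (>= 1).
#' @return Filtered values as a vector over `mask`.
#' @export
density_filter <- function(x, mask, dims = NULL, radius = 2.5) {
  if (is.logical(mask)) { dims <- dim(mask); mask <- which(mask) }
  if (is.array(x)) { dims <- dim(x); x <- x[mask] }
  H <- neighbourhood_matrix(mask, dims, radius, "cone")
  as.numeric(H %*% x)
}

#' Smoothed Heaviside (tanh) projection
#'
#' Threshold projection used to realise the eroded / nominal / dilated
#' designs of the robust formulation:
#' `(tanh(beta*eta) + tanh(beta*(x - eta))) / (tanh(beta*eta) +
#' tanh(beta*(1 - eta)))`.  Strictly increasing, maps 0 to ~0, 1 to ~1, and
#' `eta` to 0.5 exactly as `beta` grows.
#'
#' @param x Filtered design values in \[0, 1\].
#' @param beta Projection sharpness (> 0).
#' @param eta Threshold in (0, 1).
#' @param deriv If `TRUE`, return the derivative d(proj)/dx instead.
#' @return Projected values (or derivative), same shape as `x`.
#' @export
heaviside_project <- function(x, beta, eta, deriv = FALSE) {
  stopifnot(beta > 0, eta > 0, eta < 1)
  den <- tanh(beta * eta) + tanh(beta * (1 - eta))
  if (deriv) {
    beta * (1 - tanh(beta * (x - eta))^2) / den
  } else {
    (tanh(beta * eta) + tanh(beta * (x - eta))) / den
  }
}

#' Discreteness measure of a design field
#'
#' Grey-level measure `M_nd = mean(4 x (1 - x)) * 100` in percent: 0 for a
#' fully solid/void field, 100 for an all-0.5 field.  A converged design is
#' required to stay below 3%.
#'
#' @param x Design values in \[0, 1\] (any shape).
#' @return Percentage in \[0, 100\].
#' @export
discreteness <- function(x) {
  x <- as.numeric(x)
  stopifnot(all(x >= -1e-9), all(x <= 1 + 1e-9))
  mean(4 * x * (1 - x)) * 100
}
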