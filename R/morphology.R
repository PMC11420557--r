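# Iso-surface extraction, implant morphology metrics, STL I/O -------------

# Tetrahedral (Kuhn) decomposition of each cube cell, fanned around the main
# diagonal v1-v7; shared faces of neighbouring cells are split along the same
# diagonal, so the extracted surface is watertight by construction.
TET_DECOMP <- matrix(c(1, 2, 3, 7,
                       1, 3, 4, 7,
                       1, 4, 8, 7,
                       1, 8, 5, 7,
                       1, 5, 6, 7,
                       1, 6, 2, 7), ncol = 4, byrow = TRUE)

#' Extract the iso-surface of a design field as a triangle mesh
#'
#' Iso-surfaces the voxel field at the given threshold (default 0.5, the
#' solid/void contour used for export and binarisation) by marching a
#' consistent six-tetrahedron decomposition of each grid cell.  Voxel values
#' are treated as samples at voxel centres; the field is zero-padded so the
#' surface is closed.  Vertices are returned in physical millimetres.
#'
#' @param field 3-D numeric array in \[0, 1\] (e.g. from
#'   [design_field_array()]).
#' @param iso Iso-contour threshold.
#' @param spacing Voxel edge length (mm).
#' @param origin Physical coordinate of the centre of voxel (1,1,1).
#' @return A `tri_mesh`: list with `vertices` (3n x 3 matrix, consecutive
#'   triples form triangles) and `n_triangles`.  Empty fields give an empty
#'   mesh with a warning.
#' @export
extract_surface <- function(field, iso = 0.5, spacing = 1,
                            origin = c(0, 0, 0)) {
  stopifnot(length(dim(field)) == 3)
  d <- dim(field) + 2L
  a <- array(0, dim = d)
  a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- field
  if (all(a <= iso) || all(a >= iso)) {
    warning("empty iso-level set: returning empty mesh")
    return(structure(list(vertices = matrix(0, 0, 3), n_triangles = 0L),
                     class = "tri_mesh"))
  }
  # cells with a sign change (check the 8 cell corners)
  nc <- d - 1L
  cmin <- array(Inf, dim = nc); cmax <- array(-Inf, dim = nc)
  for (a8 in 1:8) {
    o <- HEX_LOC[a8, ]
    blk <- a[(1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]),
             (1 + o[3]):(nc[3] + o[3])]
    cmin <- pmin(cmin, blk); cmax <- pmax(cmax, blk)
  }
  cells <- which(cmin < iso & cmax > iso)
  if (length(cells) == 0) {
    warning("empty iso-level set: returning empty mesh")
    return(structure(list(vertices = matrix(0, 0, 3), n_triangles = 0L),
                     class = "tri_mesh"))
  }
  cijk <- arrayInd(cells, nc)
  # per-cell corner values and coordinates (voxel-centre grid incl. padding)
  vals <- matrix(0, length(cells), 8)
  for (a8 in 1:8) {
    vals[, a8] <- a[cbind(cijk[, 1] + HEX_LOC[a8, 1],
                          cijk[, 2] + HEX_LOC[a8, 2],
                          cijk[, 3] + HEX_LOC[a8, 3])]
  }
  corner_xyz <- function(a8) {
    (cijk + matrix(HEX_LOC[a8, ], length(cells), 3, byrow = TRUE) - 2) *
      spacing + matrix(origin, length(cells), 3, byrow = TRUE)
  }
  XYZ <- lapply(1:8, corner_xyz)

  tri <- list()
  emit <- function(p1, p2, p3) {
    tri[[length(tri) + 1L]] <<- rbind_interleave(p1, p2, p3)
  }
  interp <- function(ia, ib, sel) {
    va <- vals[sel, ia]; vb <- vals[sel, ib]
    t <- (iso - va) / (vb - va)
    XYZ[[ia]][sel, , drop = FALSE] * (1 - t) +
      XYZ[[ib]][sel, , drop = FALSE] * t
  }
  for (tt in seq_len(nrow(TET_DECOMP))) {
    tv <- TET_DECOMP[tt, ]
    above <- vals[, tv, drop = FALSE] > iso
    code <- above[, 1] + 2L * above[, 2] + 4L * above[, 3] + 8L * above[, 4]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (length(sel) == 0) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      ups <- which(bits); dns <- which(!bits)
      if (length(ups) == 3) { tmp <- ups; ups <- dns; dns <- tmp }
      if (length(ups) == 1) {
        i <- tv[ups]
        o <- tv[dns]
        emit(interp(i, o[1], sel), interp(i, o[2], sel),
             interp(i, o[3], sel))
      } else {
        i <- tv[ups[1]]; j <- tv[ups[2]]
        k <- tv[dns[1]]; l <- tv[dns[2]]
        pik <- interp(i, k, sel); pil <- interp(i, l, sel)
        pjl <- interp(j, l, sel); pjk <- interp(j, k, sel)
        emit(pik, pil, pjl)
        emit(pik, pjl, pjk)
      }
    }
  }
  V <- do.call(rbind, tri)
  structure(list(vertices = V, n_triangles = nrow(V) %/% 3L),
            class = "tri_mesh")
}

# interleave rows of three n x 3 matrices into a 3n x 3 matrix (triangles)
rbind_interleave <- function(p1, p2, p3) {
  n <- nrow(p1)
  out <- matrix(0, 3 * n, 3)
  out[seq(1, 3 * n, 3), ] <- p1
  out[seq(2, 3 * n, 3), ] <- p2
  out[seq(3, 3 * n, 3), ] <- p3
  out
}

#' @exportS3Method base::print
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d triangles\n", x$n_triangles))
  invisible(x)
}

#' Total surface area of a triangle mesh
#' @param mesh A `tri_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  if (mesh$n_triangles == 0) return(0)
  V <- mesh$vertices
  i1 <- seq(1, nrow(V), 3)
  e1 <- V[i1 + 1, , drop = FALSE] - V[i1, , drop = FALSE]
  e2 <- V[i1 + 2, , drop = FALSE] - V[i1, , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

# Deduplicated vertex/edge/face counts (Euler characteristic, watertightness)
mesh_topology <- function(mesh, tol = 1e-9) {
  V <- round(mesh$vertices / tol) * tol
  key <- paste(V[, 1], V[, 2], V[, 3], sep = "/")
  uid <- match(key, unique(key))
  nV <- length(unique(uid))
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  # drop degenerate triangles (repeated vertices after dedup)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[good, , drop = FALSE]
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ek <- paste(e[, 1], e[, 2], sep = "/")
  tab <- table(ek)
  list(V = nV, E = length(tab), F = nrow(f),
       euler = nV - length(tab) + nrow(f),
       watertight = all(tab == 2))
}

#' Porosity of a binarised design
#'
#' `1 - solid voxels / reference-region voxels`.  The reference region is
#' the implant design domain.
#'
#' @param x_binary Logical/0-1 array (or vector over the region).
#' @param region Logical array or linear indices of the reference region;
#'   omit when `x_binary` is already restricted to the region.
#' @return Porosity fraction in \[0, 1\].
#' @export
porosity <- function(x_binary, region = NULL) {
  if (!is.null(region)) {
    if (is.logical(region)) region <- which(region)
    if (length(region) == 0) stop("empty reference region", call. = FALSE)
    x_binary <- x_binary[region]
  }
  if (length(x_binary) == 0) stop("empty reference region", call. = FALSE)
  1 - sum(x_binary >= 0.5) / length(x_binary)
}

#' Mean pore diameter by local thickness
#'
#' Per-void-voxel local thickness: the diameter of the largest inscribed
#' sphere (bounded by solid voxels or the region boundary) containing the
#' voxel; reported as mean and standard deviation over the void phase, the
#' standard porous-media pore-size definition.
#'
#' @param x_binary 3-D 0/1 array (solid = 1).
#' @param region Logical array or linear indices of the analysis region
#'   (default: whole array).
#' @param spacing Voxel edge length (mm).
#' @return List `mean`, `sd` (mm), `n_void`; mean 0 with a warning when the
#'   region has no void phase.
#' @export
mean_pore_diameter <- function(x_binary, region = NULL, spacing = 1) {
  d <- dim(x_binary)
  stopifnot(length(d) == 3)
  reg <- array(FALSE, dim = d)
  if (is.null(region)) reg[] <- TRUE
  else if (is.logical(region)) reg <- region
  else reg[region] <- TRUE
  solid <- (x_binary >= 0.5) & reg
  void <- reg & !solid
  if (!any(void)) {
    warning("no void phase in region")
    return(list(mean = 0, sd = 0, n_void = 0L))
  }
  # pad by one obstacle layer so the array boundary bounds the pore space
  dp <- d + 2L
  voidp <- array(FALSE, dim = dp)
  voidp[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <- void
  void <- voidp
  d <- dp
  vi <- which(void)
  vxyz <- arrayInd(vi, d)
  # obstacle voxels: solid or out-of-region voxels face-adjacent to a void
  obst <- !void
  shell <- obst & dilate6(void)
  oxyz <- arrayInd(which(shell), d)
  # radius = distance to the nearest obstacle voxel centre
  r <- numeric(length(vi))
  for (i in seq_along(vi)) {
    dx <- oxyz[, 1] - vxyz[i, 1]
    dy <- oxyz[, 2] - vxyz[i, 2]
    dz <- oxyz[, 3] - vxyz[i, 3]
    r[i] <- sqrt(min(dx * dx + dy * dy + dz * dz))
  }
  # local thickness: largest 2r over spheres containing each voxel (every
  # sphere is painted; pruning by current coverage under-estimates the
  # thickness of near-wall voxels)
  lt <- numeric(length(vi))
  ord <- order(r, decreasing = TRUE)
  for (i in ord) {
    if (2 * r[i] <= min(lt)) break
    dx <- vxyz[, 1] - vxyz[i, 1]
    dy <- vxyz[, 2] - vxyz[i, 2]
    dz <- vxyz[, 3] - vxyz[i, 3]
    inside <- (dx * dx + dy * dy + dz * dz) <= r[i]^2
    lt[inside] <- pmax(lt[inside], 2 * r[i])
  }
  # physical diameter: a sphere of centre-distance radius r spans 2r plus
  # the voxel extent itself; cap by the bounding-box extent of the region
  ext <- (apply(vxyz, 2, function(v) diff(range(v))) + 1) * spacing
  lt <- pmin((lt + 1) * spacing, min(ext))
  list(mean = mean(lt), sd = stats::sd(lt), n_void = length(vi))
}

# 6-neighbourhood binary dilation
dilate6 <- function(b) {
  g <- b
  d <- dim(b)
  g[-1, , ] <- g[-1, , ] | b[-d[1], , ]
  g[-d[1], , ] <- g[-d[1], , ] | b[-1, , ]
  g[, -1, ] <- g[, -1, ] | b[, -d[2], ]
  g[, -d[2], ] <- g[, -d[2], ] | b[, -1, ]
  g[, , -1] <- g[, , -1] | b[, , -d[3]]
  g[, , -d[3]] <- g[, , -d[3]] | b[, , -1]
  g
}

#' Morphology report of an optimised implant design
#'
#' Binarises the nominal design at the iso threshold, then reports porosity
#' over the design domain, local-thickness pore-diameter statistics, and
#' iso-surface properties.
#'
#' @param design A `design_field` from [optimize_cage()] (or a 3-D field
#'   array with `region` supplied).
#' @param region Design-domain voxels when `design` is a plain array.
#' @param spacing Voxel edge length (mm).
#' @param iso Binarisation / surface threshold.
#' @return An `implant_morphology` list: `porosity`, `mean_pore_diameter`,
#'   `pore_diameter_sd` (mm), `surface_triangle_count`, `watertight`.
#' @export
implant_morphology <- function(design, region = NULL, spacing = 1,
                               iso = 0.5) {
  if (inherits(design, "design_field")) {
    region <- design$des_lin
    field <- design_field_array(design, "nominal")
  } else field <- design
  stopifnot(!is.null(region))
  mesh <- extract_surface(field, iso = iso, spacing = spacing)
  topo <- if (mesh$n_triangles > 0) mesh_topology(mesh) else
    list(watertight = FALSE)
  pores <- mean_pore_diameter(field, region = region, spacing = spacing)
  structure(list(porosity = porosity(field >= iso, region),
                 mean_pore_diameter = pores$mean,
                 pore_diameter_sd = pores$sd,
                 surface_triangle_count = mesh$n_triangles,
                 watertight = topo$watertight),
            class = "implant_morphology")
}

#' @exportS3Method base::print
print.implant_morphology <- function(x, ...) {
  cat(sprintf(paste0("<implant_morphology> porosity %.1f%%, pore diameter ",
                     "%.2f +/- %.2f mm, %d surface triangles%s\n"),
              100 * x$porosity, x$mean_pore_diameter, x$pore_diameter_sd,
              x$surface_triangle_count,
              if (x$watertight) " (watertight)" else ""))
  invisible(x)
}

#' Write/read a triangle mesh as binary STL
#'
#' Little-endian binary STL; facet normals are recomputed from the vertex
#' winding on write.
#'
#' @param mesh A `tri_mesh` (from [extract_surface()]).
#' @param path File path.
#' @return `write_stl` returns `path` invisibly; `read_stl` returns a
#'   `tri_mesh`.
#' @export
write_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(mesh$n_triangles), con, size = 4, endian = "little")
  if (mesh$n_triangles > 0) {
    V <- mesh$vertices
    i1 <- seq(1, nrow(V), 3)
    e1 <- V[i1 + 1, , drop = FALSE] - V[i1, , drop = FALSE]
    e2 <- V[i1 + 2, , drop = FALSE] - V[i1, , drop = FALSE]
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2))
    nrm <- nrm / ifelse(len > 0, len, 1)
    dat <- matrix(0, mesh$n_triangles, 12)
    dat[, 1:3] <- nrm
    dat[, 4:6] <- V[i1, ]
    dat[, 7:9] <- V[i1 + 1, ]
    dat[, 10:12] <- V[i1 + 2, ]
    for (i in seq_len(mesh$n_triangles)) {
      writeBin(as.numeric(dat[i, ]), con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nt <- readBin(con, "integer", 1, size = 4, endian = "little")
  V <- matrix(0, 3 * nt, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
    V[3 * i - 2, ] <- rec[4:6]
    V[3 * i - 1, ] <- rec[7:9]
    V[3 * i, ] <- rec[10:12]
  }
  structure(list(vertices = V, n_triangles = nt), class = "tri_mesh")
}
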