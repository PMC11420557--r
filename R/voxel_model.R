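#' @importFrom methods as new
#' @importFrom stats median rnorm runif setNames cor.test wilcox.test
#' @importFrom utils write.csv
NULL

# Voxel label codes shared by all modules.
LBL_VOID <- 0L
LBL_BONE <- 1L
LBL_DESIGN <- 2L
LBL_RIGID <- 3L

#' Voxel label codes
#'
#' Integer codes used in the `labels` array of a [voxel_model()]:
#' `void = 0`, `bone = 1`, `implant_design = 2`, `rigid = 3`.
#' @return Named integer vector.
#' @export
voxel_labels <- function() {
  c(void = LBL_VOID, bone = LBL_BONE, implant_design = LBL_DESIGN,
    rigid = LBL_RIGID)
}

#' Structured voxel model of a bone-implant domain
#'
#' The single geometric substrate shared by the optimiser and the assessment:
#' an axis-aligned structured grid (right-handed axes, z superior) with a
#' per-voxel domain label (void / bone / implant design domain / rigid
#' embedding) and a per-voxel apparent density in g/cm^3 for bone voxels.
#'
#' @param labels Integer 3-D array of label codes (see [voxel_labels()]).
#' @param density Numeric 3-D array, same dims, apparent density in g/cm^3
#'   (meaningful on bone voxels; zero elsewhere is conventional).
#' @param spacing Isotropic voxel edge length in mm.
#' @param origin Physical coordinate (mm) of the centre of voxel (1,1,1).
#' @return A `voxel_model` object with elements `dims`, `spacing`, `origin`,
#'   `labels`, `density`.
#' @export
voxel_model <- function(labels, density = NULL, spacing = 1,
                        origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, spacing > 0, length(origin) == 3)
  labels <- array(as.integer(labels), dim = dim(labels))
  if (is.null(density)) density <- array(0, dim = dim(labels))
  if (!identical(dim(density), dim(labels))) {
    stop("label and density arrays must share dims", call. = FALSE)
  }
  if (any(density[labels == LBL_BONE] < 0)) {
    stop("bone voxels must have non-negative density", call. = FALSE)
  }
  structure(list(dims = dim(labels), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), labels = labels,
                 density = density),
            class = "voxel_model")
}

#' @exportS3Method base::print
print.voxel_model <- function(x, ...) {
  d <- x$dims
  cnt <- table(factor(x$labels, levels = voxel_labels(),
                      labels = names(voxel_labels())))
  cat(sprintf("<voxel_model> %dx%dx%d voxels @ %.4g mm\n", d[1], d[2], d[3],
              x$spacing))
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "), "\n")
  invisible(x)
}

#' Physical centre coordinates of all voxels
#' @param model A [voxel_model()].
#' @return n x 3 matrix of voxel-centre coordinates (mm), column-major order.
#' @keywords internal
voxel_centres <- function(model) {
  d <- model$dims
  idx <- arrayInd(seq_len(prod(d)), d)
  sweep((idx - 1) * model$spacing, 2, model$origin, `+`)
}

#' Read/write a voxel model as NIfTI
#'
#' The model is stored as a pair of NIfTI volumes sharing grid metadata:
#' `<stem>_labels.nii.gz` (integer label codes) and `<stem>_density.nii.gz`
#' (apparent density, g/cm^3).  Spacing and origin are carried in the NIfTI
#' header and restored on read.
#'
#' @param model A [voxel_model()].
#' @param stem Path stem (without the `_labels`/`_density` suffix).
#' @return `write_voxel_model` returns `stem` invisibly; `read_voxel_model`
#'   returns the reconstructed [voxel_model()].
#' @export
write_voxel_model <- function(model, stem) {
  stopifnot(inherits(model, "voxel_model"))
  pd <- rep(model$spacing, 3)
  img_l <- RNifti::asNifti(model$labels, pixdim = pd)
  img_d <- RNifti::asNifti(model$density, pixdim = pd)
  RNifti::writeNifti(img_l, paste0(stem, "_labels.nii.gz"))
  RNifti::writeNifti(img_d, paste0(stem, "_density.nii.gz"))
  # origin stored alongside: NIfTI qform handling is overkill for phantoms
  writeLines(jsonlite::toJSON(list(origin = model$origin,
                                   spacing = model$spacing),
                              auto_unbox = TRUE, digits = NA),
             paste0(stem, "_meta.json"))
  invisible(stem)
}

#' @rdname write_voxel_model
#' @export
read_voxel_model <- function(stem) {
  lab <- RNifti::readNifti(paste0(stem, "_labels.nii.gz"))
  den <- RNifti::readNifti(paste0(stem, "_density.nii.gz"))
  meta <- jsonlite::fromJSON(paste0(stem, "_meta.json"))
  voxel_model(array(as.integer(round(lab)), dim = dim(lab)),
              array(as.numeric(den), dim = dim(den)),
              spacing = meta$spacing, origin = meta$origin)
}

#' Write/read a scalar field as VTK image data (.vti, ASCII)
#'
#' Minimal VTK XML ImageData I/O for exporting design and FFR fields to
#' standard visualisation tools.  One cell-data scalar array per file.
#'
#' @param field Numeric 3-D array (cell data, one value per voxel).
#' @param path Output `.vti` path.
#' @param spacing Voxel edge length (mm).
#' @param origin Grid origin (mm, node (0,0,0)).
#' @param name Array name.
#' @return `write_vti` returns `path` invisibly; `read_vti` returns a list
#'   with `field`, `spacing`, `origin`, `name`.
#' @export
write_vti <- function(field, path, spacing = 1, origin = c(0, 0, 0),
                      name = "field") {
  d <- dim(field)
  stopifnot(length(d) == 3)
  ext <- sprintf("0 %d 0 %d 0 %d", d[1], d[2], d[3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="%s" Origin="%.9g %.9g %.9g" Spacing="%.9g %.9g %.9g">',
            ext, origin[1], origin[2], origin[3], spacing, spacing, spacing),
    sprintf('    <Piece Extent="%s">', ext),
    sprintf('      <CellData Scalars="%s">', name),
    sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', name)),
    con)
  writeLines(paste(format(as.vector(field), digits = 17, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
  writeLines(c('        </DataArray>', '      </CellData>', '    </Piece>',
               '  </ImageData>', '</VTKFile>'), con)
  invisible(path)
}

#' @rdname write_vti
#' @export
read_vti <- function(path) {
  txt <- readLines(path)
  grab <- function(pat) {
    ln <- grep(pat, txt, value = TRUE)[1]
    ln
  }
  img <- grab("<ImageData ")
  ext <- as.integer(strsplit(sub('.*WholeExtent="([^"]*)".*', "\\1", img),
                             " ")[[1]])
  origin <- as.numeric(strsplit(sub('.*Origin="([^"]*)".*', "\\1", img),
                                " ")[[1]])
  spacing <- as.numeric(strsplit(sub('.*Spacing="([^"]*)".*', "\\1", img),
                                 " ")[[1]])[1]
  name <- sub('.*Name="([^"]*)".*', "\\1", grab("<DataArray "))
  i0 <- grep("<DataArray ", txt)[1]
  i1 <- grep("</DataArray>", txt)[1]
  vals <- as.numeric(strsplit(trimws(paste(txt[(i0 + 1):(i1 - 1)],
                                           collapse = " ")), "\\s+")[[1]])
  d <- c(ext[2] - ext[1], ext[4] - ext[3], ext[6] - ext[5])
  list(field = array(vals, dim = d), spacing = spacing, origin = origin,
       name = name)
}
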