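#' Define a voxel grid
#'
#' A grid specification ties a 3-D voxel array to millimetre space through an
#' explicit affine. Voxel indices are 0-based throughout; mm coordinates are
#' obtained as `affine[, 1:3] %*% index + affine[, 4]`.
#'
#' @param dims integer(3), voxels per axis (all positive).
#' @param voxel_size numeric(3) or scalar, mm per voxel along each axis.
#' @param affine 3x4 numeric matrix mapping 0-based voxel indices to mm. If
#'   `NULL`, built as `diag(voxel_size)` with translation `origin_mm`.
#' @param origin_mm mm coordinate of voxel (0,0,0); used only when `affine`
#'   is `NULL`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dims, voxel_size, affine = NULL, origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L))
    stop("`dims` must be 3 positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("`voxel_size` must be strictly positive")
  if (is.null(affine)) {
    affine <- cbind(diag(voxel_size), as.numeric(origin_mm))
  }
  affine <- matrix(as.numeric(affine), 3L, 4L)
  if (abs(det(affine[, 1:3])) < .Machine$double.eps^0.5)
    stop("affine 3x3 part must be invertible")
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$dims, collapse = " x "),
      " voxels, size ", paste(x$voxel_size, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' A single subject's voxel map
#'
#' @param subject_id subject identifier.
#' @param map_kind one of `"contrast_msvxas"`, `"control_scrambled"`,
#'   `"control_blank"`, `"structural_seg"`.
#' @param grid a [grid_spec()].
#' @param values numeric array (or vector) with `prod(grid$dims)` finite
#'   values, in R array order.
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(subject_id, map_kind, grid, values) {
  map_kind <- match.arg(map_kind, c("contrast_msvxas", "control_scrambled",
                                    "control_blank", "structural_seg"))
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.numeric(values)
  if (length(values) != prod(grid$dims))
    stop("`values` length must equal prod(grid$dims)")
  if (!all(is.finite(values))) stop("voxel map values must all be finite")
  structure(list(subject_id = subject_id, map_kind = map_kind, grid = grid,
                 values = array(values, dim = grid$dims)),
            class = "voxel_map")
}

#' Manhattan-ball ROI mask
#'
#' Enumerates all lattice points within L1 (city-block) distance `radius` of a
#' centre voxel. With the default radius of 2 the mask contains 25 voxels.
#' Offsets are ordered lexicographically by (dx, dy, dz) so the voxel order is
#' deterministic and identical across subjects.
#'
#' @param center_voxel integer(3), 0-based centre voxel.
#' @param radius integer >= 0, maximum L1 distance in voxels.
#' @return Integer matrix, one row per mask voxel (columns x, y, z), 0-based.
#' @export
#' @examples
#' nrow(build_roi_mask(c(10, 10, 10), 2))  # 25
build_roi_mask <- function(center_voxel, radius = 2L) {
  radius <- as.integer(radius)
  if (length(radius) != 1L || is.na(radius) || radius < 0L)
    stop("`radius` must be a single integer >= 0")
  center_voxel <- as.integer(center_voxel)
  stopifnot(length(center_voxel) == 3L)
  r <- radius
  off <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)  # dx slowest
  off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) <= r, c("dx", "dy", "dz")]
  off <- off[order(off$dx, off$dy, off$dz), , drop = FALSE]
  m <- cbind(x = center_voxel[1] + off$dx,
             y = center_voxel[2] + off$dy,
             z = center_voxel[3] + off$dz)
  rownames(m) <- NULL
  m
}

#' Convert a mm coordinate to a voxel index
#'
#' Applies the inverse affine of the grid and rounds to the nearest lattice
#' point (ties rounded half away from zero). Coordinates falling outside the
#' grid after rounding are an error, never clipped.
#'
#' @param coord_mm numeric(3) mm coordinate.
#' @param grid a [grid_spec()].
#' @return integer(3) 0-based voxel index.
#' @export
mm_to_voxel <- function(coord_mm, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  coord_mm <- as.numeric(coord_mm)
  stopifnot(length(coord_mm) == 3L)
  v <- solve(grid$affine[, 1:3], coord_mm - grid$affine[, 4])
  # round half away from zero, deterministically
  idx <- as.integer(trunc(v + 0.5 * sign(v)))
  if (any(idx < 0L) || any(idx >= grid$dims))
    stop(sprintf("coordinate outside grid: (%s) -> voxel (%s)",
                 paste(coord_mm, collapse = ", "),
                 paste(idx, collapse = ", ")))
  idx
}

# linear (1-based) indices of 0-based mask rows into a grid array; errors when
# any voxel falls outside the grid
mask_linear_index <- function(mask, grid) {
  if (any(mask < 0L) || any(t(mask) >= grid$dims))
    stop("mask exceeds grid: at least one mask voxel lies outside the grid")
  1L + mask[, 1] + grid$dims[1] * (mask[, 2] + grid$dims[2] * mask[, 3])
}

#' Extract an ROI activity pattern from a voxel map
#'
#' Returns the map values at the mask voxels, in mask order. A mask that
#' straddles the grid boundary is an error (silent truncation would change the
#' pattern dimensionality between subject sets).
#'
#' @param map a [voxel_map()].
#' @param mask integer matrix of 0-based voxel coordinates, as produced by
#'   [build_roi_mask()].
#' @return numeric vector, one value per mask voxel.
#' @export
extract_pattern <- function(map, mask) {
  stopifnot(inherits(map, "voxel_map"))
  as.numeric(map$values)[mask_linear_index(mask, map$grid)]
}

#' The packaged ROI peak table
#'
#' Twenty-three ROI peak coordinates (MNI mm) with their source partition:
#' ids 1-4 a priori (persuasion-network literature), 5-14 exploratory (peaks
#' of highest between-participant variability in the MSVxAS contrast), 15-23
#' confirmatory (MSVxAS peaks in the high drug-risk group).
#'
#' @param path optional path to an alternative TSV with columns
#'   `id source x y z label`.
#' @return data.frame with columns id, source, x, y, z, label.
#' @export
idsim_roi_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "roi_table.tsv", package = "idsim",
                        mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "source", "x", "y", "z", "label")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("ROI table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("ROI table ids must be unique")
  bad <- setdiff(unique(tab$source),
                 c("a_priori", "exploratory", "confirmatory"))
  if (length(bad))
    stop("unknown ROI source(s): ", paste(bad, collapse = ", "))
  tab[required]
}

#' Read and write voxel maps
#'
#' Two on-disk representations are supported: NIfTI-1 (affine taken from the
#' header xform) and a plain-text pair of a TSV value file plus a JSON sidecar
#' holding `dims`, `voxel_size` and the 3x4 `affine` (no orientation is ever
#' guessed for plain matrices).
#'
#' @param path file to read or write (`.nii`/`.nii.gz`, or the TSV file; the
#'   sidecar shares the basename with extension `.json`).
#' @param subject_id,map_kind metadata attached to the returned map.
#' @param map a [voxel_map()] to write.
#' @return `read_voxel_map()` returns a [voxel_map()]; writers return `path`
#'   invisibly.
#' @name voxel_map_io
NULL

#' @rdname voxel_map_io
#' @export
read_voxel_map_nifti <- function(path, subject_id, map_kind) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)              # 4x4, mm = xf %*% c(vox0, 1)
  d <- dim(img)
  grid <- grid_spec(dims = d[1:3],
                    voxel_size = sqrt(colSums(xf[1:3, 1:3]^2)),
                    affine = xf[1:3, , drop = FALSE])
  voxel_map(subject_id, map_kind, grid, as.numeric(img))
}

#' @rdname voxel_map_io
#' @export
write_voxel_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  img <- RNifti::asNifti(map$values)
  xf <- rbind(map$grid$affine, c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname voxel_map_io
#' @export
read_voxel_map_tsv <- function(path, subject_id, map_kind) {
  sidecar <- sub("\\.tsv$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- grid_spec(meta$dims, meta$voxel_size,
                    affine = matrix(unlist(meta$affine), 3L, 4L, byrow = TRUE))
  vals <- scan(path, what = numeric(), quiet = TRUE)
  voxel_map(subject_id, map_kind, grid, vals)
}

#' @rdname voxel_map_io
#' @export
write_voxel_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  writeLines(format(as.numeric(map$values), trim = TRUE, digits = 15), path)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(dims = map$grid$dims, voxel_size = map$grid$voxel_size,
         affine = as.numeric(t(map$grid$affine))),  # row-major, 12 values
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
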