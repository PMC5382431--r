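#' Regular 3-D dose grid
#'
#' A rectilinear scalar field of physical dose in Gy with spatial metadata.
#' World coordinates follow the voxel-centre convention: the centre of voxel
#' \code{(i, j, k)} (1-based array index) lies at
#' \code{origin + (index - 1) * spacing}.
#'
#' @param values 3-D numeric array of dose in Gy, all values >= 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param spacing numeric length-3, positive voxel spacing in mm.
#' @param frame_id character label of the reference frame; grids are
#'   co-registered iff \code{frame_id}, \code{origin}, \code{spacing} and
#'   \code{dim} all agree.
#' @return An object of class \code{"dose_grid"}.
#' @export
dose_grid <- function(values, spacing = c(1.5, 1.5, 1.5),
                      origin = c(0, 0, 0), frame_id = "ref") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (any(values < 0)) stop("dose values must be non-negative")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (mm)")
  if (length(origin) != 3L) stop("'origin' must be length 3")
  structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing), dim = dim(values),
         frame_id = as.character(frame_id)),
    class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm, frame '%s'\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(format(x$spacing), collapse = " x "), x$frame_id))
  cat(sprintf("  dose range [%.2f, %.2f] Gy\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Voxel volume of a grid, in cc
#'
#' One cc is 1000 mm^3; spacings are in mm.
#' @param grid a \code{dose_grid} (or any object with a \code{spacing} field).
#' @return voxel volume in cc.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

frame_key <- function(g) {
  paste(g$frame_id, paste(g$origin, collapse = ","),
        paste(g$spacing, collapse = ","), paste(g$dim, collapse = ","),
        sep = "|")
}

#' Test whether two grids share one frame
#' @param a,b grid-like objects (\code{dose_grid}, \code{eqd2_grid} or
#'   \code{structure_mask}).
#' @return logical.
#' @export
co_registered <- function(a, b) identical(frame_key(a), frame_key(b))

stop_if_unregistered <- function(a, b) {
  if (!co_registered(a, b))
    stop("grids are not co-registered; resample to a common frame upstream ",
         "(silent resampling is never performed)")
  invisible(TRUE)
}

#' Structure mask on a grid frame
#'
#' Stores the linear indices of member voxels together with the frame
#' metadata of the grid the mask was drawn on.
#'
#' @param name structure label, e.g. \code{"GTV"} or \code{"rib_3"}.
#' @param member_idx integer vector of linear voxel indices into the grid
#'   array (may be empty only if \code{allow_empty}).
#' @param grid the grid supplying frame metadata.
#' @param allow_empty allow an empty mask (default \code{FALSE}).
#' @return An object of class \code{"structure_mask"}.
#' @export
structure_mask <- function(name, member_idx, grid, allow_empty = FALSE) {
  member_idx <- as.integer(member_idx)
  if (!allow_empty && length(member_idx) == 0L)
    stop("mask '", name, "' is empty")
  if (length(member_idx) && (min(member_idx) < 1L ||
                             max(member_idx) > prod(grid$dim)))
    stop("mask indices outside the grid")
  structure(
    list(name = as.character(name), member_idx = sort(member_idx),
         origin = grid$origin, spacing = grid$spacing, dim = grid$dim,
         frame_id = grid$frame_id),
    class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.3f cc, frame '%s'\n",
              x$name, length(x$member_idx), mask_volume_cc(x), x$frame_id))
  invisible(x)
}

#' Mask volume in cc
#' @param mask a \code{structure_mask}.
#' @return volume in cc (member-voxel count times voxel volume).
#' @export
mask_volume_cc <- function(mask) length(mask$member_idx) * voxel_volume_cc(mask)

# linear index -> 1-based (i, j, k) triples
idx_to_ijk <- function(idx, dims) {
  idx0 <- idx - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

#' World coordinates (mm) of a mask's voxel centres
#' @param mask a \code{structure_mask}.
#' @return numeric matrix, one row per member voxel, columns x/y/z in mm.
#' @export
mask_coords <- function(mask) {
  ijk <- idx_to_ijk(mask$member_idx, mask$dim)
  sweep(sweep(ijk - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# surface voxels: members with at least one non-member 6-neighbour
# (grid-boundary faces count as non-member)
surface_idx <- function(mask) {
  d <- mask$dim
  inside <- logical(prod(d))
  inside[mask$member_idx] <- TRUE
  ijk <- idx_to_ijk(mask$member_idx, d)
  has_out <- logical(nrow(ijk))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(6)) {
    nb <- sweep(ijk, 2, offs[r, ], "+")
    oob <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
    lin[oob] <- 1L                       # placeholder, overridden below
    out <- !inside[lin]
    out[oob] <- TRUE
    has_out <- has_out | out
  }
  mask$member_idx[has_out]
}
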