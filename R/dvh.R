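#' Sweep grids for the D_V and V_D metric families
#'
#' Volumes from 0.1 to 5 cc in 0.1 cc steps plus 6 to 10 cc in 1 cc steps
#' (55 points); doses from 50 to 300 Gy EQD2 in 10 Gy steps (26 points).
#' @return numeric vector of grid points.
#' @export
dv_volume_grid <- function() c(seq(0.1, 5, by = 0.1), 6:10)

#' @rdname dv_volume_grid
#' @export
vd_dose_grid <- function() seq(50, 300, by = 10)

# shared constructor: cumulative DVH from member-voxel EQD2 values
dvh_from_values <- function(values, voxel_cc, structure = "structure",
                            bin_width = 0.1) {
  if (!length(values)) stop("empty structure: no voxels to histogram")
  d_max <- max(values)
  edges <- seq(0, (floor(d_max / bin_width) + 1) * bin_width, by = bin_width)
  # voxels with value >= edge, per edge
  counts <- length(values) -
    findInterval(edges, sort(values), left.open = TRUE)
  structure(
    list(structure = structure, bin_edges = edges,
         volume_at_or_above = counts * voxel_cc,
         total_volume = length(values) * voxel_cc,
         d_max = d_max, bin_width = bin_width),
    class = "cum_dvh")
}

#' Cumulative absolute-volume DVH
#'
#' For each dose edge \code{e}, the absolute volume (cc) of structure voxels
#' with EQD2 >= \code{e}: member-voxel count times voxel volume, no
#' partial-volume weighting.  \code{d_max} is the exact voxel maximum
#' (maximum point dose), stored separately from the binned curve.
#'
#' @param eqd2_grid an \code{eqd2_grid} (a \code{dose_grid} is also accepted;
#'   the curve is then in physical Gy).
#' @param mask non-empty \code{structure_mask} on the same frame.
#' @param bin_width uniform bin width in Gy (default 0.1).
#' @return An object of class \code{"cum_dvh"}.
#' @export
cumulative_dvh <- function(eqd2_grid, mask, bin_width = 0.1) {
  stop_if_unregistered(eqd2_grid, mask)
  if (!length(mask$member_idx)) stop("empty mask")
  dvh_from_values(eqd2_grid$values[mask$member_idx], voxel_volume_cc(mask),
                  structure = mask$name, bin_width = bin_width)
}

#' @export
print.cum_dvh <- function(x, ...) {
  cat(sprintf("<cum_dvh> '%s': %.2f cc total, D_max %.2f Gy, bin %.2g Gy\n",
              x$structure, x$total_volume, x$d_max, x$bin_width))
  invisible(x)
}

#' @export
plot.cum_dvh <- function(x, ...) {
  graphics::plot(x$bin_edges, x$volume_at_or_above, type = "s",
                 xlab = "EQD2 (Gy)", ylab = "Volume (cc)",
                 main = x$structure, ...)
  invisible(x)
}

#' Dose to the hottest V cc (D_V)
#'
#' The smallest dose whose at-or-above volume is <= \code{v}, refined by
#' linear interpolation between the bracketing DVH edges and capped at
#' \code{d_max}.
#'
#' @param dvh a \code{cum_dvh}.
#' @param v volume in cc, 0 < v <= total structure volume.
#' @return dose in Gy.
#' @export
dose_at_volume <- function(dvh, v) {
  if (v <= 0) stop("'v' must be > 0")
  if (v > dvh$total_volume + 1e-12)
    stop("requested volume ", v, " cc exceeds structure volume ",
         dvh$total_volume, " cc")
  vol <- dvh$volume_at_or_above
  e <- dvh$bin_edges
  i <- which(vol < v)[1]             # exists: the last edge has volume 0
  if (is.na(i) || i == 1L) return(min(e[1], dvh$d_max))
  v_hi <- vol[i - 1]                  # >= v
  v_lo <- vol[i]                      # < v
  d <- e[i - 1] + (v_hi - v) / (v_hi - v_lo) * (e[i] - e[i - 1])
  min(d, dvh$d_max)
}

#' Volume receiving at least dose D (V_D)
#'
#' Linear interpolation of the cumulative curve; \code{0} above
#' \code{d_max}, the total volume at 0 Gy.
#'
#' @param dvh a \code{cum_dvh}.
#' @param d dose in Gy, >= 0.
#' @return volume in cc.
#' @export
volume_at_dose <- function(dvh, d) {
  if (d < 0) stop("'d' must be >= 0")
  if (d > dvh$d_max) return(0)
  if (d <= 0) return(dvh$total_volume)
  stats::approx(dvh$bin_edges, dvh$volume_at_or_above, xout = d,
                rule = 2)$y
}

#' Full D_V / V_D metric sweep of one DVH
#'
#' Evaluates \code{\link{dose_at_volume}} on the 55-point volume grid
#' (points exceeding the structure volume are recorded as \code{NA}) and
#' \code{\link{volume_at_dose}} on the 26-point dose grid, plus
#' \code{d_max}.
#'
#' @param dvh a \code{cum_dvh}.
#' @return An object of class \code{"metric_family"}: list with named
#'   numeric vectors \code{dv} (names \code{"D_0.1cc"} ...), \code{vd}
#'   (names \code{"V_50"} ...) and scalar \code{d_max}.
#' @export
metric_sweep <- function(dvh) {
  vg <- dv_volume_grid()
  dg <- vd_dose_grid()
  dv <- vapply(vg, function(v) {
    if (v > dvh$total_volume) NA_real_ else dose_at_volume(dvh, v)
  }, 0)
  vd <- vapply(dg, function(d) volume_at_dose(dvh, d), 0)
  names(dv) <- paste0("D_", format_cc(vg), "cc")
  names(vd) <- paste0("V_", dg)
  structure(list(dv = dv, vd = vd, d_max = dvh$d_max),
            class = "metric_family")
}

format_cc <- function(v) ifelse(v == round(v), as.character(round(v)),
                                sprintf("%.1f", v))

#' One-row data frame of a metric family
#' @param family a \code{metric_family}.
#' @return data frame with columns \code{D_max}, \code{D_0.1cc} ...,
#'   \code{V_50} ...
#' @export
metric_row <- function(family) {
  as.data.frame(c(list(D_max = family$d_max), as.list(family$dv),
                  as.list(family$vd)), check.names = FALSE)
}
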