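#' Fraction schedule
#'
#' Total prescribed dose and the number of fractions it is delivered in.
#'
#' @param total_dose total dose in Gy at the prescription point, > 0.
#' @param n_fractions number of fractions, >= 1.
#' @return An object of class \code{"fraction_schedule"}.
#' @export
fraction_schedule <- function(total_dose, n_fractions) {
  if (total_dose <= 0) stop("'total_dose' must be > 0")
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("'n_fractions' must be a positive integer")
  structure(list(total_dose = total_dose, n_fractions = as.integer(n_fractions)),
            class = "fraction_schedule")
}

#' Equivalent dose in 2-Gy fractions (linear-quadratic model)
#'
#' \code{EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)} with \code{d} the
#' dose per fraction.  For late-responding bone such as rib the conventional
#' alpha/beta ratio is 3 Gy.  Vectorised over \code{total_dose}.
#'
#' @param total_dose total physical dose D in Gy (voxel dose or prescription).
#' @param n_fractions number of fractions the dose is split into.
#' @param alpha_beta tissue alpha/beta ratio in Gy (default 3, rib).
#' @return EQD2 in Gy, same shape as \code{total_dose}.
#' @examples
#' eqd2(41.7, 3)        # ~ 141 Gy, the 140 Gy cutoff at 10 Gy resolution
#' eqd2(60, 3)          # 276 Gy
#' eqd2(50, 25)         # 50 Gy: 2 Gy/fraction is the fixed point
#' @export
eqd2 <- function(total_dose, n_fractions, alpha_beta = 3) {
  if (alpha_beta <= 0) stop("'alpha_beta' must be > 0")
  if (n_fractions < 1) stop("'n_fractions' must be >= 1")
  if (any(total_dose < 0)) stop("dose must be non-negative")
  d <- total_dose / n_fractions
  total_dose * (d + alpha_beta) / (2 + alpha_beta)
}

#' Convert a physical dose grid to EQD2
#'
#' Applies the linear-quadratic conversion voxel-wise, with each voxel's own
#' per-fraction dose \code{d = D_voxel / n_fractions} (the standard DVH
#' practice, preserving the radiobiological weighting of the dose gradient).
#' Setting \code{per_voxel_fraction = FALSE} instead scales every voxel by
#' the factor implied by the prescription per-fraction dose.
#'
#' @param dose a \code{dose_grid} of physical dose for one course.
#' @param schedule a \code{fraction_schedule}.
#' @param alpha_beta alpha/beta ratio in Gy (default 3).
#' @param per_voxel_fraction logical; see Details.
#' @param course_id label recorded in the provenance of the result.
#' @return An object of class \code{"eqd2_grid"} with the same spatial
#'   metadata, an \code{alpha_beta} field and a \code{provenance} list of
#'   contributing course ids.
#' @export
eqd2_convert <- function(dose, schedule, alpha_beta = 3,
                         per_voxel_fraction = TRUE, course_id = "course1") {
  stopifnot(inherits(dose, "dose_grid"), inherits(schedule, "fraction_schedule"))
  if (any(dose$values < 0)) stop("negative dose voxel")
  n <- schedule$n_fractions
  if (per_voxel_fraction) {
    vals <- eqd2(dose$values, n, alpha_beta)
  } else {
    d_rx <- schedule$total_dose / n
    vals <- dose$values * (d_rx + alpha_beta) / (2 + alpha_beta)
  }
  structure(
    list(values = vals, origin = dose$origin, spacing = dose$spacing,
         dim = dose$dim, frame_id = dose$frame_id,
         alpha_beta = alpha_beta, provenance = list(course_id)),
    class = "eqd2_grid")
}

#' @export
print.eqd2_grid <- function(x, ...) {
  cat(sprintf(
    "<eqd2_grid> %d x %d x %d voxels, alpha/beta %.1f Gy, %d course(s)\n",
    x$dim[1], x$dim[2], x$dim[3], x$alpha_beta, length(x$provenance)))
  cat(sprintf("  EQD2 range [%.2f, %.2f] Gy\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Sum EQD2 grids of multiple courses
#'
#' Voxel-wise addition of co-registered EQD2 grids (multi-course dose
#' summation on fused images, no time-gap recovery factor).  Grids on
#' different frames are rejected, never silently resampled.
#'
#' @param courses list of \code{eqd2_grid} objects on one frame.
#' @return An \code{eqd2_grid} whose provenance concatenates the inputs'.
#' @export
sum_courses <- function(courses) {
  if (!length(courses)) stop("no courses to sum")
  stopifnot(all(vapply(courses, inherits, TRUE, "eqd2_grid")))
  ref <- courses[[1]]
  for (g in courses[-1]) stop_if_unregistered(ref, g)
  ab <- unique(vapply(courses, `[[`, 0, "alpha_beta"))
  if (length(ab) > 1) stop("courses use different alpha/beta ratios")
  vals <- ref$values
  for (g in courses[-1]) vals <- vals + g$values
  out <- ref
  out$values <- vals
  out$provenance <- do.call(c, lapply(courses, `[[`, "provenance"))
  out
}

#' Select ribs irradiated above an EQD2 threshold
#'
#' Returns, in input order, the ribs containing at least one voxel with
#' EQD2 at or above \code{threshold} (default 10 Gy, the contouring rule for
#' ribs at risk).
#'
#' @param eqd2_grid an \code{eqd2_grid}.
#' @param ribs list of \code{structure_mask} on the same frame.
#' @param threshold EQD2 threshold in Gy.
#' @return sub-list of \code{ribs}; empty list if none qualify.
#' @export
select_irradiated_ribs <- function(eqd2_grid, ribs, threshold = 10) {
  if (!length(ribs)) return(list())
  for (r in ribs) stop_if_unregistered(eqd2_grid, r)
  keep <- vapply(ribs, function(r) {
    any(eqd2_grid$values[r$member_idx] >= threshold)
  }, TRUE)
  ribs[keep]
}

#' Are two lesions dosimetrically separable?
#'
#' Two lesions are analysed separately only when no single rib receives the
#' threshold EQD2 (default 10 Gy) from both; otherwise their courses must be
#' merged with \code{\link{sum_courses}} before rib metrics are computed.
#'
#' @param eqd2_a,eqd2_b \code{eqd2_grid}s of the two lesions, co-registered.
#' @param ribs list of rib \code{structure_mask}s.
#' @param threshold EQD2 threshold in Gy.
#' @return logical: \code{TRUE} iff no rib is shared above threshold.
#' @export
lesions_separable <- function(eqd2_a, eqd2_b, ribs, threshold = 10) {
  stop_if_unregistered(eqd2_a, eqd2_b)
  a <- select_irradiated_ribs(eqd2_a, ribs, threshold)
  b <- select_irradiated_ribs(eqd2_b, ribs, threshold)
  !any(vapply(a, `[[`, "", "name") %in% vapply(b, `[[`, "", "name"))
}

#' Minimum rib-tumor distance
#'
#' Minimum Euclidean distance, in cm, between any GTV surface-voxel centre
#' and any rib surface-voxel centre; 0 when the masks touch or overlap
#' (shared voxels).
#'
#' @param gtv GTV \code{structure_mask} (non-empty).
#' @param ribs list of rib \code{structure_mask}s (at least one).
#' @return distance in cm.
#' @export
rib_tumor_distance <- function(gtv, ribs) {
  if (!length(gtv$member_idx)) stop("empty GTV")
  if (!length(ribs)) stop("at least one rib required")
  rib_idx <- unlist(lapply(ribs, function(r) {
    stop_if_unregistered(gtv, r)
    r$member_idx
  }))
  if (any(gtv$member_idx %in% rib_idx)) return(0)
  g <- gtv; g$member_idx <- surface_idx(gtv)
  gc_ <- mask_coords(g)
  best <- Inf
  for (r in ribs) {
    rs <- r; rs$member_idx <- surface_idx(r)
    rc <- mask_coords(rs)
    # chunk over rib voxels to bound the distance-matrix size
    step <- max(1L, floor(2e6 / max(1, nrow(gc_))))
    for (s in seq(1, nrow(rc), by = step)) {
      e <- min(nrow(rc), s + step - 1)
      d2 <- outer(rowSums(gc_^2), rowSums(rc[s:e, , drop = FALSE]^2), "+") -
        2 * gc_ %*% t(rc[s:e, , drop = FALSE])
      best <- min(best, min(d2))
    }
  }
  sqrt(max(best, 0)) / 10   # mm -> cm
}
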