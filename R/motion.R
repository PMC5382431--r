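# 10-phase respiratory dose emulation: phase binning of a periodic trace,
# per-phase rigid dose displacement, fiducial registration, accumulation.

#' Periodic respiratory trace
#'
#' A rigid-translation breathing model for the tumor/fiducial complex: per
#' axis, displacement(t) = amplitude * w(t) with w a periodic waveform in
#' [0, 1] (\code{"cos4"}: cos^4(pi t / period), the typical
#' spends-longer-at-exhale shape) or [-1, 1] (\code{"sin"}).
#'
#' @param period seconds (default 4).
#' @param amplitude mm per axis, SI/AP/LR order (default 5, 2, 1 mm).
#' @param waveform \code{"cos4"} or \code{"sin"}.
#' @return object of class \code{"resp_trace"} with a \code{displacement(t)}
#'   function (rows = times, cols = axes).
#' @export
respiratory_trace <- function(period = 4, amplitude = c(5, 2, 1),
                              waveform = c("cos4", "sin")) {
  waveform <- match.arg(waveform)
  stopifnot(period > 0, length(amplitude) == 3, all(amplitude >= 0))
  w <- switch(waveform,
              cos4 = function(t) cos(pi * t / period)^4,
              sin = function(t) sin(2 * pi * t / period))
  structure(
    list(period = period, amplitude = amplitude, waveform = waveform,
         displacement = function(t) outer(w(t), amplitude)),
    class = "resp_trace")
}

#' Bin one breathing period into phase displacements
#'
#' Phase-angle binning: one period is split into \code{n_phases} equal time
#' bins and the per-phase displacement is the mean trace displacement
#' within the bin (numerical quadrature with \code{n_sub} samples per bin).
#'
#' @param trace a \code{\link{respiratory_trace}}.
#' @param n_phases number of phases (default 10).
#' @param n_sub quadrature samples per bin.
#' @return numeric matrix \code{n_phases x 3} of mm displacements.
#' @export
bin_phases <- function(trace, n_phases = 10, n_sub = 200) {
  stopifnot(inherits(trace, "resp_trace"), n_phases >= 1)
  t(vapply(seq_len(n_phases), function(p) {
    t0 <- (p - 1) / n_phases * trace$period
    tt <- t0 + (seq_len(n_sub) - 0.5) / n_sub * trace$period / n_phases
    colMeans(trace$displacement(tt))
  }, numeric(3)))
}

# integer-offset array shift with zero padding
shift_int <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) { dst[[a]] <- (1 + o):d[a]; src[[a]] <- 1:(d[a] - o) }
    else       { dst[[a]] <- 1:(d[a] + o); src[[a]] <- (1 - o):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# translate a grid's values by a world shift (mm) with trilinear
# interpolation; exact lattice copy for integer-voxel shifts
translate_values <- function(vals, spacing, shift_mm) {
  f <- shift_mm / spacing
  i0 <- floor(f)
  fr <- f - i0
  out <- 0
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    w <- (if (bx) fr[1] else 1 - fr[1]) *
      (if (by) fr[2] else 1 - fr[2]) *
      (if (bz) fr[3] else 1 - fr[3])
    if (w == 0) next
    out <- out + w * shift_int(vals, c(i0[1] + bx, i0[2] + by, i0[3] + bz))
  }
  out
}

#' Per-phase dose grid under rigid tumor motion
#'
#' With \code{tracking = TRUE} the delivery follows the tumor, so in the
#' static rib frame the dose cloud is translated by the tumor displacement;
#' with \code{tracking = FALSE} the dose stays fixed in the room frame and
#' the displacement is ignored.  Resampling is trilinear with zero padding
#' (a warning is raised when dose is pushed off the grid support); a zero
#' or integer-voxel displacement is an exact lattice copy.
#'
#' @param planned a \code{dose_grid} (the 3D planning dose).
#' @param displacement mm triple, tumor displacement for this phase.
#' @param tracking logical (default TRUE).
#' @return a \code{dose_grid}.
#' @export
phase_dose <- function(planned, displacement, tracking = TRUE) {
  stopifnot(inherits(planned, "dose_grid"), length(displacement) == 3)
  if (!tracking || all(displacement == 0)) return(planned)
  vals <- translate_values(planned$values, planned$spacing, displacement)
  lost <- 1 - sum(vals) / sum(planned$values)
  if (lost > 1e-6)
    warning(sprintf("%.3g%% of integral dose shifted off the grid (zero pad)",
                    100 * lost), call. = FALSE)
  out <- planned
  out$values <- vals
  out
}

#' Rigid (translation-only) fiducial registration
#'
#' Least-squares translation aligning a phase's fiducials to the reference:
#' the per-axis mean of the pairwise differences \code{ref - phase}.
#'
#' @param fiducials_phase,fiducials_ref n x 3 matrices of matched fiducial
#'   coordinates (mm), same row order.
#' @return object of class \code{"rigid_transform"} with a
#'   \code{translation} mm triple.
#' @export
register_phase <- function(fiducials_phase, fiducials_ref) {
  fp <- rbind(fiducials_phase); fr <- rbind(fiducials_ref)
  if (nrow(fp) != nrow(fr)) stop("mismatched fiducial counts")
  if (!nrow(fp)) stop("at least one fiducial pair required")
  structure(list(translation = colMeans(fr - fp)), class = "rigid_transform")
}

#' Build a 10-phase set for one lesion
#'
#' Bins the trace, produces per-phase dose grids and fiducial positions
#' (fiducials ride with the tumor), with uniform phase weights.
#'
#' @param planned the 3D planning \code{dose_grid}.
#' @param trace a \code{\link{respiratory_trace}}.
#' @param fiducials_ref n x 3 matrix of fiducial positions at reference
#'   (mm); defaults to a single marker at the grid centre.
#' @param n_phases number of phases (default 10).
#' @param tracking see \code{\link{phase_dose}}.
#' @return object of class \code{"phase_set"}: per-phase \code{dose},
#'   \code{fiducials}, \code{displacement}; \code{weights} summing to 1.
#' @export
make_phase_set <- function(planned, trace, fiducials_ref = NULL,
                           n_phases = 10, tracking = TRUE) {
  if (is.null(fiducials_ref))
    fiducials_ref <- rbind(planned$origin + (planned$dim - 1) *
                             planned$spacing / 2)
  disp <- bin_phases(trace, n_phases)
  phases <- lapply(seq_len(n_phases), function(p) {
    list(index = p - 1L,
         dose = phase_dose(planned, disp[p, ], tracking),
         fiducials = sweep(fiducials_ref, 2, disp[p, ], "+"),
         displacement = disp[p, ])
  })
  structure(list(phases = phases, weights = rep(1 / n_phases, n_phases),
                 fiducials_ref = fiducials_ref, tracking = tracking),
            class = "phase_set")
}

#' Accumulate a phase set into a cumulative dose grid
#'
#' Each phase dose is resampled through its rigid transform into the
#' reference frame (trilinear) and the phase-weighted sum is returned.
#' With transforms from perfect fiducial registration, tracked delivery of
#' a rigidly moving target accumulates back to the planned dose.
#'
#' @param phase_set a \code{\link{make_phase_set}} result.
#' @param transforms list of \code{rigid_transform}, one per phase; default
#'   registers each phase's fiducials to the reference set.
#' @return a \code{dose_grid} of cumulative physical dose.
#' @export
accumulate_phases <- function(phase_set, transforms = NULL) {
  ph <- phase_set$phases
  if (length(ph) != length(phase_set$weights)) stop("missing phase")
  if (is.null(transforms))
    transforms <- lapply(ph, function(p)
      register_phase(p$fiducials, phase_set$fiducials_ref))
  if (length(transforms) != length(ph)) stop("one transform per phase required")
  ref <- ph[[1]]$dose
  # zero-motion shortcut keeps the 4D pipeline bit-identical to 3D
  zero <- all(vapply(transforms, function(t) all(t$translation == 0), TRUE)) &&
    all(vapply(ph, function(p) identical(p$dose$values, ref$values), TRUE))
  if (zero && isTRUE(all.equal(sum(phase_set$weights), 1))) return(ref)
  vals <- 0
  for (p in seq_along(ph)) {
    tr <- transforms[[p]]$translation
    v <- if (all(tr == 0)) ph[[p]]$dose$values else
      translate_values(ph[[p]]$dose$values, ref$spacing, tr)
    vals <- vals + phase_set$weights[p] * v
  }
  out <- ref
  out$values <- vals
  out
}

#' Compare 3D planning and 4D accumulated rib metrics
#'
#' For each lesion of a (small) synthetic cohort: computes the rib metric
#' family from the 3D planning dose and from the 10-phase accumulated dose
#' (EQD2 conversion applied after physical-dose accumulation), then a
#' paired t-test per requested metric.
#'
#' @param cohort a \code{synthetic_cohort} (metrics need not be filled).
#' @param metrics character vector of metric columns to compare.
#' @param trace a \code{\link{respiratory_trace}}.
#' @param tracking logical, tumor-tracking delivery (default TRUE).
#' @param lesion_idx lesion rows to process (default all).
#' @param threshold rib-contouring EQD2 threshold (Gy).
#' @return list: \code{table} (per-lesion 3D and 4D values),
#'   \code{tests} (one \code{paired_comparison} per metric).  Lesions with
#'   either arm missing are dropped with a warning.
#' @export
compare_3d_4d <- function(cohort, metrics = c("D_4.6cc", "V_160"),
                          trace = respiratory_trace(), tracking = TRUE,
                          lesion_idx = seq_len(nrow(cohort$lesions)),
                          threshold = 10) {
  cf <- cohort$config
  rib_union_metrics <- function(grid_vals, lesion) {
    ed <- eqd2(grid_vals, lesion$n_fractions)
    per_rib <- lapply(cohort$ribs, function(r) ed[r$member_idx])
    sel <- vapply(per_rib, max, 0) >= threshold
    if (!any(sel)) return(NULL)
    metric_row(metric_sweep(dvh_from_values(
      unlist(per_rib[sel]), prod(cf$grid$spacing) / 1000)))
  }
  rows <- list()
  for (i in lesion_idx) {
    l <- cohort$lesions[i, ]
    planned <- lesion_dose_grid(cohort, i)$dose
    ps <- make_phase_set(planned, trace,
                         fiducials_ref = rbind(c(l$cx, l$cy, l$cz)),
                         tracking = tracking)
    acc <- accumulate_phases(ps)
    m3 <- rib_union_metrics(planned$values, l)
    m4 <- rib_union_metrics(acc$values, l)
    if (is.null(m3) || is.null(m4) ||
        anyNA(m3[metrics]) || anyNA(m4[metrics])) {
      warning("lesion ", l$lesion_id, " lacks one arm; excluded",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lesion_id = l$lesion_id,
      stats::setNames(m3[metrics], paste0(metrics, "_3d")),
      stats::setNames(m4[metrics], paste0(metrics, "_4d")),
      check.names = FALSE)
  }
  if (!length(rows)) stop("no lesion has both arms")
  tab <- do.call(rbind, rows)
  tests <- lapply(metrics, function(m)
    paired_ttest(tab[[paste0(m, "_3d")]], tab[[paste0(m, "_4d")]], metric = m))
  names(tests) <- metrics
  list(table = tab, tests = tests)
}
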