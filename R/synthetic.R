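# Synthetic SABR lung cohort: dose grids, rib cage, covariates, outcomes.
# Everything is driven by one integer seed; regenerating with the same
# (config, seed) gives a bit-identical cohort.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Grid specification for synthetic dose grids
#'
#' @param dim voxel counts per axis (default 128^3).
#' @param spacing voxel spacing in mm (default 1.5 isotropic).
#' @param origin world position of the first voxel centre (mm).
#' @param frame_id frame label shared by all synthetic grids.
#' @return list with the grid metadata.
#' @export
grid_spec <- function(dim = c(128L, 128L, 128L), spacing = c(1.5, 1.5, 1.5),
                      origin = c(0, 0, 0), frame_id = "synth") {
  if (any(spacing <= 0)) stop("spacing must be positive")
  list(dim = as.integer(dim), spacing = as.numeric(spacing),
       origin = as.numeric(origin), frame_id = frame_id)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a SABR lung cohort: 49 lesions in 39
#' patients, 45-66 Gy in 3-6 fractions prescribed to the 80% isodose line,
#' log-normal GTV volumes with median 5.90 cc, near-exponential rib-tumor
#' distances with median 0.25 cm, fracture hazard increasing with rib dose
#' and follow-up with median 26.7 months.
#'
#' @param n_patients,n_lesions cohort size (lesions >= patients).
#' @param prescription_range total-dose range in Gy, within [45, 66].
#' @param fraction_choices admissible fraction numbers, subset of 3:6.
#' @param fraction_weights sampling weights for \code{fraction_choices}.
#' @param isodose_prescription_fraction prescription isodose level (0.8:
#'   the hot spot is prescription / 0.8).
#' @param gtv_volume_log_median,gtv_volume_sdlog log-normal GTV volume
#'   parameters (cc); the median is \code{gtv_volume_log_median}.
#' @param rib_distance_median_cm median of the rib-tumor distance
#'   distribution (cm).
#' @param zero_distance_fraction probability that a lesion abuts or invades
#'   the chest wall (recorded distance 0.00 cm); the remaining distances
#'   are exponential with the rate that keeps the configured overall
#'   median.  Must be < 0.5.
#' @param embed_depth_mm range of the chest-wall embed depth (mm) of
#'   zero-distance lesions (how far the GTV presses into the rib plane).
#' @param ptv_margin_mm GTV-to-PTV margin in mm (default 4, the midpoint of
#'   a 3-5 mm planning margin).
#' @param falloff_per_mm fractional dose falloff per mm outside the PTV
#'   (default 0.05, a typical clinical SABR penumbra gradient; dose at
#'   1 cm from the PTV surface is then ~60% of prescription).
#' @param male_fraction,middle_lower_fraction,dm_fraction,copd_fraction
#'   covariate marginals.
#' @param followup_median_months,followup_sdlog,followup_range_months
#'   log-normal censoring-time parameters (months), clamped to the range.
#' @param hazard baseline Weibull scale (months) and shape, log-hazard
#'   slope per Gy of the driving metric above \code{threshold} (Gy EQD2),
#'   and the driving metric name.
#' @param incidence_band_2yr declared plausibility band for the 2-year
#'   actuarial fracture incidence of a default cohort (calibration check).
#' @param grid a \code{\link{grid_spec}}.
#' @param rib_count,rib_radius_mm,rib_pitch_mm,chest_wall_x_mm rib-cage
#'   geometry.
#' @param seed integer seed; every random draw flows from it.
#' @return list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_patients = 39L, n_lesions = 49L,
                          prescription_range = c(45, 66),
                          fraction_choices = 3:6,
                          fraction_weights = c(0.45, 0.2, 0.2, 0.15),
                          isodose_prescription_fraction = 0.8,
                          gtv_volume_log_median = 5.90,
                          gtv_volume_sdlog = 1.1,
                          rib_distance_median_cm = 0.25,
                          zero_distance_fraction = 0.30,
                          embed_depth_mm = c(4, 12),
                          ptv_margin_mm = 4,
                          falloff_per_mm = 0.05,
                          male_fraction = 0.59,
                          middle_lower_fraction = 0.612,
                          dm_fraction = 0.224,
                          copd_fraction = 0.184,
                          followup_median_months = 26.7,
                          followup_sdlog = 0.55,
                          followup_range_months = c(6, 84),
                          hazard = list(scale = 150, shape = 1.5,
                                        slope = 0.04, threshold = 140,
                                        metric = "D_4.6cc"),
                          incidence_band_2yr = c(0.02, 0.35),
                          grid = grid_spec(),
                          rib_count = 8L, rib_radius_mm = 6,
                          rib_pitch_mm = 16, chest_wall_x_mm = 150,
                          seed = 1234L) {
  stopifnot(prescription_range[1] >= 45, prescription_range[2] <= 66,
            all(fraction_choices %in% 3:6),
            isodose_prescription_fraction > 0,
            isodose_prescription_fraction <= 1,
            n_lesions >= n_patients, falloff_per_mm > 0,
            zero_distance_fraction >= 0, zero_distance_fraction < 0.5)
  structure(as.list(environment()), class = "cohort_config")
}

# analytic dose law: hot spot inside the GTV, exponential taper to the
# prescription at the PTV surface, exponential falloff outside
dose_at_distance <- function(dist_mm, r_gtv, r_ptv, prescription,
                             iso_fraction, falloff_per_mm) {
  d_hot <- prescription / iso_fraction
  out <- numeric(length(dist_mm))
  inside <- dist_mm <= r_gtv
  taper <- dist_mm > r_gtv & dist_mm <= r_ptv
  beyond <- dist_mm > r_ptv
  out[inside] <- d_hot
  out[taper] <- d_hot *
    iso_fraction^((dist_mm[taper] - r_gtv) / (r_ptv - r_gtv))
  out[beyond] <- prescription * (1 - falloff_per_mm)^(dist_mm[beyond] - r_ptv)
  out
}

# GTV radius matched so the voxelised sphere volume equals the target to
# within one voxel: the radius of the n-th nearest voxel centre
count_matched_radius <- function(center, volume_cc, gs) {
  vox_cc <- prod(gs$spacing) / 1000
  n_target <- max(1L, round(volume_cc / vox_cc))
  r_hint <- (3 * volume_cc * 1000 / (4 * pi))^(1 / 3)
  ax <- lapply(1:3, function(a) {
    x <- gs$origin[a] + (seq_len(gs$dim[a]) - 1) * gs$spacing[a]
    which(abs(x - center[a]) <= r_hint + 3 * gs$spacing[a])
  })
  if (any(!lengths(ax))) stop("GTV centre outside the grid")
  d2 <- function(a) (gs$origin[a] + (ax[[a]] - 1) * gs$spacing[a] - center[a])^2
  dist2 <- outer(outer(d2(1), d2(2), "+"), d2(3), "+")
  ds <- sort(dist2[dist2 <= (r_hint + 2 * max(gs$spacing))^2])
  if (length(ds) < n_target)
    stop("bounding box too small for requested GTV volume")
  # tie-aware: pick the distinct radius whose inclusive count is closest to
  # the target, and return a radius strictly between distance classes
  u <- unique(ds)
  cc <- cumsum(tabulate(match(ds, u)))
  k <- which.min(abs(cc - n_target))
  upper <- if (k < length(u)) u[k + 1] else u[k] + max(gs$spacing)^2
  sqrt((u[k] + upper) / 2)
}

#' Synthetic spherical-target dose grid
#'
#' Builds a planning dose grid for one lesion: a spherical GTV of the
#' requested volume (voxelised to within one voxel volume), a PTV obtained
#' by isotropic dilation, a hot spot of prescription / isodose-fraction
#' inside the GTV tapering to exactly the prescription at the PTV surface,
#' and exponential falloff at \code{falloff_per_mm} outside the PTV.
#'
#' @param gtv_center world coordinates of the GTV centre (mm).
#' @param gtv_volume GTV volume in cc.
#' @param schedule a \code{\link{fraction_schedule}}.
#' @param falloff_per_mm fractional falloff per mm (e.g. 0.10).
#' @param gs a \code{\link{grid_spec}}.
#' @param ptv_margin_mm GTV-to-PTV margin in mm.
#' @param iso_fraction prescription isodose fraction (default 0.8).
#' @param falloff_extent_mm clearance beyond the PTV that must fit inside
#'   the grid (sizing check).
#' @return list with \code{dose} (\code{dose_grid}), \code{gtv} and
#'   \code{ptv} (\code{structure_mask}s) and the matched GTV radius
#'   \code{r_gtv} (mm).
#' @export
generate_dose_grid <- function(gtv_center, gtv_volume, schedule,
                               falloff_per_mm = 0.10, gs = grid_spec(),
                               ptv_margin_mm = 4, iso_fraction = 0.8,
                               falloff_extent_mm = 10) {
  stopifnot(falloff_per_mm > 0, gtv_volume > 0)
  r_g <- count_matched_radius(gtv_center, gtv_volume, gs)
  r_p <- r_g + ptv_margin_mm
  ext_lo <- gs$origin
  ext_hi <- gs$origin + (gs$dim - 1) * gs$spacing
  if (any(gtv_center - (r_p + falloff_extent_mm) < ext_lo) ||
      any(gtv_center + (r_p + falloff_extent_mm) > ext_hi))
    stop("grid too small for PTV plus falloff region")
  d2 <- function(a) {
    (gs$origin[a] + (seq_len(gs$dim[a]) - 1) * gs$spacing[a] - gtv_center[a])^2
  }
  dist <- sqrt(outer(outer(d2(1), d2(2), "+"), d2(3), "+"))
  vals <- array(dose_at_distance(dist, r_g, r_p, schedule$total_dose,
                                 iso_fraction, falloff_per_mm), dim = gs$dim)
  grid <- dose_grid(vals, spacing = gs$spacing, origin = gs$origin,
                    frame_id = gs$frame_id)
  list(dose = grid,
       gtv = structure_mask("GTV", which(dist <= r_g), grid),
       ptv = structure_mask("PTV", which(dist <= r_p), grid),
       r_gtv = r_g)
}

#' Synthetic rib cage
#'
#' A stack of parallel tube-shaped ribs (axis along y) on the chest-wall
#' plane \code{x = chest_wall_x_mm}, stacked along z at the stated pitch.
#'
#' @param rib_count number of ribs (0 returns an empty list).
#' @param rib_radius_mm tube radius in mm.
#' @param rib_pitch_mm centre-to-centre spacing along z; must be at least
#'   twice the radius (disjointness).
#' @param chest_wall_x_mm x position of the rib axes (mm).
#' @param gs a \code{\link{grid_spec}}.
#' @param y_range_mm axial extent of the ribs; default leaves a 20 mm
#'   margin at both ends of the grid.
#' @param z_first_mm z of the first rib axis (default centres the stack).
#' @return list of disjoint \code{structure_mask}s named \code{rib_1} ...
#' @export
generate_rib_cage <- function(rib_count = 8L, rib_radius_mm = 5,
                              rib_pitch_mm = 18, chest_wall_x_mm = 150,
                              gs = grid_spec(), y_range_mm = NULL,
                              z_first_mm = NULL) {
  if (rib_count == 0L) return(list())
  if (rib_pitch_mm < 2 * rib_radius_mm)
    stop("rib pitch ", rib_pitch_mm, " mm < 2 x radius: ribs would overlap")
  ext_hi <- gs$origin + (gs$dim - 1) * gs$spacing
  if (is.null(y_range_mm)) y_range_mm <- c(gs$origin[2] + 20, ext_hi[2] - 20)
  span <- (rib_count - 1) * rib_pitch_mm
  if (is.null(z_first_mm))
    z_first_mm <- gs$origin[3] + (ext_hi[3] - gs$origin[3] - span) / 2
  z_axes <- z_first_mm + (seq_len(rib_count) - 1) * rib_pitch_mm
  if (any(z_axes - rib_radius_mm < gs$origin[3]) ||
      any(z_axes + rib_radius_mm > ext_hi[3]) ||
      chest_wall_x_mm - rib_radius_mm < gs$origin[1] ||
      chest_wall_x_mm + rib_radius_mm > ext_hi[1])
    stop("rib cage does not fit inside the grid")
  xs <- gs$origin[1] + (seq_len(gs$dim[1]) - 1) * gs$spacing[1]
  ys <- gs$origin[2] + (seq_len(gs$dim[2]) - 1) * gs$spacing[2]
  zs <- gs$origin[3] + (seq_len(gs$dim[3]) - 1) * gs$spacing[3]
  jy <- which(ys >= y_range_mm[1] & ys <= y_range_mm[2])
  nx <- gs$dim[1]; nxy <- gs$dim[1] * gs$dim[2]
  fake_grid <- list(origin = gs$origin, spacing = gs$spacing, dim = gs$dim,
                    frame_id = gs$frame_id)
  lapply(seq_len(rib_count), function(k) {
    circ <- which(outer((xs - chest_wall_x_mm)^2, (zs - z_axes[k])^2, "+")
                  <= rib_radius_mm^2, arr.ind = TRUE)
    if (!nrow(circ)) stop("rib ", k, " contains no voxels")
    idx <- as.vector(outer((circ[, 2] - 1L) * nxy + circ[, 1],
                           (jy - 1L) * nx, "+"))
    structure_mask(paste0("rib_", k), idx, fake_grid)
  })
}

#' Sample a synthetic cohort (covariates and geometry)
#'
#' Draws patients and lesions with the configured covariate marginals,
#' assigns each lesion a position next to the synthetic rib cage realising
#' its sampled rib-tumor distance, and attaches the rib-cage geometry.
#' Dosimetric metrics and outcomes are filled by
#' \code{\link{compute_cohort_metrics}} and \code{\link{sample_outcomes}};
#' \code{\link{simulate_cohort}} runs all three.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list of class \code{"synthetic_cohort"}: \code{patients} and
#'   \code{lesions} data frames, \code{ribs} (list of masks), and the
#'   config.
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cf <- config
  with_seed(cf$seed, {
    np <- cf$n_patients; nl <- cf$n_lesions
    patients <- data.frame(
      patient_id = sprintf("P%02d", seq_len(np)),
      age = pmin(95, pmax(40, round(stats::rnorm(np, 66, 9)))),
      sex = ifelse(stats::runif(np) < cf$male_fraction, "male", "female"),
      primary_site = sample(c("lung", "breast", "colorectal", "other"), np,
                            replace = TRUE,
                            prob = c(0.571, 0.061, 0.327, 0.041)),
      dm = stats::runif(np) < cf$dm_fraction,
      copd = stats::runif(np) < cf$copd_fraction,
      stringsAsFactors = FALSE)

    # every patient gets one lesion; the surplus goes to random patients
    extra <- if (nl > np)
      sample(patients$patient_id, nl - np, replace = TRUE) else character()
    owner <- c(patients$patient_id, extra)
    patients$multiple_treatment <- patients$patient_id %in%
      names(which(table(owner) > 1))

    gtv <- stats::rlnorm(nl, log(cf$gtv_volume_log_median), cf$gtv_volume_sdlog)
    gtv <- pmin(gtv, 115)               # keep the PTV inside the grid
    # distance mixture: abutting/invading lesions at 0.00 cm, the rest
    # exponential with the rate preserving the configured overall median
    w0 <- cf$zero_distance_fraction
    at_wall <- stats::runif(nl) < w0
    p_exp <- (0.5 - w0) / (1 - w0)
    rate <- -log(1 - p_exp) / cf$rib_distance_median_cm
    dist_cm <- ifelse(at_wall, 0, pmin(stats::rexp(nl, rate = rate), 4.1))
    embed <- ifelse(at_wall,
                    stats::runif(nl, cf$embed_depth_mm[1], cf$embed_depth_mm[2]),
                    0)
    n_frac <- sample(cf$fraction_choices, nl, replace = TRUE,
                     prob = cf$fraction_weights)
    rx <- round(stats::runif(nl, cf$prescription_range[1],
                             cf$prescription_range[2]))
    location <- ifelse(stats::runif(nl) < cf$middle_lower_fraction,
                       "middle_lower", "upper")

    gs <- cf$grid
    ext_hi <- gs$origin + (gs$dim - 1) * gs$spacing
    span <- (cf$rib_count - 1) * cf$rib_pitch_mm
    z_first <- gs$origin[3] + (ext_hi[3] - gs$origin[3] - span) / 2
    rib_z <- z_first + (seq_len(cf$rib_count) - 1) * cf$rib_pitch_mm
    r_gtv <- (3 * gtv * 1000 / (4 * pi))^(1 / 3)
    wall_surface <- cf$chest_wall_x_mm - cf$rib_radius_mm
    cx <- wall_surface - r_gtv - dist_cm * 10 + pmin(embed, r_gtv)
    cy <- stats::runif(nl, gs$origin[2] + 60, ext_hi[2] - 60)
    near_rib <- sample(seq_len(cf$rib_count), nl, replace = TRUE)
    cz <- rib_z[near_rib] + stats::runif(nl, -cf$rib_pitch_mm / 2,
                                         cf$rib_pitch_mm / 2)

    lesions <- data.frame(
      lesion_id = sprintf("L%03d", seq_len(nl)),
      patient_id = owner,
      location = location,
      gtv_volume = gtv,
      rib_distance = dist_cm,
      total_dose = rx,
      n_fractions = n_frac,
      cx = cx, cy = cy, cz = cz,
      stringsAsFactors = FALSE)

    ribs <- generate_rib_cage(cf$rib_count, cf$rib_radius_mm,
                              cf$rib_pitch_mm, cf$chest_wall_x_mm, gs)
    structure(list(patients = patients, lesions = lesions, ribs = ribs,
                   config = cf),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d lesions in %d patients",
              nrow(x$lesions), nrow(x$patients)))
  if ("event" %in% names(x$lesions))
    cat(sprintf(", %d fracture events", sum(x$lesions$event)))
  cat("\n")
  invisible(x)
}

#' Per-lesion analysis table with patient covariates merged in
#'
#' One row per lesion: lesion covariates, any computed metric and outcome
#' columns, plus the owning patient's clinical covariates (age, sex,
#' primary site, diabetes, COPD, multiple-treatment flag).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @return data frame.
#' @export
cohort_table <- function(cohort) {
  merge(cohort$lesions, cohort$patients, by = "patient_id", sort = FALSE)
}

#' Full planning dose grid of one cohort lesion
#'
#' Materialises the lesion's analytic dose law on the cohort grid (the
#' per-lesion metric computation itself uses only the rib voxels; this
#' accessor exists for DVH or 4D work on full grids).
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param i lesion row index.
#' @return as \code{\link{generate_dose_grid}}.
#' @export
lesion_dose_grid <- function(cohort, i) {
  l <- cohort$lesions[i, ]
  cf <- cohort$config
  generate_dose_grid(c(l$cx, l$cy, l$cz), l$gtv_volume,
                     fraction_schedule(l$total_dose, l$n_fractions),
                     cf$falloff_per_mm, cf$grid, cf$ptv_margin_mm,
                     cf$isodose_prescription_fraction)
}

# rib-union voxel machinery shared by the cohort-scale fast path
rib_voxel_table <- function(cohort) {
  coords <- do.call(rbind, lapply(cohort$ribs, mask_coords))
  rib_id <- rep(seq_along(cohort$ribs),
                vapply(cohort$ribs, function(r) length(r$member_idx), 0L))
  list(coords = coords, rib_id = rib_id,
       vox_cc = prod(cohort$config$grid$spacing) / 1000)
}

# EQD2 at the rib voxels of one lesion, via the analytic dose law
lesion_rib_eqd2 <- function(cohort, i, rv = rib_voxel_table(cohort)) {
  l <- cohort$lesions[i, ]
  cf <- cohort$config
  r_g <- count_matched_radius(c(l$cx, l$cy, l$cz), l$gtv_volume, cf$grid)
  dd <- sqrt((rv$coords[, 1] - l$cx)^2 + (rv$coords[, 2] - l$cy)^2 +
               (rv$coords[, 3] - l$cz)^2)
  phys <- dose_at_distance(dd, r_g, r_g + cf$ptv_margin_mm, l$total_dose,
                           cf$isodose_prescription_fraction, cf$falloff_per_mm)
  eqd2(phys, l$n_fractions)
}

#' Compute rib DVH metrics for every cohort lesion
#'
#' For each lesion: EQD2 at the rib voxels (analytic dose law, the lesion's
#' own fraction schedule, alpha/beta = 3), selection of ribs with any voxel
#' at or above \code{threshold} Gy EQD2, cumulative DVH of the selected-rib
#' union, and the full D_V / V_D metric sweep.  Lesions irradiating no rib
#' above threshold get \code{NA} metrics.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param threshold rib-contouring EQD2 threshold in Gy (default 10).
#' @return the cohort with metric columns bound onto \code{lesions}.
#' @export
compute_cohort_metrics <- function(cohort, threshold = 10) {
  rv <- rib_voxel_table(cohort)
  rows <- lapply(seq_len(nrow(cohort$lesions)), function(i) {
    vals <- lesion_rib_eqd2(cohort, i, rv)
    sel <- vapply(split(vals, rv$rib_id), max, 0) >= threshold
    keep <- rv$rib_id %in% as.integer(names(sel))[sel]
    if (!any(keep)) {
      fam <- metric_sweep(dvh_from_values(0, rv$vox_cc))
      out <- metric_row(fam)
      out[] <- NA_real_
      return(out)
    }
    metric_row(metric_sweep(dvh_from_values(vals[keep], rv$vox_cc)))
  })
  cohort$lesions <- cbind(cohort$lesions, do.call(rbind, rows))
  cohort
}

#' Draw fracture outcomes from a dose-dependent Weibull hazard
#'
#' Time to fracture follows a Weibull proportional-hazards model whose
#' log-hazard is linear in \code{max(0, metric - threshold)}; the censoring
#' time is drawn independently from a clamped log-normal follow-up
#' distribution.  The observed event indicator is fracture-before-censoring.
#'
#' @param lesions data frame containing the driving metric column.
#' @param hazard list: \code{scale} (months), \code{shape}, \code{slope}
#'   (per Gy above threshold), \code{threshold} (Gy EQD2), \code{metric}
#'   (column name).
#' @param followup list: \code{median} (months), \code{sdlog}, \code{range}.
#' @param seed integer seed.
#' @param na_metric_zero treat a missing driving metric as zero dose
#'   (no excess hazard); if \code{FALSE} (default) a missing metric is a
#'   precondition error.
#' @return \code{lesions} with \code{event} (logical) and \code{time}
#'   (months) columns.
#' @export
sample_outcomes <- function(lesions,
                            hazard = list(scale = 150, shape = 1.5,
                                          slope = 0.04, threshold = 140,
                                          metric = "D_4.6cc"),
                            followup = list(median = 26.7, sdlog = 0.55,
                                            range = c(6, 84)),
                            seed = 1L, na_metric_zero = FALSE) {
  m <- lesions[[hazard$metric]]
  if (is.null(m)) stop("driving metric '", hazard$metric, "' not computed")
  if (anyNA(m)) {
    if (!na_metric_zero)
      stop("driving metric '", hazard$metric, "' missing for ",
           sum(is.na(m)), " lesion(s)")
    m[is.na(m)] <- 0
  }
  with_seed(seed, {
    lp <- hazard$slope * pmax(0, m - hazard$threshold)
    u <- stats::runif(length(m))
    t_frac <- hazard$scale * (-log(u) / exp(lp))^(1 / hazard$shape)
    cens <- stats::rlnorm(length(m), log(followup$median), followup$sdlog)
    cens <- pmin(pmax(cens, followup$range[1]), followup$range[2])
    lesions$event <- t_frac <= cens
    lesions$time <- pmin(t_frac, cens)
    lesions
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience pipeline: \code{\link{sample_cohort}} +
#' \code{\link{compute_cohort_metrics}} + \code{\link{sample_outcomes}}
#' (outcome seed derived as \code{seed + 1}; lesions with no contoured rib
#' carry no excess hazard).
#'
#' @param config a \code{\link{cohort_config}}.
#' @return a \code{synthetic_cohort} with metrics and outcomes filled.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  cohort <- compute_cohort_metrics(sample_cohort(config))
  cohort$lesions <- sample_outcomes(
    cohort$lesions, hazard = config$hazard,
    followup = list(median = config$followup_median_months,
                    sdlog = config$followup_sdlog,
                    range = config$followup_range_months),
    seed = config$seed + 1L, na_metric_zero = TRUE)
  cohort
}
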