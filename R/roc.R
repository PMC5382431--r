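#' Empirical ROC curve with Mann-Whitney AUC
#'
#' Builds the empirical ROC of a continuous metric against a binary outcome
#' (predict positive when the metric exceeds a threshold).  The area under
#' the curve is computed from midranks, which equals the trapezoidal area
#' and the Mann-Whitney concordance probability with ties counted one half.
#' The p-value against AUC = 0.5 uses the normal approximation to the
#' Mann-Whitney statistic with tie-corrected variance.
#'
#' @param values numeric metric per lesion; \code{NA}s dropped pairwise with
#'   their outcomes.
#' @param outcomes logical (or 0/1) event indicator per lesion.
#' @return An object of class \code{"roc_curve"}: thresholds (sorted unique
#'   metric values), sensitivity and specificity per threshold, \code{auc},
#'   \code{auc_p}, and the class counts \code{n_pos}, \code{n_neg}.
#' @export
roc_curve <- function(values, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(values) != length(outcomes))
    stop("'values' and 'outcomes' lengths differ")
  keep <- !is.na(values) & !is.na(outcomes)
  values <- values[keep]; outcomes <- outcomes[keep]
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need at least one positive and one negative outcome")

  thr <- sort(unique(values))
  # counts above each threshold, by class
  sens <- vapply(thr, function(t) sum(values[outcomes] > t), 0) / n_pos
  spec <- vapply(thr, function(t) sum(values[!outcomes] <= t), 0) / n_neg

  r <- rank(values)                       # midranks
  u <- sum(r[outcomes]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)

  n <- n_pos + n_neg
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  var_u <- n_pos * n_neg / 12 * ((n + 1) - tie_term)
  auc_p <- if (var_u <= 0) 1 else
    2 * stats::pnorm(-abs(u - n_pos * n_neg / 2) / sqrt(var_u))

  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, auc_p = auc_p, n_pos = n_pos, n_neg = n_neg,
         values = values, outcomes = outcomes),
    class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (p = %.4g), %d positives / %d negatives\n",
              x$auc, x$auc_p, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(c(1, 1 - x$specificity, 0), c(1, x$sensitivity, 0),
                 type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' The threshold maximising Youden's J = sensitivity + specificity - 1.
#' Candidate thresholds are midpoints between consecutive distinct metric
#' values, so a perfectly separating metric returns the midpoint of the
#' separating gap.  Ties in J are broken toward higher specificity, then
#' toward the larger threshold.
#'
#' @param roc a \code{roc_curve}.
#' @return the cutoff on the metric's own scale (Gy or cc).
#' @export
optimal_cutoff <- function(roc) {
  u <- sort(unique(roc$values))
  if (length(u) == 1L) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  pos <- roc$values[roc$outcomes]; neg <- roc$values[!roc$outcomes]
  sens <- vapply(cand, function(t) mean(pos > t), 0)
  spec <- vapply(cand, function(t) mean(neg <= t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(spec[best], cand[best], decreasing = TRUE)][1]
  cand[best]
}

#' Select the most discriminative D_V and V_D metrics
#'
#' Computes the AUC of every volume-grid D_V column and every dose-grid V_D
#' column of a per-lesion metric table against the fracture outcome, and
#' returns within each family the grid point maximising the AUC (first
#' maximum, i.e. smaller V / smaller D on ties), together with the
#' Youden-optimal cutoff of each winner.  Grid points with fewer than
#' \code{min_n} non-missing values are skipped with a warning.
#'
#' @param metrics data frame with columns named \code{D_<V>cc} and
#'   \code{V_<D>} as produced by \code{\link{metric_row}}, one row per
#'   lesion.
#' @param outcomes logical event indicator aligned with the rows.
#' @param min_n minimum non-missing values per grid point (default 5).
#' @return An object of class \code{"metric_selection"}: per-family AUC
#'   tables and the fields \code{best_dv_volume}, \code{best_dv_auc},
#'   \code{best_dv_p}, \code{cutoff_dv} (Gy), and the \code{vd}
#'   counterparts (\code{cutoff_vd} in cc).
#' @export
select_best_metric <- function(metrics, outcomes, min_n = 5) {
  outcomes <- as.logical(outcomes)
  stopifnot(nrow(metrics) == length(outcomes))
  vg <- dv_volume_grid(); dg <- vd_dose_grid()
  dv_cols <- paste0("D_", format_cc(vg), "cc")
  vd_cols <- paste0("V_", dg)
  miss <- setdiff(c(dv_cols, vd_cols), names(metrics))
  if (length(miss)) stop("metric table lacks columns: ",
                         paste(miss, collapse = ", "))

  fam_auc <- function(cols, grid) {
    auc <- p <- rep(NA_real_, length(cols))
    skipped <- character()
    for (i in seq_along(cols)) {
      v <- metrics[[cols[i]]]
      ok <- !is.na(v)
      if (sum(ok) < min_n || length(unique(outcomes[ok])) < 2L) {
        skipped <- c(skipped, cols[i]); next
      }
      r <- roc_curve(v[ok], outcomes[ok])
      auc[i] <- r$auc; p[i] <- r$auc_p
    }
    if (length(skipped))
      warning("skipped grid points with < ", min_n, " usable values: ",
              paste(skipped, collapse = ", "), call. = FALSE)
    data.frame(grid = grid, metric = cols, auc = auc, p = p)
  }

  dv_tab <- fam_auc(dv_cols, vg)
  vd_tab <- fam_auc(vd_cols, dg)
  pick <- function(tab) which.max(tab$auc)   # first maximum: smaller grid point
  i_dv <- pick(dv_tab); i_vd <- pick(vd_tab)
  roc_dv <- {
    v <- metrics[[dv_tab$metric[i_dv]]]
    roc_curve(v[!is.na(v)], outcomes[!is.na(v)])
  }
  roc_vd <- {
    v <- metrics[[vd_tab$metric[i_vd]]]
    roc_curve(v[!is.na(v)], outcomes[!is.na(v)])
  }
  structure(
    list(dv_table = dv_tab, vd_table = vd_tab,
         best_dv_volume = dv_tab$grid[i_dv], best_dv_metric = dv_tab$metric[i_dv],
         best_dv_auc = dv_tab$auc[i_dv], best_dv_p = dv_tab$p[i_dv],
         best_vd_dose = vd_tab$grid[i_vd], best_vd_metric = vd_tab$metric[i_vd],
         best_vd_auc = vd_tab$auc[i_vd], best_vd_p = vd_tab$p[i_vd],
         cutoff_dv = optimal_cutoff(roc_dv), cutoff_vd = optimal_cutoff(roc_vd),
         roc_dv = roc_dv, roc_vd = roc_vd),
    class = "metric_selection")
}

#' @export
print.metric_selection <- function(x, ...) {
  cat("<metric_selection>\n")
  cat(sprintf("  best D_V : %s  AUC %.3f (p = %.4g), Youden cutoff %.1f Gy\n",
              x$best_dv_metric, x$best_dv_auc, x$best_dv_p, x$cutoff_dv))
  cat(sprintf("  best V_D : %s  AUC %.3f (p = %.4g), Youden cutoff %.2f cc\n",
              x$best_vd_metric, x$best_vd_auc, x$best_vd_p, x$cutoff_vd))
  invisible(x)
}
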