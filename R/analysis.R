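#' Percentage as printed in clinical reports
#'
#' \code{100 * k / n} rounded to a fixed number of decimals (default 1),
#' e.g. 8 fracture patients of 39 analysed is 20.5.
#'
#' @param k numerator count.
#' @param n denominator count, > 0.
#' @param digits decimals to round to.
#' @return percentage on the 0-100 scale.
#' @export
percent_of <- function(k, n, digits = 1) {
  if (n <= 0) stop("'n' must be > 0")
  round(100 * k / n, digits)
}

#' Rib-fracture risk analysis of a lesion cohort
#'
#' The full dosimetric risk analysis on a per-lesion table with DVH metric
#' columns and time-to-fracture outcomes: overall Kaplan-Meier actuarial
#' incidence; ROC sweep over the D_V and V_D families with AUC-maximising
#' metric selection and Youden cutoffs; univariate log-rank screening of
#' clinical and dosimetric factors (continuous factors dichotomised at the
#' stated or selected cutoffs); a collinearity screen that keeps one factor
#' per cluster of mutually associated candidates (the one with the highest
#' univariate AUC); and a multivariate Cox proportional-hazards model on
#' the retained factors.
#'
#' @param lesions data frame with columns \code{event} (logical),
#'   \code{time} (months), the metric columns from
#'   \code{\link{metric_row}}, and (if present) the clinical covariates
#'   \code{sex-}/\code{location-}/\code{dm}/\code{copd}-style columns used
#'   below.
#' @param gtv_cutoff_cc GTV-volume split for the univariate table (cc).
#' @param distance_cutoff_cm rib-tumor distance split (cm).
#' @param entry \code{"all"}: every factor surviving the collinearity
#'   screen enters the Cox model; \code{"p_gated"}: only those with
#'   univariate log-rank p below \code{alpha}.
#' @param alpha significance level for the collinearity screen and the
#'   p-gated entry.
#' @param ties Cox tie handling (default Breslow).
#' @return object of class \code{"rib_fracture_analysis"}.
#' @export
rib_fracture_analysis <- function(lesions, gtv_cutoff_cc = 17,
                                  distance_cutoff_cm = 0.4,
                                  entry = c("all", "p_gated"), alpha = 0.05,
                                  ties = "breslow") {
  entry <- match.arg(entry)
  stopifnot(all(c("event", "time") %in% names(lesions)))
  ev <- as.logical(lesions$event)
  tm <- lesions$time

  km <- km_estimate(tm, ev)
  sel <- select_best_metric(lesions, ev)

  # candidate factors: value vector + the binary split used for log-rank
  cand <- list()
  add <- function(name, value, high) {
    cand[[name]] <<- list(value = value, high = high)
  }
  if ("sex" %in% names(lesions))
    add("sex_male", lesions$sex == "male", lesions$sex == "male")
  if ("location" %in% names(lesions))
    add("location_upper", lesions$location == "upper",
        lesions$location == "upper")
  for (b in intersect(c("multiple_treatment", "dm", "copd"), names(lesions)))
    add(b, as.logical(lesions[[b]]), as.logical(lesions[[b]]))
  if ("gtv_volume" %in% names(lesions))
    add("gtv_volume", lesions$gtv_volume, lesions$gtv_volume > gtv_cutoff_cc)
  if ("rib_distance" %in% names(lesions))
    add("rib_distance", lesions$rib_distance,
        lesions$rib_distance <= distance_cutoff_cm)   # closer = higher risk
  dv <- lesions[[sel$best_dv_metric]]
  vd <- lesions[[sel$best_vd_metric]]
  add(sel$best_dv_metric, dv, dv > sel$cutoff_dv)
  add(sel$best_vd_metric, vd, vd > sel$cutoff_vd)

  univariate <- do.call(rbind, lapply(names(cand), function(nm) {
    hi <- cand[[nm]]$high
    ok <- !is.na(hi)
    if (length(unique(hi[ok])) < 2L)
      return(data.frame(factor = nm, n_high = sum(hi, na.rm = TRUE),
                        events_high = NA, events_low = NA,
                        chisq = NA_real_, p = NA_real_))
    lr <- logrank_test(hi[ok], tm[ok], ev[ok])
    data.frame(factor = nm, n_high = sum(hi, na.rm = TRUE),
               events_high = unname(lr$observed["TRUE"]),
               events_low = unname(lr$observed["FALSE"]),
               chisq = lr$chisq, p = lr$p)
  }))

  # univariate AUC scores drive which member of a collinear cluster is kept
  scores <- vapply(cand, function(cc) {
    v <- as.numeric(cc$value)
    ok <- !is.na(v)
    if (length(unique(ev[ok])) < 2L || length(unique(v[ok])) < 2L)
      return(0.5)
    max(roc_curve(v[ok], ev[ok])$auc, 1 - roc_curve(v[ok], ev[ok])$auc)
  }, 0)
  fac_tab <- as.data.frame(lapply(cand, function(cc) as.numeric(cc$value)))
  retained <- collinearity_screen(fac_tab, scores, alpha = alpha)

  cox_terms <- as.character(retained)
  if (entry == "p_gated") {
    pu <- stats::setNames(univariate$p, univariate$factor)
    cox_terms <- cox_terms[!is.na(pu[cox_terms]) & pu[cox_terms] < alpha]
  }
  cox <- NULL
  if (length(cox_terms)) {
    covs <- as.data.frame(lapply(cand[cox_terms],
                                 function(cc) as.numeric(cc$high)))
    names(covs) <- cox_terms
    ok <- stats::complete.cases(covs)
    cox <- tryCatch(
      cox_fit(covs[ok, , drop = FALSE], tm[ok], ev[ok], ties = ties),
      error = function(e) {
        warning("Cox model not fitted: ", conditionMessage(e), call. = FALSE)
        NULL
      })
  }

  structure(
    list(km = km,
         incidence_2yr = incidence_at(km, 24),
         incidence_3yr = incidence_at(km, 36),
         selection = sel, univariate = univariate,
         retained = as.character(retained),
         clusters = attr(retained, "clusters"),
         cox = cox, entry = entry, n = nrow(lesions), n_event = sum(ev)),
    class = "rib_fracture_analysis")
}

#' @export
print.rib_fracture_analysis <- function(x, ...) {
  cat("Rib fracture dosimetric risk analysis\n")
  cat(sprintf("  %d lesions, %d fracture events (crude %.1f%%)\n",
              x$n, x$n_event, 100 * x$n_event / x$n))
  cat(sprintf("  actuarial incidence: %.1f%% at 2 years, %.1f%% at 3 years\n",
              100 * x$incidence_2yr, 100 * x$incidence_3yr))
  cat(sprintf("  best D_V : %s (AUC %.3f, p = %.3g), cutoff %.1f Gy EQD2\n",
              x$selection$best_dv_metric, x$selection$best_dv_auc,
              x$selection$best_dv_p, x$selection$cutoff_dv))
  cat(sprintf("  best V_D : %s (AUC %.3f, p = %.3g), cutoff %.2f cc\n",
              x$selection$best_vd_metric, x$selection$best_vd_auc,
              x$selection$best_vd_p, x$selection$cutoff_vd))
  cat("  retained after collinearity screen:",
      paste(x$retained, collapse = ", "), "\n")
  if (!is.null(x$cox)) {
    cat(sprintf("  multivariate Cox (%s entry):\n", x$entry))
    print(x$cox$table, digits = 3)
  } else cat("  multivariate Cox: not fitted\n")
  invisible(x)
}

#' @export
summary.rib_fracture_analysis <- function(object, ...) {
  cat("Univariate log-rank screening:\n")
  print(object$univariate, digits = 3, row.names = FALSE)
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
plot.rib_fracture_analysis <- function(x, which = c("km", "roc"), ...) {
  which <- match.arg(which)
  if (which == "km") {
    plot(x$km, incidence = TRUE,
         main = "Actuarial incidence of rib fracture", ...)
  } else {
    plot(x$selection$roc_dv,
         main = sprintf("%s (AUC %.3f)", x$selection$best_dv_metric,
                        x$selection$best_dv_auc), ...)
  }
  invisible(x)
}
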