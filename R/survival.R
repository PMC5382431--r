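#' Kaplan-Meier estimate of fracture-free survival
#'
#' Product-limit estimator of the time-to-fracture distribution; the
#' actuarial incidence at time t is 1 minus the survivor function.  Ties at
#' a time are processed with events before censorings (the standard
#' product-limit convention).
#'
#' @param times follow-up in months, > 0 (time origin: first day of SABR).
#' @param events logical; \code{TRUE} = fracture observed at \code{times},
#'   \code{FALSE} = censored.
#' @return An object of class \code{"km_curve"}: per distinct event-time
#'   step the time, at-risk and event counts, survival and incidence.
#' @export
km_estimate <- function(times, events) {
  events <- as.logical(events)
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(
    list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         survival = fit$surv, incidence = 1 - fit$surv, n = length(times)),
    class = "km_curve")
}

#' Actuarial incidence at a time point
#'
#' Step-function read-off of 1 - S(t) from a \code{km_curve}.
#' @param km a \code{km_curve}.
#' @param t time in months.
#' @return incidence in [0, 1].
#' @export
incidence_at <- function(km, t) {
  i <- findInterval(t, km$time)
  if (i == 0L) 0 else km$incidence[i]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d events; final survival %.3f\n",
              x$n, sum(x$n_event), min(1, utils::tail(x$survival, 1))))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, incidence = FALSE, ...) {
  if (incidence) {
    graphics::plot(c(0, x$time), c(0, x$incidence), type = "s",
                   xlab = "months", ylab = "actuarial incidence",
                   ylim = c(0, 1), ...)
  } else {
    graphics::plot(c(0, x$time), c(1, x$survival), type = "s",
                   xlab = "months", ylab = "fracture-free survival",
                   ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance; p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param groups two-level grouping (factor, character or logical).
#' @param times follow-up in months.
#' @param events logical event indicator.
#' @return An object of class \code{"logrank_result"}: \code{chisq},
#'   \code{p}, and per-group \code{observed} / \code{expected} counts.
#' @export
logrank_test <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank needs two non-empty groups")
  if (nlevels(g) > 2L) stop("only two groups supported")
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ g)
  structure(
    list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
         observed = stats::setNames(sd$obs, levels(g)),
         expected = stats::setNames(sd$exp, levels(g))),
    class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chisq(1) = %.3f, p = %.4g\n", x$chisq, x$p))
  print(rbind(observed = x$observed, expected = x$expected))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Newton-Raphson, Breslow tie handling by
#' default, Efron optional).  Fits that fail to converge or show a monotone
#' likelihood (complete separation, diverging coefficient) are flagged and
#' report no estimates.
#'
#' @param covariates data frame of numeric/logical covariates, one row per
#'   lesion; constant columns are rejected.
#' @param times follow-up in months.
#' @param events logical event indicator; must outnumber the covariates.
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @return An object of class \code{"cox_fit"}: a coefficient table
#'   (\code{coef}, \code{hr}, \code{se}, \code{z}, \code{p} per covariate),
#'   \code{converged}, and the \code{ties} label.
#' @export
cox_fit <- function(covariates, times, events, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(lapply(covariates, as.numeric))
  events <- as.logical(events)
  if (sum(events) <= ncol(covariates))
    stop("need more events than covariates")
  const <- vapply(covariates, function(v) length(unique(v)) < 2L, TRUE)
  if (any(const)) stop("constant covariate(s): ",
                       paste(names(covariates)[const], collapse = ", "))
  dat <- cbind(covariates, .time = times, .event = events)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  s <- summary(fit)
  co <- s$coefficients
  converged <- all(is.finite(co[, "se(coef)"])) &&
    max(abs(co[, "coef"])) < 15 && fit$iter < 50
  tab <- data.frame(
    term = names(covariates),
    coef = co[, "coef"], hr = co[, "exp(coef)"],
    se = co[, "se(coef)"], z = co[, "z"], p = co[, "Pr(>|z|)"],
    row.names = NULL)
  if (!converged) tab[, -1] <- NA_real_
  structure(list(table = tab, converged = converged, ties = ties,
                 n = length(times), n_event = sum(events)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n,
              x$n_event, x$ties,
              if (x$converged) "" else "  [DID NOT CONVERGE]"))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...)
  stats::setNames(object$table$coef, object$table$term)

#' Paired t-test comparison of two dose calculations
#'
#' Classical paired t-test on per-lesion differences (e.g. 3D planning vs
#' 4D accumulated metric).  A zero-variance difference vector is flagged as
#' degenerate: p = 1 when the mean difference is 0, p = 0 otherwise.
#'
#' @param x,y equal-length paired numeric vectors, n >= 2.
#' @param metric label carried into the result.
#' @return An object of class \code{"paired_comparison"}: \code{mean_diff},
#'   \code{t}, \code{df}, \code{p}, \code{degenerate}, and the pairs.
#' @export
paired_ttest <- function(x, y, metric = "metric") {
  if (length(x) != length(y)) stop("unpaired input")
  if (length(x) < 2L) stop("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    res <- list(mean_diff = mean(d),
                t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else 0, degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
  }
  structure(c(list(metric = metric, x = x, y = y), res),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: mean diff %.4g, t(%d) = %.3f, p = %.4g%s\n",
              x$metric, x$mean_diff, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Collinearity screen for candidate risk factors
#'
#' Computes pairwise association between candidate factors (Spearman
#' correlation for continuous pairs, rank-biserial via Wilcoxon for
#' binary-continuous pairs, the phi coefficient with a chi-square test for
#' binary pairs), links factors whose association p-value is below
#' \code{alpha}, and keeps from each linked cluster only the factor with
#' the highest univariate AUC.  The outcome plays no role in the
#' associations, only in the per-factor AUC scores supplied by the caller.
#'
#' @param factors data frame of candidates (numeric, or logical/2-level for
#'   binary).
#' @param scores named numeric, univariate AUC (or any score where larger =
#'   more predictive) per factor.
#' @param alpha association significance level (default 0.05).
#' @return character vector of retained factor names, plus attributes
#'   \code{clusters} and \code{p_matrix}.
#' @export
collinearity_screen <- function(factors, scores, alpha = 0.05) {
  nm <- names(factors)
  if (!length(nm)) stop("at least one candidate required")
  stopifnot(all(nm %in% names(scores)))
  is_bin <- vapply(factors, function(v) length(unique(v[!is.na(v)])) <= 2L, TRUE)
  num <- lapply(factors, function(v) as.numeric(as.factor(v)))
  k <- length(nm)
  pmat <- matrix(1, k, k, dimnames = list(nm, nm))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    a <- num[[i]]; b <- num[[j]]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    p <- if (is_bin[i] && is_bin[j]) {
      suppressWarnings(stats::chisq.test(table(a, b), correct = FALSE)$p.value)
    } else if (is_bin[i] || is_bin[j]) {
      bin <- if (is_bin[i]) a else b
      cont <- if (is_bin[i]) b else a
      if (length(unique(bin)) < 2L) 1 else
        suppressWarnings(stats::wilcox.test(cont ~ factor(bin))$p.value)
    } else {
      suppressWarnings(stats::cor.test(a, b, method = "spearman")$p.value)
    }
    pmat[i, j] <- pmat[j, i] <- if (is.na(p)) 1 else p
  }
  # connected components of the alpha-linked graph (union-find)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
    if (pmat[i, j] < alpha) parent[find(j)] <- find(i)
  comp <- vapply(seq_len(k), find, 0L)
  keep <- vapply(unique(comp), function(cl) {
    members <- nm[comp == cl]
    members[which.max(scores[members])]
  }, "")
  structure(keep, clusters = split(nm, comp), p_matrix = pmat)
}
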