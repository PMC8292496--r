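#' Accuracy-band evaluation of INR predictions
#'
#' Scores predictions the way the clinician comparison is scored: a success
#' is a prediction strictly less than a threshold away from the actual value
#' ("within" bands at 0.2, 0.25, 0.3), and a very inaccurate prediction is
#' strictly more than a threshold away ("beyond" bands at 0.5, 1.0). The mean
#' and sample sd of the absolute error are also reported.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @param thresholds Within-band thresholds (default `c(0.2, 0.25, 0.3)`).
#' @param outlier_thresholds Beyond-band thresholds (default `c(0.5, 1.0)`).
#' @param inclusive If `TRUE`, count `|error| <= t` as within (sensitivity
#'   analysis; the published definition is strict, the default).
#' @return An `inr_eval_report`: `n`, per-band counts and fractions, `mae`,
#'   `sd_ae`.
#' @export
accuracy_bands <- function(predicted, actual,
                           thresholds = c(0.2, 0.25, 0.3),
                           outlier_thresholds = c(0.5, 1.0),
                           inclusive = FALSE) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  err <- abs(predicted - actual)
  n <- length(err)
  thresholds <- sort(thresholds)
  outlier_thresholds <- sort(outlier_thresholds)
  within <- vapply(thresholds,
                   function(t) sum(if (inclusive) err <= t else err < t),
                   numeric(1))
  beyond <- vapply(outlier_thresholds, function(t) sum(err > t), numeric(1))
  names(within) <- paste0("within_", thresholds)
  names(beyond) <- paste0("beyond_", outlier_thresholds)
  structure(list(
    n = n,
    within = within,
    within_frac = if (n > 0) within / n else within * NA_real_,
    beyond = beyond,
    beyond_frac = if (n > 0) beyond / n else beyond * NA_real_,
    mae = if (n > 0) mean(err) else NA_real_,
    sd_ae = if (n > 1) stats::sd(err) else NA_real_,
    inclusive = inclusive
  ), class = "inr_eval_report")
}

#' @export
print.inr_eval_report <- function(x, ...) {
  cat("<inr_eval_report> n =", x$n, "\n")
  if (x$n > 0) {
    for (i in seq_along(x$within)) {
      cat(sprintf("  %s of the actual value: %d (%.1f%%)\n",
                  sub("_", " ", names(x$within)[i]), x$within[i],
                  100 * x$within_frac[i]))
    }
    for (i in seq_along(x$beyond)) {
      cat(sprintf("  %s from the actual value: %d (%.1f%%)\n",
                  sub("_", " > ", names(x$beyond)[i]), x$beyond[i],
                  100 * x$beyond_frac[i]))
    }
    cat(sprintf("  absolute error: %.3f +/- %.3f\n", x$mae,
                ifelse(is.na(x$sd_ae), 0, x$sd_ae)))
  }
  invisible(x)
}

#' Two-proportion comparison
#'
#' Compares two success proportions with the uncorrected pooled two-proportion
#' z-test (two-sided), the test that reproduces the published comparisons of
#' model and physician accuracy bands from their printed counts. Fisher's
#' exact test is available as an alternative.
#'
#' @param k1,n1 Successes and total for group 1.
#' @param k2,n2 Successes and total for group 2.
#' @param method `"z"` (default) or `"fisher"`.
#' @return An `inr_prop_test`: proportions, test statistic, two-sided
#'   `p_value` (full precision; display-rounded to 3 decimals in print).
#' @export
compare_proportions <- function(k1, n1, k2, n2, method = c("z", "fisher")) {
  method <- match.arg(method)
  for (v in list(k1, n1, k2, n2)) {
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v)) {
      stop("counts must be single non-negative integers", call. = FALSE)
    }
  }
  if (n1 < 1 || n2 < 1) stop("totals must be >= 1", call. = FALSE)
  if (k1 > n1 || k2 > n2) stop("successes cannot exceed totals", call. = FALSE)
  p1 <- k1 / n1; p2 <- k2 / n2
  if (method == "z") {
    pp <- (k1 + k2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    p <- 2 * stats::pnorm(-abs(z))
    stat <- c(z = z)
    name <- "two-proportion z-test (pooled, uncorrected)"
  } else {
    ft <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                                    byrow = TRUE))
    p <- ft$p.value
    stat <- c(odds_ratio = unname(ft$estimate))
    name <- "Fisher's exact test"
  }
  structure(list(k = c(k1, k2), n = c(n1, n2), proportions = c(p1, p2),
                 statistic = stat, p_value = p, method = name),
            class = "inr_prop_test")
}

#' @export
print.inr_prop_test <- function(x, ...) {
  cat("<inr_prop_test>", x$method, "\n")
  cat(sprintf("  group 1: %d/%d (%.1f%%)   group 2: %d/%d (%.1f%%)\n",
              x$k[1], x$n[1], 100 * x$proportions[1],
              x$k[2], x$n[2], 100 * x$proportions[2]))
  cat(sprintf("  %s = %.4f, two-sided p = %.3f\n", names(x$statistic),
              x$statistic, x$p_value))
  invisible(x)
}

#' Evaluate chained day-8 predictions against held-out fixed-dose stays
#'
#' For each case from [select_chain_eval_cases()], runs the chain calculation
#' from the case's days 1-4 with the case's own fixed day 4-7 dose, takes the
#' day-8 prediction, and scores all cases with [accuracy_bands()].
#'
#' @param predictor As in [chain_predict()].
#' @param cases Data frame from [select_chain_eval_cases()] (may be empty or
#'   `NULL`).
#' @param ... Passed to [accuracy_bands()].
#' @return An `inr_eval_report` with attribute `predictions` (the per-case
#'   day-8 predictions).
#' @export
evaluate_chain <- function(predictor, cases, ...) {
  if (is.null(cases) || nrow(cases) == 0) {
    return(accuracy_bands(numeric(0), numeric(0), ...))
  }
  preds <- chain_predict(predictor, cases, cases$fixed_dose, horizon = 4)
  day8 <- preds[, "day8"]
  rep <- accuracy_bands(day8, cases$actual_day8_inr, ...)
  attr(rep, "predictions") <- day8
  rep
}
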