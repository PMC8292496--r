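#' Fit a feature standardizer on training windows
#'
#' Computes per-feature means and standard deviations (sample, n-1 convention)
#' for the 5 static features, the two series channels (INR and dose, pooled
#' over the four day positions), and the target INR. All variables, the
#' target included, are shifted and scaled to mean 0 / sd 1; predictions are
#' mapped back with the stored target statistics. Statistics must come from
#' training data only; test data are transformed with the stored values.
#'
#' @param windows Training windows from [extract_windows()] (>= 2 rows).
#' @return An object of class `inr_standardizer`.
#' @export
fit_standardizer <- function(windows) {
  if (nrow(windows) < 2) stop("need >= 2 training samples", call. = FALSE)
  static_cols <- c("sex", "age", "weight_kg", "height_cm", "bsa")
  stats <- list()
  for (col in static_cols) {
    stats[[col]] <- c(mean = mean(windows[[col]]), sd = stats::sd(windows[[col]]))
  }
  inr_vals <- unlist(windows[paste0("inr", 1:4)], use.names = FALSE)
  dose_vals <- unlist(windows[paste0("dose", 1:4)], use.names = FALSE)
  stats$inr <- c(mean = mean(inr_vals), sd = stats::sd(inr_vals))
  stats$dose <- c(mean = mean(dose_vals), sd = stats::sd(dose_vals))
  stats$target_inr <- c(mean = mean(windows$target_inr),
                        sd = stats::sd(windows$target_inr))
  zero <- names(stats)[vapply(stats, function(s) s["sd"] <= 0, logical(1))]
  if (length(zero) > 0) {
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  structure(list(stats = stats, sd_convention = "sample"),
            class = "inr_standardizer")
}

#' @export
print.inr_standardizer <- function(x, ...) {
  cat("<inr_standardizer> (", x$sd_convention, " sd)\n", sep = "")
  m <- do.call(rbind, x$stats)
  print(round(m, 4))
  invisible(x)
}

std_feature <- function(std, feature, x, inverse = FALSE) {
  s <- std$stats[[feature]]
  if (is.null(s)) stop("unknown feature '", feature, "'", call. = FALSE)
  if (inverse) x * s["sd"] + s["mean"] else (x - s["mean"]) / s["sd"]
}

#' Standardize or inverse-standardize windows
#'
#' @param std An `inr_standardizer`.
#' @param windows Windows data frame (the `target_inr` column is optional).
#' @param inverse If `TRUE`, map standardized values back to original scale.
#' @return Windows data frame with transformed numeric columns.
#' @export
standardize_windows <- function(std, windows, inverse = FALSE) {
  out <- windows
  for (col in c("sex", "age", "weight_kg", "height_cm", "bsa")) {
    out[[col]] <- std_feature(std, col, windows[[col]], inverse)
  }
  for (j in 1:4) {
    out[[paste0("inr", j)]] <- std_feature(std, "inr", windows[[paste0("inr", j)]], inverse)
    out[[paste0("dose", j)]] <- std_feature(std, "dose", windows[[paste0("dose", j)]], inverse)
  }
  if ("target_inr" %in% names(windows)) {
    out$target_inr <- std_feature(std, "target_inr", windows$target_inr, inverse)
  }
  out
}

#' Serialize / restore a standardizer as JSON
#'
#' @param std An `inr_standardizer`.
#' @param path File path for the JSON representation.
#' @return `read_standardizer` returns the restored `inr_standardizer`.
#' @export
write_standardizer <- function(std, path) {
  # values stored as %.17g strings: doubles round-trip exactly
  obj <- list(sd_convention = std$sd_convention,
              features = lapply(std$stats, function(s)
                list(mean = sprintf("%.17g", unname(s["mean"])),
                     sd = sprintf("%.17g", unname(s["sd"])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  obj <- jsonlite::read_json(path)
  stats <- lapply(obj$features, function(s)
    c(mean = as.numeric(s$mean), sd = as.numeric(s$sd)))
  structure(list(stats = stats, sd_convention = obj$sd_convention),
            class = "inr_standardizer")
}
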