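#' Chain calculation: roll the day-5 predictor forward under a fixed dose
#'
#' Starting from real INRs for days 1-4 and real doses for days 1-3, a
#' virtual fixed dose is inserted for day 4 and the day-5 INR is predicted.
#' The window then slides one day: the predicted INR and another copy of the
#' fixed dose are appended, days 2-5 predict day 6, and so on for `horizon`
#' steps. Predicted INRs are fed back on the raw INR scale and re-standardized
#' at each step; no clipping is applied (out-of-range values are the caller's
#' signal that the rollout diverged).
#'
#' @param predictor A trained [train_predictor()] object, or any function
#'   `f(static, series)` mapping an `n x 5` static matrix and an `n x 8`
#'   series matrix (columns `inr1..inr4, dose1..dose4`) to `n` predicted INRs
#'   (useful for stubs and oracles).
#' @param chain_input Data frame with one row per patient: `sex`, `age`,
#'   `weight_kg`, `height_cm`, `bsa` (computed from height/weight when
#'   absent), real `inr1..inr4` and real `dose1..dose3`.
#' @param fixed_dose Virtual daily dose in mg (> 0); scalar or one per row.
#' @param horizon Number of days to predict (default 4: days 5-8).
#' @return Numeric matrix, one row per patient, columns `day5 .. day<4+H>`.
#' @export
chain_predict <- function(predictor, chain_input, fixed_dose, horizon = 4) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  ci <- as.data.frame(chain_input)
  if (!"bsa" %in% names(ci)) ci$bsa <- compute_bsa(ci$height_cm, ci$weight_kg)
  need <- c("sex", "age", "weight_kg", "height_cm", "bsa",
            paste0("inr", 1:4), paste0("dose", 1:3))
  missing <- setdiff(need, names(ci))
  if (length(missing) > 0) {
    stop("chain_input is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ci)
  fixed_dose <- rep_len(as.numeric(fixed_dose), n)
  if (any(fixed_dose <= 0)) stop("fixed_dose must be > 0", call. = FALSE)
  if (any(as.matrix(ci[paste0("dose", 1:3)]) <= 0)) {
    stop("real doses for days 1-3 must be > 0", call. = FALSE)
  }

  one_step <- if (is.function(predictor)) {
    predictor
  } else if (inherits(predictor, "inr_predictor")) {
    function(Xs, Xq) predict_core(predictor, Xs, Xq)
  } else {
    stop("predictor must be an inr_predictor or a function(static, series)",
         call. = FALSE)
  }

  Xs <- as.matrix(ci[c("sex", "age", "weight_kg", "height_cm", "bsa")])
  inrs <- as.matrix(ci[paste0("inr", 1:4)])
  doses <- cbind(as.matrix(ci[paste0("dose", 1:3)]), fixed_dose)
  out <- matrix(NA_real_, n, horizon,
                dimnames = list(NULL, paste0("day", 5:(4 + horizon))))
  for (h in seq_len(horizon)) {
    pred <- one_step(Xs, unname(cbind(inrs, doses)))
    if (length(pred) != n) {
      stop("one-step predictor returned ", length(pred), " values for ", n,
           " patients", call. = FALSE)
    }
    out[, h] <- pred
    inrs <- cbind(inrs[, 2:4, drop = FALSE], pred)
    doses <- cbind(doses[, 2:4, drop = FALSE], fixed_dose)
  }
  out
}

#' Generate an individualized warfarin dose-PT INR table
#'
#' Runs the chain calculation for one patient across a grid of candidate
#' fixed daily doses and tabulates the predicted INRs for days 5 to
#' `4 + horizon`. The default grid is 1.0-8.0 mg in 0.5 mg increments,
#' endpoints included (15 rows). Cells outside the plausible INR range
#' (<= 0 or > 10) are flagged, never truncated.
#'
#' @param predictor As in [chain_predict()].
#' @param chain_input One-row chain input (see [chain_predict()]).
#' @param grid Strictly increasing vector of positive doses in mg.
#' @param horizon Days to predict (default 4).
#' @return A `dose_inr_table`: data frame with `dose_mg` and one column per
#'   predicted day, plus attributes `horizon`, `grid` and `out_of_range`
#'   (logical matrix of flagged cells).
#' @export
generate_dose_table <- function(predictor, chain_input,
                                grid = seq(1, 8, by = 0.5), horizon = 4) {
  if (length(grid) == 0) stop("dose grid must be non-empty", call. = FALSE)
  if (any(grid <= 0)) stop("all grid doses must be > 0", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0)) {
    stop("dose grid must be strictly increasing", call. = FALSE)
  }
  ci <- as.data.frame(chain_input)
  if (nrow(ci) != 1) {
    stop("generate_dose_table expects a single patient (one row)",
         call. = FALSE)
  }
  rows <- lapply(grid, function(d) chain_predict(predictor, ci, d, horizon))
  m <- do.call(rbind, rows)
  tab <- data.frame(dose_mg = grid, m, check.names = FALSE)
  oor <- !is.finite(m) | m <= 0 | m > 10
  structure(tab, class = c("dose_inr_table", "data.frame"),
            horizon = horizon, grid = grid, out_of_range = oor)
}

#' @export
print.dose_inr_table <- function(x, ...) {
  cat("Individualized warfarin dose-PT INR table (predicted)\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, 2)
  print.data.frame(df, row.names = FALSE)
  if (any(attr(x, "out_of_range"))) {
    cat("note:", sum(attr(x, "out_of_range")),
        "cell(s) outside the plausible INR range (flagged, not truncated)\n")
  }
  invisible(x)
}

#' Convergence diagnostic for a dose-INR table
#'
#' Under repeated fixed dosing the predicted INR should stabilize; this
#' reports, per dose row, the largest absolute day-to-day change across the
#' predicted days and flags rows that exceed a threshold.
#'
#' @param table A [generate_dose_table()] result (horizon >= 2).
#' @param threshold Flag rows whose maximum day-to-day step exceeds this
#'   (INR units; default 0.2).
#' @return Data frame with `dose_mg`, `max_step` and `flagged`.
#' @export
convergence_diagnostic <- function(table, threshold = 0.2) {
  day_cols <- grep("^day", names(table), value = TRUE)
  if (length(day_cols) < 2) {
    stop("convergence diagnostic needs horizon >= 2", call. = FALSE)
  }
  m <- as.matrix(as.data.frame(table)[day_cols])
  steps <- abs(m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE])
  max_step <- apply(steps, 1, max)
  data.frame(dose_mg = table$dose_mg, max_step = max_step,
             flagged = max_step > threshold)
}
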