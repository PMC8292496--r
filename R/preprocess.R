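#' Body surface area by the Mosteller formula
#'
#' Computes BSA in square metres as `sqrt(height_cm * weight_kg / 3600)`.
#'
#' @param height_cm Height in centimetres (> 0).
#' @param weight_kg Body weight in kilograms (> 0).
#' @return Numeric vector of BSA values in m^2.
#' @examples
#' compute_bsa(180, 80)  # exactly 2
#' @export
compute_bsa <- function(height_cm, weight_kg) {
  if (!is.numeric(height_cm) || !is.numeric(weight_kg)) {
    stop("height_cm and weight_kg must be numeric", call. = FALSE)
  }
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height_cm and weight_kg must be finite and positive", call. = FALSE)
  }
  sqrt(height_cm * weight_kg / 3600)
}

# Columns every daily-record data frame must carry, in schema order.
daily_record_columns <- function() {
  c("patient_id", "day", "sex", "age", "weight_kg", "height_cm",
    "inr", "dose_mg", "doses_per_day", "administered")
}

check_daily_schema <- function(records) {
  missing <- setdiff(daily_record_columns(), names(records))
  if (length(missing) > 0) {
    stop("daily records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("day", "age", "weight_kg", "height_cm", "inr", "dose_mg",
                "doses_per_day", "administered")
  for (col in num_cols) {
    if (!is.numeric(records[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  invisible(records)
}

#' Consolidate raw measurements into one record per patient-day
#'
#' Raw exports may carry several rows for the same patient-day (repeat INR
#' measurements, one row per dose administration, prescriptions that were never
#' given). This collapses them to a single row: the day's INR by the chosen
#' policy, the total dose actually administered, and the count of administered
#' doses. Rows with `administered == 0` contribute nothing to the day's dose.
#'
#' @param records Data frame in the daily-record schema (see
#'   [read_daily_records()]).
#' @param inr_policy How to consolidate multiple same-day INR measurements:
#'   `"last"` (default; the value seen latest in row order, clinically the one
#'   available before evening dosing) or `"mean"`.
#' @return Data frame with one row per patient-day, sorted by patient and day.
#' @export
consolidate_daily <- function(records, inr_policy = c("last", "mean")) {
  inr_policy <- match.arg(inr_policy)
  check_daily_schema(records)
  key <- paste(records$patient_id, records$day, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  out <- lapply(idx, function(i) {
    rows <- records[i, , drop = FALSE]
    statics <- unique(rows[, c("sex", "age", "weight_kg", "height_cm")])
    if (nrow(statics) > 1) {
      stop("conflicting static covariates for patient ", rows$patient_id[1],
           " day ", rows$day[1], call. = FALSE)
    }
    inrs <- rows$inr[!is.na(rows$inr)]
    if (length(inrs) == 0) {
      stop("no PT INR measurement for patient ", rows$patient_id[1],
           " day ", rows$day[1], call. = FALSE)
    }
    inr <- if (inr_policy == "last") inrs[length(inrs)] else mean(inrs)
    given <- rows$administered == 1 & !is.na(rows$dose_mg)
    data.frame(
      patient_id = rows$patient_id[1],
      day = rows$day[1],
      sex = rows$sex[1],
      age = rows$age[1],
      weight_kg = rows$weight_kg[1],
      height_cm = rows$height_cm[1],
      inr = inr,
      dose_mg = sum(rows$dose_mg[given]),
      doses_per_day = sum(rows$doses_per_day[given]),
      administered = 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$patient_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the cohort exclusion filters
#'
#' Removes unreliable observations with the strict boundaries as stated:
#' patients with weight < 35 or > 120 kg, height < 130 or > 220 cm, age < 18
#' years, or any day on which warfarin was taken two or more times; records
#' with PT INR > 10.0 or daily dose > 20 mg. Values exactly at a boundary
#' (35 kg, 120 kg, 130 cm, 220 cm, INR 10.0, 20 mg) are retained.
#'
#' @param records Consolidated daily records (one row per patient-day).
#' @return A list with `records` (retained rows) and `log`, a data frame of
#'   per-rule exclusion counts (`rule`, `level`, `n_excluded`) reproducing the
#'   attrition accounting.
#' @export
apply_exclusion_filters <- function(records) {
  check_daily_schema(records)
  log <- data.frame(rule = character(), level = character(),
                    n_excluded = integer(), stringsAsFactors = FALSE)
  add_log <- function(rule, level, n) {
    rbind(log, data.frame(rule = rule, level = level, n_excluded = n,
                          stringsAsFactors = FALSE))
  }

  # Patient-level rules: any offending day excludes the whole patient.
  patient_rules <- list(
    weight_out_of_range = function(r) r$weight_kg < 35 | r$weight_kg > 120,
    height_out_of_range = function(r) r$height_cm < 130 | r$height_cm > 220,
    under_18            = function(r) r$age < 18,
    multiple_daily_doses = function(r) r$doses_per_day >= 2
  )
  for (rule in names(patient_rules)) {
    bad <- patient_rules[[rule]](records)
    bad_patients <- unique(records$patient_id[bad])
    drop <- records$patient_id %in% bad_patients
    log <- add_log(rule, "patient", length(bad_patients))
    records <- records[!drop, , drop = FALSE]
  }

  # Record-level rules: only the offending day is dropped.
  record_rules <- list(
    inr_above_10  = function(r) r$inr > 10.0,
    dose_above_20 = function(r) r$dose_mg > 20
  )
  for (rule in names(record_rules)) {
    bad <- record_rules[[rule]](records)
    log <- add_log(rule, "record", sum(bad))
    records <- records[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  list(records = records, log = log)
}

# Runs of k consecutive days with INR present and dose > 0 on each day.
# Returns start indices within the patient's day-sorted rows.
eligible_run_starts <- function(days, inr, dose, k) {
  n <- length(days)
  if (n < k) return(integer(0))
  ok <- !is.na(inr) & !is.na(dose) & dose > 0
  starts <- integer(0)
  for (s in seq_len(n - k + 1)) {
    i <- s:(s + k - 1)
    if (all(ok[i]) && all(diff(days[i]) == 1)) starts <- c(starts, s)
  }
  starts
}

#' Extract 5-day training windows in single-line format
#'
#' Slides a window over each patient's consolidated, filtered records and
#' emits one sample per run of `window_length` consecutive days that all have
#' an INR and a positive administered dose. The first four days supply the
#' (INR, dose) series, the fifth day's INR is the prediction target. Windows
#' overlap by default and never span patients. Days with a 0 mg dose break
#' windows: the model is not trained on missed administrations.
#'
#' @param records Consolidated, filtered daily records.
#' @param window_length Days per window (default 5: 4 input days + target).
#' @param overlapping If `FALSE`, windows within a patient are taken greedily
#'   without overlap instead of at every eligible start day.
#' @return Data frame with columns `patient_id`, `start_day`, `sex`, `age`,
#'   `weight_kg`, `height_cm`, `bsa`, `inr1..inr4`, `dose1..dose4`,
#'   `target_inr`.
#' @export
extract_windows <- function(records, window_length = 5, overlapping = TRUE) {
  check_daily_schema(records)
  if (window_length < 2) stop("window_length must be >= 2", call. = FALSE)
  k <- window_length
  res <- lapply(split(records, records$patient_id), function(r) {
    r <- r[order(r$day), , drop = FALSE]
    starts <- eligible_run_starts(r$day, r$inr, r$dose_mg, k)
    if (!overlapping && length(starts) > 1) {
      keep <- starts[1]
      for (s in starts[-1]) if (s >= keep[length(keep)] + k) keep <- c(keep, s)
      starts <- keep
    }
    if (length(starts) == 0) return(NULL)
    do.call(rbind, lapply(starts, function(s) {
      i <- s:(s + k - 1)
      w <- data.frame(
        patient_id = r$patient_id[1],
        start_day = r$day[s],
        sex = r$sex[1],
        age = r$age[1],
        weight_kg = r$weight_kg[1],
        height_cm = r$height_cm[1],
        bsa = compute_bsa(r$height_cm[1], r$weight_kg[1]),
        stringsAsFactors = FALSE
      )
      for (j in seq_len(k - 1)) w[[paste0("inr", j)]] <- r$inr[i[j]]
      for (j in seq_len(k - 1)) w[[paste0("dose", j)]] <- r$dose_mg[i[j]]
      w$target_inr <- r$inr[i[k]]
      w
    }))
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(patient_id = character(), start_day = numeric(),
                      sex = numeric(), age = numeric(), weight_kg = numeric(),
                      height_cm = numeric(), bsa = numeric(),
                      stringsAsFactors = FALSE)
    for (j in 1:(k - 1)) res[[paste0("inr", j)]] <- numeric()
    for (j in 1:(k - 1)) res[[paste0("dose", j)]] <- numeric()
    res$target_inr <- numeric()
  }
  rownames(res) <- NULL
  res
}

#' Select 8-day chain-evaluation cases
#'
#' Finds every run of 8 consecutive days within a patient where the same dose
#' was administered on days 4-7 of the run (the fixed-dose assumption behind
#' the chain calculation). The day-8 INR is kept as ground truth. Doses on
#' days 1-7 must be positive; the day-8 dose is not used.
#'
#' @param records Consolidated, filtered daily records.
#' @param dose_tol Numeric tolerance for "identical" day 4-7 doses (default 0:
#'   exact equality).
#' @return Data frame with static columns, `inr1..inr8`, `dose1..dose8`,
#'   `fixed_dose` (the common day 4-7 dose) and `actual_day8_inr`.
#' @export
select_chain_eval_cases <- function(records, dose_tol = 0) {
  check_daily_schema(records)
  res <- lapply(split(records, records$patient_id), function(r) {
    r <- r[order(r$day), , drop = FALSE]
    n <- nrow(r)
    if (n < 8) return(NULL)
    rows <- list()
    for (s in seq_len(n - 7)) {
      i <- s:(s + 7)
      if (any(diff(r$day[i]) != 1)) next
      if (any(is.na(r$inr[i]))) next
      d <- r$dose_mg[i]
      if (any(is.na(d[1:7])) || any(d[1:7] <= 0)) next
      if (max(d[4:7]) - min(d[4:7]) > dose_tol) next
      w <- data.frame(
        patient_id = r$patient_id[1],
        start_day = r$day[s],
        sex = r$sex[1], age = r$age[1],
        weight_kg = r$weight_kg[1], height_cm = r$height_cm[1],
        bsa = compute_bsa(r$height_cm[1], r$weight_kg[1]),
        stringsAsFactors = FALSE
      )
      for (j in 1:8) w[[paste0("inr", j)]] <- r$inr[i[j]]
      for (j in 1:8) w[[paste0("dose", j)]] <- d[j]
      w$fixed_dose <- d[4]
      w$actual_day8_inr <- r$inr[i[8]]
      rows[[length(rows) + 1]] <- w
    }
    if (length(rows) == 0) NULL else do.call(rbind, rows)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) return(res)
  rownames(res) <- NULL
  res
}
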