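#' Read daily inpatient records from CSV
#'
#' Expects a UTF-8 header row with exactly the documented columns:
#' `patient_id,day,sex,age,weight_kg,height_cm,inr,dose_mg,doses_per_day,administered`
#' with `sex` in {M, F} and `administered` in {0, 1}. Numeric fields are
#' parsed locale-independently (dot decimal); a comma decimal is a parse
#' error, not a silent coercion. Several rows per patient-day are allowed
#' (repeat measurements, per-administration rows) but byte-identical
#' duplicate rows are rejected as double entries.
#'
#' @param path CSV file path.
#' @return Data frame in the daily-record schema (sex recoded 0 = F, 1 = M),
#'   with a `schema_report` attribute (`n_rows`, `n_patients`).
#' @export
read_daily_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  expected <- daily_record_columns()
  missing <- setdiff(expected, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), expected)
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, integer_only = FALSE) {
    x <- trimws(raw[[col]])
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(x %in% c("", "NA")))
    if (length(bad) > 0) {
      stop("non-numeric value '", x[bad[1]], "' in column '", col,
           "' at data row ", bad[1], call. = FALSE)
    }
    if (integer_only) {
      frac <- which(!is.na(v) & v != round(v))
      if (length(frac) > 0) {
        stop("non-integer value in column '", col, "' at data row ", frac[1],
             call. = FALSE)
      }
    }
    v
  }
  sex_chr <- trimws(raw$sex)
  bad_sex <- which(!sex_chr %in% c("M", "F"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'M' or 'F' at data row ", bad_sex[1], call. = FALSE)
  }
  records <- data.frame(
    patient_id = raw$patient_id,
    day = parse_num("day", integer_only = TRUE),
    sex = ifelse(sex_chr == "M", 1, 0),
    age = parse_num("age"),
    weight_kg = parse_num("weight_kg"),
    height_cm = parse_num("height_cm"),
    inr = parse_num("inr"),
    dose_mg = parse_num("dose_mg"),
    doses_per_day = parse_num("doses_per_day", integer_only = TRUE),
    administered = parse_num("administered", integer_only = TRUE),
    stringsAsFactors = FALSE
  )
  if (any(!records$administered %in% c(0, 1))) {
    stop("administered must be 0 or 1", call. = FALSE)
  }
  if (any(records$day < 1)) stop("day must be >= 1", call. = FALSE)
  dup <- duplicated(raw)
  if (any(dup)) {
    stop("byte-identical duplicate row(s) at data row ",
         which(dup)[1], call. = FALSE)
  }
  attr(records, "schema_report") <- list(
    n_rows = nrow(records),
    n_patients = length(unique(records$patient_id))
  )
  records
}

#' Write daily records to schema-conformant CSV
#'
#' @param records In-memory daily records (numeric sex 0/1).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_daily_records <- function(records, path) {
  check_daily_schema(records)
  out <- records
  out$sex <- ifelse(records$sex == 1, "M", "F")
  utils::write.csv(out[daily_record_columns()], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

log_line <- function(log_path, stage, ...) {
  if (is.null(log_path)) return(invisible(NULL))
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = log_path, append = TRUE)
  invisible(NULL)
}

run_config_keys <- function() {
  c("stages", "seed", "out_dir", "log", "n_patients", "n_days",
    "cohort_csv", "truth_json", "windows_csv", "cases_csv",
    "exclusions_csv", "model_dir", "table_csv", "report_json",
    "patient_csv", "grid", "inr_policy", "network", "population")
}

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected so typos cannot silently change a run.
#'
#' @param config Named list (possibly read from YAML).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), run_config_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(stages = c("simulate", "preprocess", "train", "evaluate"),
                   seed = 1L, out_dir = ".", log = NULL,
                   n_patients = 200L, n_days = 10L, grid = "1.0:8.0:0.5",
                   inr_policy = "last",
                   network = list(), population = list())
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  bad <- setdiff(config$stages,
                 c("simulate", "preprocess", "train", "table", "evaluate"))
  if (length(bad) > 0) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  config
}

parse_grid <- function(grid) {
  if (is.numeric(grid)) return(grid)
  parts <- as.numeric(strsplit(grid, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3 || any(is.na(parts))) {
    stop("grid must be 'lo:hi:step', e.g. '1.0:8.0:0.5'", call. = FALSE)
  }
  seq(parts[1], parts[2], by = parts[3])
}

path_in <- function(config, key, default) {
  p <- config[[key]]
  if (is.null(p)) p <- file.path(config$out_dir, default)
  p
}

#' Run the simulate / preprocess / train / table / evaluate pipeline
#'
#' Dispatches the configured stages in order. Each stage writes its artifact
#' under `out_dir` and appends one machine-parseable JSON log line with its
#' input and output row counts, reproducing an attrition trail, plus the
#' hash of the resolved configuration.
#'
#' @param config Named list or YAML file path; see [validate_run_config()]
#'   for the recognised keys. All randomness flows from `config$seed`.
#' @return Exit status 0, invisibly; any stage failure raises an error.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config[order(names(config))], cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  log <- config$log

  cohort_csv <- path_in(config, "cohort_csv", "cohort.csv")
  truth_json <- path_in(config, "truth_json", "truth.json")
  windows_csv <- path_in(config, "windows_csv", "windows.csv")
  cases_csv <- path_in(config, "cases_csv", "chain_cases.csv")
  exclusions_csv <- path_in(config, "exclusions_csv", "exclusions.csv")
  model_dir <- path_in(config, "model_dir", "model")
  table_csv <- path_in(config, "table_csv", "dose_table.csv")
  report_json <- path_in(config, "report_json", "report.json")

  for (stage in config$stages) {
    if (stage == "simulate") {
      pop <- do.call(pkpd_population, config$population)
      cohort <- generate_cohort(config$n_patients, config$n_days, pop,
                                seed = config$seed)
      write_daily_records(cohort$records, cohort_csv)
      jsonlite::write_json(
        list(seed = cohort$truth$seed, params = cohort$truth$params,
             dosing = cohort$truth$dosing,
             noiseless = cohort$truth$noiseless),
        truth_json, digits = NA)
      log_line(log, "simulate", config_hash = cfg_hash, seed = config$seed,
               n_patients = config$n_patients,
               n_rows_out = nrow(cohort$records))
    } else if (stage == "preprocess") {
      records <- read_daily_records(cohort_csv)
      n_in <- nrow(records)
      records <- consolidate_daily(records, inr_policy = config$inr_policy)
      filt <- apply_exclusion_filters(records)
      windows <- extract_windows(filt$records)
      cases <- select_chain_eval_cases(filt$records)
      utils::write.csv(windows, windows_csv, row.names = FALSE)
      utils::write.csv(filt$log, exclusions_csv, row.names = FALSE)
      if (!is.null(cases)) {
        utils::write.csv(cases, cases_csv, row.names = FALSE)
      }
      log_line(log, "preprocess", config_hash = cfg_hash, n_rows_in = n_in,
               n_rows_kept = nrow(filt$records), n_windows = nrow(windows),
               n_chain_cases = if (is.null(cases)) 0L else nrow(cases))
    } else if (stage == "train") {
      windows <- utils::read.csv(windows_csv)
      net_args <- config$network
      net_args$seed <- config$seed
      net_config <- do.call(network_config, net_args)
      predictor <- train_predictor(windows, net_config)
      save_predictor(predictor, model_dir)
      log_line(log, "train", config_hash = cfg_hash,
               n_samples = nrow(windows), epochs = nrow(predictor$history),
               best_val_loss = predictor$best_val_loss)
    } else if (stage == "table") {
      predictor <- load_predictor(model_dir)
      patient_csv <- config$patient_csv
      if (is.null(patient_csv)) {
        stop("the table stage needs patient_csv (one chain-input row)",
             call. = FALSE)
      }
      patient <- utils::read.csv(patient_csv)
      tab <- generate_dose_table(predictor, patient[1, , drop = FALSE],
                                 grid = parse_grid(config$grid))
      utils::write.csv(as.data.frame(tab), table_csv, row.names = FALSE)
      log_line(log, "table", config_hash = cfg_hash, n_doses = nrow(tab))
    } else if (stage == "evaluate") {
      if (!dir.exists(model_dir)) {
        stop("evaluate needs a trained model bundle at ", model_dir,
             call. = FALSE)
      }
      predictor <- load_predictor(model_dir)
      windows <- utils::read.csv(windows_csv)
      day5 <- accuracy_bands(predict(predictor, windows),
                             windows$target_inr)
      cases <- if (file.exists(cases_csv)) utils::read.csv(cases_csv) else NULL
      day8 <- evaluate_chain(predictor, cases)
      report <- list(config_hash = cfg_hash,
                     day5 = unclass(day5)[c("n", "within", "within_frac",
                                            "beyond", "beyond_frac",
                                            "mae", "sd_ae")],
                     day8_chain = unclass(day8)[c("n", "within",
                                                  "within_frac", "beyond",
                                                  "beyond_frac", "mae",
                                                  "sd_ae")])
      jsonlite::write_json(report, report_json, auto_unbox = TRUE, digits = NA)
      log_line(log, "evaluate", config_hash = cfg_hash, n_day5 = day5$n,
               n_day8 = day8$n)
    }
  }
  invisible(0L)
}
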