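#' Configuration for the day-5 INR predictor network
#'
#' Defaults mirror the published architecture: a dense branch of 2 x 16 ReLU
#' units over the 5 static covariates, 5 stacked LSTM layers of 32 units over
#' the 4-day (INR, dose) series, and a dense head of 4 x 32 ReLU layers ending
#' in a single linear output. Mean absolute error loss, Adam optimizer, and a
#' 20% validation split with early stopping at the onset of overfitting.
#'
#' @param static_branch Integer vector of dense-layer widths for the static
#'   branch (each capped at 16 by convention; default `c(16, 16)`).
#' @param recurrent_layers Number of stacked LSTM layers (default 5).
#' @param recurrent_units Units per LSTM layer (default 32).
#' @param head_layers,head_units Dense head depth and width (default 4 x 32).
#' @param output_units Must be 1: the network emits one predicted INR.
#' @param learning_rate,batch_size,max_epochs,early_stop_patience Adam
#'   learning rate and the training loop controls.
#' @param validation_fraction Fraction of training samples held out for the
#'   validation loss that drives early stopping (default 0.20).
#' @param seed Integer seed controlling weight initialization and shuffles.
#' @return An object of class `inr_network_config`.
#' @export
network_config <- function(static_branch = c(16, 16),
                           recurrent_layers = 5,
                           recurrent_units = 32,
                           head_layers = 4,
                           head_units = 32,
                           output_units = 1,
                           learning_rate = 1e-3,
                           batch_size = 64,
                           max_epochs = 200,
                           early_stop_patience = 10,
                           validation_fraction = 0.20,
                           seed = 1) {
  if (recurrent_layers < 1) stop("recurrent_layers must be >= 1", call. = FALSE)
  if (recurrent_units < 1 || head_units < 1 || head_layers < 1 ||
      any(static_branch < 1)) {
    stop("layer widths and counts must be positive", call. = FALSE)
  }
  if (output_units != 1) {
    stop("the head must emit exactly 1 value (output_units = 1)", call. = FALSE)
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    static_branch = as.integer(static_branch),
    recurrent_layers = as.integer(recurrent_layers),
    recurrent_units = as.integer(recurrent_units),
    head_layers = as.integer(head_layers),
    head_units = as.integer(head_units),
    output_units = 1L,
    activation = "relu",
    loss = "mae",
    optimizer = "adam",
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    early_stop_patience = as.integer(early_stop_patience),
    validation_fraction = validation_fraction,
    seed = as.integer(seed)
  ), class = "inr_network_config")
}

# Low-level layout shared with src/network.cpp.
cpp_cfg <- function(config) {
  list(static_widths = config$static_branch,
       lstm_layers = config$recurrent_layers,
       lstm_units = config$recurrent_units,
       head_layers = config$head_layers,
       head_units = config$head_units,
       n_static = 5L, seq_len = 4L, n_channels = 2L)
}

# Shapes of every weight matrix / bias in flat-vector order.
param_shapes <- function(config) {
  shapes <- list()
  add <- function(name, r, c) shapes[[name]] <<- c(r, c)
  input <- 5L
  for (j in seq_along(config$static_branch)) {
    w <- config$static_branch[j]
    add(paste0("static_W", j), input, w); add(paste0("static_b", j), 1L, w)
    input <- w
  }
  sin <- 2L; U <- config$recurrent_units
  for (l in seq_len(config$recurrent_layers)) {
    add(paste0("lstm_Wx", l), sin, 4L * U)
    add(paste0("lstm_Wh", l), U, 4L * U)
    add(paste0("lstm_b", l), 1L, 4L * U)
    sin <- U
  }
  hin <- config$static_branch[length(config$static_branch)] + U
  for (j in seq_len(config$head_layers)) {
    add(paste0("head_W", j), hin, config$head_units)
    add(paste0("head_b", j), 1L, config$head_units)
    hin <- config$head_units
  }
  add("out_W", hin, 1L); add("out_b", 1L, 1L)
  shapes
}

n_params <- function(config) {
  sum(vapply(param_shapes(config), prod, numeric(1)))
}

#' Build an untrained network with seeded initial weights
#'
#' Weight matrices get Glorot-uniform initialization, biases start at zero
#' except the LSTM forget-gate block, which starts at 1 (the standard
#' remember-by-default initialization). The same seed yields bitwise-identical
#' initial weights.
#'
#' @param config An [network_config()] object.
#' @return An object of class `inr_network` holding the flat parameter vector.
#' @export
build_network <- function(config) {
  if (!inherits(config, "inr_network_config")) {
    stop("config must come from network_config()", call. = FALSE)
  }
  shapes <- param_shapes(config)
  U <- config$recurrent_units
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  par <- unlist(lapply(names(shapes), function(nm) {
    dm <- shapes[[nm]]
    if (grepl("_b", nm)) {
      b <- rep(0, prod(dm))
      if (grepl("^lstm_b", nm)) b[(U + 1):(2 * U)] <- 1  # forget gate
      b
    } else {
      limit <- sqrt(6 / (dm[1] + dm[2]))
      stats::runif(prod(dm), -limit, limit)
    }
  }), use.names = FALSE)
  structure(list(par = par, config = config), class = "inr_network")
}

# Save/restore the global RNG state so builds don't disturb user streams.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' @export
print.inr_network <- function(x, ...) {
  cat("<inr_network> untrained;", length(x$par), "parameters\n")
  invisible(x)
}

# Windows data frame -> model matrices (raw scale).
windows_to_matrices <- function(windows, require_target = TRUE) {
  static_cols <- c("sex", "age", "weight_kg", "height_cm", "bsa")
  need <- c(static_cols, paste0("inr", 1:4), paste0("dose", 1:4))
  if (require_target) need <- c(need, "target_inr")
  missing <- setdiff(need, names(windows))
  if (length(missing) > 0) {
    stop("windows are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Xs <- as.matrix(windows[static_cols])
  Xq <- as.matrix(windows[c(paste0("inr", 1:4), paste0("dose", 1:4))])
  y <- if (require_target) windows$target_inr else NULL
  list(Xs = Xs, Xq = Xq, y = y)
}

# Standardize raw matrices with a fitted standardizer.
standardize_matrices <- function(std, Xs, Xq) {
  feats <- c("sex", "age", "weight_kg", "height_cm", "bsa")
  for (j in 1:5) Xs[, j] <- std_feature(std, feats[j], Xs[, j])
  for (j in 1:4) Xq[, j] <- std_feature(std, "inr", Xq[, j])
  for (j in 5:8) Xq[, j] <- std_feature(std, "dose", Xq[, j])
  list(Xs = Xs, Xq = Xq)
}

#' Train the day-5 INR predictor
#'
#' Shuffles the samples with the configured seed, holds out the last
#' `validation_fraction` as the validation set, fits the standardizer on the
#' training portion only, and minimizes mean absolute error on standardized
#' targets with Adam. Training stops once the validation loss has not improved
#' for `early_stop_patience` epochs (the onset of overfitting) and the
#' best-validation weights are restored.
#'
#' @param windows Training windows from [extract_windows()] (>= 10 rows).
#' @param config An [network_config()] object.
#' @param verbose Print per-epoch losses.
#' @return An object of class `inr_predictor`: weights, the standardizer used
#'   at fit time, the per-epoch loss history, config and seed.
#' @export
train_predictor <- function(windows, config = network_config(),
                            verbose = FALSE) {
  n <- nrow(windows)
  if (is.null(n) || n < 10) {
    stop("need at least 10 training samples, got ", n, call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  perm <- sample.int(n)
  n_val <- max(1L, floor(config$validation_fraction * n))
  val_idx <- perm[(n - n_val + 1):n]
  tr_idx <- perm[1:(n - n_val)]

  std <- fit_standardizer(windows[tr_idx, , drop = FALSE])
  mats <- windows_to_matrices(windows)
  sm <- standardize_matrices(std, mats$Xs, mats$Xq)
  y_std <- std_feature(std, "target_inr", mats$y)

  tXs <- sm$Xs[tr_idx, , drop = FALSE]; tXq <- sm$Xq[tr_idx, , drop = FALSE]
  ty <- y_std[tr_idx]
  vXs <- sm$Xs[val_idx, , drop = FALSE]; vXq <- sm$Xq[val_idx, , drop = FALSE]
  vy <- y_std[val_idx]

  net <- build_network(config)
  cfg <- cpp_cfg(config)
  par <- net$par
  m <- numeric(length(par)); v <- numeric(length(par)); step <- 0L
  best_par <- par; best_val <- Inf; best_epoch <- 0L; wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  n_tr <- length(ty)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr) - 1L
    res <- nn_train_epoch_cpp(par, m, v, step, tXs, tXq, ty, ord,
                              config$batch_size, config$learning_rate,
                              0.9, 0.999, 1e-8, cfg)
    par <- res$par; m <- res$m; v <- res$v; step <- res$step
    val_loss <- mean(abs(nn_forward_cpp(par, vXs, vXq, cfg) - vy))
    if (!is.finite(val_loss)) {
      stop("non-finite validation loss at epoch ", epoch,
           "; training diverged (try a lower learning rate)", call. = FALSE)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = res$train_loss,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      res$train_loss, val_loss))
    }
    if (val_loss < best_val) {
      best_val <- val_loss; best_par <- par; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  structure(list(par = best_par, config = config, standardizer = std,
                 history = history, best_epoch = best_epoch,
                 best_val_loss = best_val, seed = config$seed),
            class = "inr_predictor")
}

#' @export
print.inr_predictor <- function(x, ...) {
  cat("<inr_predictor>", length(x$par), "parameters; trained",
      nrow(x$history), "epochs (best epoch", x$best_epoch,
      sprintf("val MAE %.4f standardized)", x$best_val_loss), "\n")
  invisible(x)
}

# Forward pass on raw-scale matrices; returns INR-scale predictions.
predict_core <- function(predictor, Xs_raw, Xq_raw) {
  sm <- standardize_matrices(predictor$standardizer, Xs_raw, Xq_raw)
  z <- nn_forward_cpp(predictor$par, sm$Xs, sm$Xq, cpp_cfg(predictor$config))
  as.numeric(std_feature(predictor$standardizer, "target_inr", z,
                         inverse = TRUE))
}

#' Predict the 5th-day PT INR
#'
#' Applies the predictor to one patient: five static values and four day-
#' ordered (INR, dose) pairs. Inputs are standardized with the standardizer
#' stored at fit time and the output is returned on the INR scale.
#'
#' @param predictor A trained `inr_predictor`.
#' @param static Numeric vector of length 5: sex (0 = F, 1 = M), age, weight
#'   (kg), height (cm), BSA (m^2).
#' @param series 4 x 2 matrix: rows are days 1-4 in order, columns are
#'   (INR, dose_mg). All doses must be positive.
#' @return The predicted day-5 PT INR (scalar).
#' @export
predict_day5 <- function(predictor, static, series) {
  if (!inherits(predictor, "inr_predictor")) {
    stop("predictor must be a trained inr_predictor", call. = FALSE)
  }
  if (length(static) != 5) stop("static must have 5 values", call. = FALSE)
  series <- as.matrix(series)
  if (!all(dim(series) == c(4, 2))) {
    stop("series must be a 4 x 2 matrix of (inr, dose) day-ordered pairs",
         call. = FALSE)
  }
  if (any(series[, 2] <= 0)) stop("all 4 doses must be > 0", call. = FALSE)
  Xs <- matrix(as.numeric(static), nrow = 1)
  Xq <- matrix(c(series[, 1], series[, 2]), nrow = 1)
  predict_core(predictor, Xs, Xq)
}

#' @describeIn train_predictor Predict day-5 INR for each row of a windows
#'   data frame (the `target_inr` column, if present, is ignored).
#' @param object A trained `inr_predictor`.
#' @param newdata Windows data frame.
#' @param ... Unused.
#' @export
predict.inr_predictor <- function(object, newdata, ...) {
  mats <- windows_to_matrices(newdata, require_target = FALSE)
  predict_core(object, mats$Xs, mats$Xq)
}

#' Save or load a trained predictor as a model bundle directory
#'
#' The bundle holds `weights.txt` (full-precision flat parameter vector),
#' `standardizer.json`, `config.yaml`, `history.csv` and a `manifest.json`
#' with checksums so that mismatched weight/standardizer pairs are refused at
#' load time. The round trip reproduces bitwise-identical predictions.
#'
#' @param predictor A trained `inr_predictor`.
#' @param dir Bundle directory (created if needed).
#' @return `load_predictor` returns the restored `inr_predictor`.
#' @export
save_predictor <- function(predictor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(sprintf("%.17g", predictor$par), file.path(dir, "weights.txt"))
  write_standardizer(predictor$standardizer, file.path(dir, "standardizer.json"))
  cfg <- unclass(predictor$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  utils::write.csv(predictor$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  manifest <- list(
    weights_md5 = unname(tools::md5sum(file.path(dir, "weights.txt"))),
    standardizer_md5 = unname(tools::md5sum(file.path(dir, "standardizer.json"))),
    config_md5 = unname(tools::md5sum(file.path(dir, "config.yaml"))),
    best_epoch = predictor$best_epoch,
    best_val_loss = predictor$best_val_loss,
    seed = predictor$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(dir) {
  need <- c("weights.txt", "standardizer.json", "config.yaml", "history.csv",
            "manifest.json")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) {
      stop("model bundle is missing ", f, call. = FALSE)
    }
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  for (pair in list(c("weights_md5", "weights.txt"),
                    c("standardizer_md5", "standardizer.json"),
                    c("config_md5", "config.yaml"))) {
    actual <- unname(tools::md5sum(file.path(dir, pair[2])))
    if (!identical(actual, manifest[[pair[1]]])) {
      stop("model bundle checksum mismatch for ", pair[2],
           "; the weights/standardizer/config pairing cannot be trusted",
           call. = FALSE)
    }
  }
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- do.call(network_config, cfg_list[setdiff(names(cfg_list),
    c("activation", "loss", "optimizer"))])
  par <- as.numeric(readLines(file.path(dir, "weights.txt")))
  if (length(par) != n_params(config)) {
    stop("weights.txt length does not match the config architecture",
         call. = FALSE)
  }
  std <- read_standardizer(file.path(dir, "standardizer.json"))
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(par = par, config = config, standardizer = std,
                 history = history,
                 best_epoch = manifest$best_epoch,
                 best_val_loss = manifest$best_val_loss,
                 seed = manifest$seed),
            class = "inr_predictor")
}
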