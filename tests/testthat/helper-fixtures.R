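# Builders for small in-code fixtures shared across test files.

# One patient's consolidated daily records.
make_patient_records <- function(id = "P1", days = 1:8, inr = NULL,
                                 dose = NULL, sex = 1, age = 60,
                                 weight = 70, height = 170,
                                 doses_per_day = 1) {
  n <- length(days)
  data.frame(
    patient_id = id, day = days, sex = sex, age = age,
    weight_kg = weight, height_cm = height,
    inr = if (is.null(inr)) rep(2, n) else inr,
    dose_mg = if (is.null(dose)) rep(3, n) else dose,
    doses_per_day = doses_per_day, administered = 1,
    stringsAsFactors = FALSE
  )
}

# Random but plausible training windows (already in single-line format).
make_random_windows <- function(n, seed = 1) {
  set.seed(seed)
  height <- round(runif(n, 140, 190), 1)
  weight <- round(runif(n, 40, 110), 1)
  data.frame(
    patient_id = sprintf("W%04d", seq_len(n)),
    start_day = 1,
    sex = rbinom(n, 1, 0.5),
    age = round(runif(n, 18, 90)),
    weight_kg = weight, height_cm = height,
    bsa = compute_bsa(height, weight),
    inr1 = runif(n, 1, 4), inr2 = runif(n, 1, 4),
    inr3 = runif(n, 1, 4), inr4 = runif(n, 1, 4),
    dose1 = sample(seq(1, 10, 0.5), n, replace = TRUE),
    dose2 = sample(seq(1, 10, 0.5), n, replace = TRUE),
    dose3 = sample(seq(1, 10, 0.5), n, replace = TRUE),
    dose4 = sample(seq(1, 10, 0.5), n, replace = TRUE),
    target_inr = runif(n, 1, 4),
    stringsAsFactors = FALSE
  )
}

# A predictor with untrained (seeded) weights but a fitted standardizer:
# enough structure to exercise prediction plumbing without training.
make_dummy_predictor <- function(seed = 1, config = NULL) {
  windows <- make_random_windows(50, seed = seed)
  if (is.null(config)) config <- network_config(seed = seed)
  net <- build_network(config)
  structure(list(par = net$par, config = config,
                 standardizer = fit_standardizer(windows),
                 history = data.frame(), best_epoch = 0L,
                 best_val_loss = NA_real_, seed = seed),
            class = "inr_predictor")
}

# Small fast architecture for tests that must train.
tiny_config <- function(...) {
  network_config(static_branch = 8, recurrent_layers = 1,
                 recurrent_units = 8, head_layers = 1, head_units = 8,
                 batch_size = 32, ...)
}

# Hand-unrolled R forward pass: the independent oracle for the C++ network.
# Applies the recurrent cell step by step with plain matrix algebra.
r_reference_forward <- function(par, config, static, series8) {
  shapes <- inrcast:::param_shapes(config)
  off <- 0; P <- list()
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    P[[nm]] <- matrix(par[(off + 1):(off + prod(d))], d[1], d[2])
    off <- off + prod(d)
  }
  stopifnot(off == length(par))
  sigm <- function(x) 1 / (1 + exp(-x))
  relu <- function(x) pmax(x, 0)
  U <- config$recurrent_units
  a <- matrix(static, 1)
  for (j in seq_along(config$static_branch)) {
    a <- relu(a %*% P[[paste0("static_W", j)]] + P[[paste0("static_b", j)]])
  }
  xseq <- lapply(1:4, function(t) matrix(c(series8[t], series8[4 + t]), 1))
  for (l in seq_len(config$recurrent_layers)) {
    h <- matrix(0, 1, U); cc <- matrix(0, 1, U); hs <- vector("list", 4)
    for (t in 1:4) {
      z <- xseq[[t]] %*% P[[paste0("lstm_Wx", l)]] +
        h %*% P[[paste0("lstm_Wh", l)]] + P[[paste0("lstm_b", l)]]
      i <- sigm(z[, 1:U, drop = FALSE])
      f <- sigm(z[, (U + 1):(2 * U), drop = FALSE])
      g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
      o <- sigm(z[, (3 * U + 1):(4 * U), drop = FALSE])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      hs[[t]] <- h
    }
    xseq <- hs
  }
  b <- cbind(a, xseq[[4]])
  for (j in seq_len(config$head_layers)) {
    b <- relu(b %*% P[[paste0("head_W", j)]] + P[[paste0("head_b", j)]])
  }
  as.numeric(b %*% P$out_W + P$out_b)
}

# Brute-force window enumeration: test every possible 5-day subsequence.
brute_force_windows <- function(records, k = 5) {
  out <- list()
  for (pid in unique(records$patient_id)) {
    r <- records[records$patient_id == pid, ]
    r <- r[order(r$day), ]
    for (s in seq_len(nrow(r))) {
      want <- r$day[s] + 0:(k - 1)
      rows <- r[match(want, r$day), ]
      if (any(is.na(rows$day))) next
      if (any(is.na(rows$inr)) || any(is.na(rows$dose_mg)) ||
          any(rows$dose_mg <= 0)) next
      out[[length(out) + 1]] <- c(pid, r$day[s])
    }
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(), start_day = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(patient_id = m[, 1], start_day = as.numeric(m[, 2]),
             stringsAsFactors = FALSE)
}
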