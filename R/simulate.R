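#' Population defaults for the warfarin PK/PD cohort simulator
#'
#' One-compartment oral pharmacokinetics drives an Emax inhibition of
#' clotting-factor synthesis; factor activity turns over with first-order
#' rate `kout`, which is what delays the INR response to a dose change by
#' days. INR is mapped from factor activity F through the monotone link
#' `INR = base_inr / F^gamma`, so steady-state INR increases strictly with
#' steady-state concentration. All rates are per day, volumes in litres,
#' concentrations in mg/L.
#'
#' @param ka Absorption rate constant (1/day).
#' @param cl Typical clearance (L/day) for a 70 kg, 50-year-old.
#' @param v Typical volume of distribution (L) for 70 kg.
#' @param ec50 Half-maximal inhibitory concentration (mg/L).
#' @param emax Maximal synthesis inhibition, in (0, 1].
#' @param kout Clotting-factor turnover rate (1/day); smaller = longer delay.
#' @param base_inr Baseline INR off warfarin (about 1.0).
#' @param gamma Link steepness exponent.
#' @param cl_weight_exp Allometric weight exponent on clearance.
#' @param cl_age_slope Fractional clearance loss per year beyond age 50.
#' @param omega_cl,omega_v,omega_ec50,omega_kout Log-normal inter-individual
#'   sd on the corresponding parameter.
#' @param sigma_base Log-normal sd on baseline INR.
#' @param noise_sd Additive INR measurement noise sd (INR units).
#' @param target_low,target_high Therapeutic INR range steering titration.
#' @param dose_step Titration increment (mg).
#' @param dose_min,dose_max Dose clamp (mg/day).
#' @param hold_from_day First day from which the dose is held fixed (the
#'   titrate-then-hold pattern that yields fixed-dose evaluation stays).
#' @param safety_inr Observed INR above which a held dose is still reduced.
#' @param init_dose_range Range of starting doses (mg, on the 0.5 grid).
#' @param dt Integration substep (days; forward Euler).
#' @return A list of class `pkpd_population`.
#' @export
pkpd_population <- function(ka = 1.0, cl = 4.8, v = 10, ec50 = 1.0,
                            emax = 0.95, kout = 0.3, base_inr = 1.0,
                            gamma = 1.5, cl_weight_exp = 0.75,
                            cl_age_slope = 0.005,
                            omega_cl = 0.3, omega_v = 0.1, omega_ec50 = 0.3,
                            omega_kout = 0.2, sigma_base = 0.03,
                            noise_sd = 0.1,
                            target_low = 2, target_high = 3,
                            dose_step = 0.5, dose_min = 0.5, dose_max = 20,
                            hold_from_day = 4, safety_inr = 4.5,
                            init_dose_range = c(2, 6), dt = 0.05) {
  pop <- list(ka = ka, cl = cl, v = v, ec50 = ec50, emax = emax, kout = kout,
              base_inr = base_inr, gamma = gamma,
              cl_weight_exp = cl_weight_exp, cl_age_slope = cl_age_slope,
              omega_cl = omega_cl, omega_v = omega_v, omega_ec50 = omega_ec50,
              omega_kout = omega_kout, sigma_base = sigma_base,
              noise_sd = noise_sd, target_low = target_low,
              target_high = target_high, dose_step = dose_step,
              dose_min = dose_min, dose_max = dose_max,
              hold_from_day = hold_from_day, safety_inr = safety_inr,
              init_dose_range = init_dose_range, dt = dt)
  rates <- c(ka = ka, cl = cl, v = v, ec50 = ec50, kout = kout,
             base_inr = base_inr, gamma = gamma)
  if (any(rates <= 0)) stop("all rates/volumes/concentrations must be > 0",
                            call. = FALSE)
  if (emax <= 0 || emax > 1) stop("emax must be in (0, 1]", call. = FALSE)
  class(pop) <- "pkpd_population"
  pop
}

check_pkpd_params <- function(params) {
  need <- c("ka", "cl", "v", "ec50", "emax", "kout", "base_inr", "gamma")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("PK/PD params missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in need) {
    if (any(!is.finite(params[[f]])) || any(params[[f]] <= 0)) {
      stop("PK/PD parameter '", f, "' must be finite and > 0", call. = FALSE)
    }
  }
  if (any(params$emax > 1)) stop("emax must be <= 1", call. = FALSE)
  invisible(params)
}

inr_link <- function(F_act, base_inr, gamma) base_inr / F_act^gamma

# Advance (A_gut, A_c, F) one day by forward Euler at substep dt.
advance_one_day <- function(agut, ac, f_act, params, dt) {
  nsub <- round(1 / dt)
  kel <- params$cl / params$v
  for (s in seq_len(nsub)) {
    conc <- ac / params$v
    inh <- params$emax * conc / (params$ec50 + conc)
    d_agut <- -params$ka * agut
    d_ac <- params$ka * agut - kel * ac
    d_f <- params$kout * ((1 - inh) - f_act)
    agut <- agut + dt * d_agut
    ac <- ac + dt * d_ac
    f_act <- f_act + dt * d_f
  }
  list(agut = agut, ac = ac, f = f_act)
}

# Vectorized multi-patient engine. params: data.frame, one row per patient.
# dosing: n x n_days matrix, or NULL to titrate toward the target range.
# noise: n x n_days matrix of additive INR measurement errors.
# INR is measured at the start of each day, before that day's dose.
simulate_trajectories <- function(params, n_days, noise, dosing = NULL,
                                  init_dose = NULL, pop = pkpd_population()) {
  check_pkpd_params(params)
  n <- nrow(params)
  titrate <- is.null(dosing)
  if (titrate && is.null(init_dose)) {
    stop("titration needs init_dose", call. = FALSE)
  }
  if (!titrate) dosing <- matrix(dosing, n, n_days)
  doses <- matrix(NA_real_, n, n_days)
  noiseless <- matrix(NA_real_, n, n_days)
  observed <- matrix(NA_real_, n, n_days)
  states <- array(NA_real_, dim = c(n, n_days, 3),
                  dimnames = list(NULL, NULL, c("agut", "ac", "f")))
  agut <- numeric(n); ac <- numeric(n); f_act <- rep(1, n)
  for (d in seq_len(n_days)) {
    states[, d, "agut"] <- agut
    states[, d, "ac"] <- ac
    states[, d, "f"] <- f_act
    noiseless[, d] <- inr_link(f_act, params$base_inr, params$gamma)
    observed[, d] <- noiseless[, d] + noise[, d]
    if (titrate) {
      if (d == 1) {
        doses[, d] <- init_dose
      } else if (d < pop$hold_from_day) {
        doses[, d] <- titration_policy(observed[, d], doses[, d - 1],
                                       target = c(pop$target_low,
                                                  pop$target_high),
                                       step = pop$dose_step,
                                       dose_min = pop$dose_min,
                                       dose_max = pop$dose_max)
      } else {
        held <- doses[, d - 1]
        unsafe <- observed[, d] > pop$safety_inr
        held[unsafe] <- pmax(pop$dose_min,
                             held[unsafe] - 2 * pop$dose_step)
        doses[, d] <- held
      }
    } else {
      doses[, d] <- dosing[, d]
    }
    agut <- agut + doses[, d]
    st <- advance_one_day(agut, ac, f_act, params, pop$dt)
    agut <- st$agut; ac <- st$ac; f_act <- st$f
  }
  list(doses = doses, noiseless = noiseless, observed = observed,
       states = states)
}

#' Proportional dose-titration policy
#'
#' When the observed INR is outside the target range the dose moves toward
#' the range midpoint in 0.5 mg steps (at least one step, at most
#' `max_change`), clamped to `[dose_min, dose_max]`; inside the range the
#' dose is unchanged.
#'
#' @param inr Observed INR(s).
#' @param current_dose Current daily dose(s) in mg.
#' @param target Two-element therapeutic range (default `c(2, 3)`).
#' @param step Dose grid increment in mg (default 0.5).
#' @param kp Proportional gain (mg per INR unit of deviation).
#' @param max_change Largest single-day adjustment in mg.
#' @param dose_min,dose_max Dose clamp in mg.
#' @return Next-day dose(s) in mg.
#' @export
titration_policy <- function(inr, current_dose, target = c(2, 3), step = 0.5,
                             kp = 0.75, max_change = 1, dose_min = 0.5,
                             dose_max = 20) {
  if (length(target) != 2 || target[1] >= target[2]) {
    stop("target must be a non-empty range c(low, high)", call. = FALSE)
  }
  mid <- mean(target)
  dev <- mid - inr
  outside <- inr < target[1] | inr > target[2]
  delta <- round(kp * dev / step) * step
  delta <- pmin(max_change, pmax(-max_change, delta))
  need_min <- outside & delta == 0
  delta[need_min] <- step * sign(dev[need_min])
  delta[!outside] <- 0
  pmin(dose_max, pmax(dose_min, current_dose + delta))
}

#' Simulate one virtual warfarin patient
#'
#' Integrates the PK/PD equations for a given dosing sequence and adds seeded
#' measurement noise. INR is measured each morning before that day's dose.
#'
#' @param params Named list/one-row data frame with `ka`, `cl`, `v`, `ec50`,
#'   `emax`, `kout`, `base_inr`, `gamma` (see [pkpd_population()] for units).
#' @param dosing Numeric vector of daily doses in mg (length = number of
#'   days; 0 allowed = missed dose).
#' @param seed Integer seed for the measurement noise.
#' @param noise_sd Additive INR noise sd (default 0.1).
#' @param dt Integration substep in days.
#' @return A list with `params`, `dosing`, `noiseless_inr`, `observed_inr`,
#'   `states` (per-day pre-dose PK/PD state) and `seed`.
#' @export
simulate_patient <- function(params, dosing, seed = 1, noise_sd = 0.1,
                             dt = 0.05) {
  params <- as.data.frame(params)
  check_pkpd_params(params)
  if (any(dosing < 0)) stop("doses must be >= 0", call. = FALSE)
  n_days <- length(dosing)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_days, sd = noise_sd), 1, n_days)
  pop <- pkpd_population(dt = dt)
  tr <- simulate_trajectories(params, n_days, noise,
                              dosing = matrix(dosing, 1), pop = pop)
  list(params = params, dosing = as.numeric(tr$doses),
       noiseless_inr = as.numeric(tr$noiseless),
       observed_inr = as.numeric(tr$observed),
       states = tr$states[1, , , drop = TRUE], seed = seed)
}

# Independent per-patient substream: patient i is reproducible regardless of
# cohort size. Kept below 2^31.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

#' Generate a virtual inpatient warfarin cohort
#'
#' Draws static covariates inside the cohort filter ranges (age 18-90, weight
#' 40-110 kg, height 140-190 cm, sex Bernoulli 0.5), log-normal individual
#' PK/PD parameters around the population values, titration-style dosing
#' (adjusted daily until `hold_from_day`, then held fixed), and noisy daily
#' INR observations. The emitted records conform to the daily-record schema
#' so the whole preprocessing pipeline applies unchanged; the returned truth
#' object holds the latent parameters, noiseless trajectories and PK/PD
#' states for oracle evaluation.
#'
#' @param n_patients Number of patients (>= 1).
#' @param n_days Days of inpatient stay per patient (default 10).
#' @param pop A [pkpd_population()] configuration.
#' @param seed Cohort seed; each patient gets an independent substream.
#' @return List with `records` (data frame, one row per patient-day; sex
#'   coded 0 = F, 1 = M) and `truth` (list: `params`, `dosing`, `noiseless`,
#'   `observed`, `states`, `seed`).
#' @export
generate_cohort <- function(n_patients, n_days = 10, pop = pkpd_population(),
                            seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  draws <- lapply(seq_len(n_patients), function(i) {
    set.seed(patient_seed(seed, i))
    sex <- stats::rbinom(1, 1, 0.5)
    age <- round(stats::runif(1, 18, 90))
    weight <- round(stats::runif(1, 40, 110), 1)
    height <- round(stats::runif(1, 140, 190), 1)
    z <- stats::rnorm(5)
    grid <- seq(pop$init_dose_range[1], pop$init_dose_range[2],
                by = pop$dose_step)
    init_dose <- grid[sample.int(length(grid), 1)]
    noise <- stats::rnorm(n_days, sd = pop$noise_sd)
    list(sex = sex, age = age, weight = weight, height = height, z = z,
         init_dose = init_dose, noise = noise)
  })
  g <- function(f) vapply(draws, function(d) d[[f]], numeric(1))
  sex <- g("sex"); age <- g("age"); weight <- g("weight"); height <- g("height")
  z <- t(vapply(draws, function(d) d$z, numeric(5)))
  init_dose <- g("init_dose")
  noise <- t(vapply(draws, function(d) d$noise, numeric(n_days)))

  age_factor <- pmax(0.3, 1 - pop$cl_age_slope * (age - 50))
  params <- data.frame(
    ka = rep(pop$ka, n_patients),
    cl = pop$cl * (weight / 70)^pop$cl_weight_exp * age_factor *
      exp(pop$omega_cl * z[, 1]),
    v = pop$v * (weight / 70) * exp(pop$omega_v * z[, 2]),
    ec50 = pop$ec50 * exp(pop$omega_ec50 * z[, 3]),
    emax = rep(pop$emax, n_patients),
    kout = pop$kout * exp(pop$omega_kout * z[, 4]),
    base_inr = pop$base_inr * exp(pop$sigma_base * z[, 5]),
    gamma = rep(pop$gamma, n_patients)
  )
  tr <- simulate_trajectories(params, n_days, noise, dosing = NULL,
                              init_dose = init_dose, pop = pop)
  ids <- sprintf("P%05d", seq_len(n_patients))
  records <- data.frame(
    patient_id = rep(ids, each = n_days),
    day = rep(seq_len(n_days), n_patients),
    sex = rep(sex, each = n_days),
    age = rep(age, each = n_days),
    weight_kg = rep(weight, each = n_days),
    height_cm = rep(height, each = n_days),
    inr = as.numeric(t(tr$observed)),
    dose_mg = as.numeric(t(tr$doses)),
    doses_per_day = 1,
    administered = 1,
    stringsAsFactors = FALSE
  )
  truth <- list(
    params = cbind(data.frame(patient_id = ids, sex = sex, age = age,
                              weight_kg = weight, height_cm = height,
                              init_dose = init_dose,
                              stringsAsFactors = FALSE), params),
    dosing = tr$doses, noiseless = tr$noiseless, observed = tr$observed,
    states = tr$states, seed = seed, pop = pop
  )
  list(records = records, truth = truth)
}

#' Ground-truth INR trajectory under virtual fixed dosing
#'
#' Integrates the same PK/PD equations forward from a patient's true day-4
#' pre-dose state with a fixed dose administered on days 4 to
#' `3 + horizon`, returning the noiseless INRs for days 5 to `4 + horizon`.
#' This is the ground-truth counterpart of the chain calculation.
#'
#' @param truth Cohort truth object from [generate_cohort()].
#' @param patient Patient index (row in `truth$params`).
#' @param fixed_dose Daily dose in mg administered from day 4 on.
#' @param horizon Number of predicted days (default 4: days 5-8).
#' @param from_day First virtual dosing day (default 4).
#' @return Numeric vector of noiseless INRs for days
#'   `(from_day + 1) .. (from_day + horizon)`.
#' @export
oracle_trajectory <- function(truth, patient, fixed_dose, horizon = 4,
                              from_day = 4) {
  if (fixed_dose <= 0) stop("fixed_dose must be > 0", call. = FALSE)
  params <- truth$params[patient, c("ka", "cl", "v", "ec50", "emax", "kout",
                                    "base_inr", "gamma")]
  st <- truth$states[patient, from_day, ]
  agut <- st["agut"]; ac <- st["ac"]; f_act <- st["f"]
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    agut <- agut + fixed_dose
    s <- advance_one_day(agut, ac, f_act, params, truth$pop$dt)
    agut <- s$agut; ac <- s$ac; f_act <- s$f
    out[h] <- inr_link(f_act, params$base_inr, params$gamma)
  }
  names(out) <- paste0("day", (from_day + 1):(from_day + horizon))
  out
}

#' @describeIn oracle_trajectory True day-8 INR under fixed dosing from day 4.
#' @export
oracle_day8 <- function(truth, patient, fixed_dose) {
  unname(oracle_trajectory(truth, patient, fixed_dose, horizon = 4,
                           from_day = 4)["day8"])
}
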