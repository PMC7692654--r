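# Synthetic-data generators with known ground truth. Every generator is
# the forward model of exactly one fitting operation in the package, so
# each fitter can be round-trip tested against the generating parameters.

#' Configuration for the decay-series generator
#'
#' Defaults reproduce the study design the package targets: holding
#' temperatures 80-180 degrees C in 10-degree steps, sampling times
#' 0/2/5/7/10/20/30/40 min, triplicate measurements, an activation
#' energy of 55.75 kJ/mol anchored so that k(120 C) = 0.0228 min^-1,
#' and no measurable degradation below 120 degrees C.
#'
#' @param ea_true True activation energy, kJ/mol (> 0).
#' @param ln_a_true Log pre-exponential factor, ln(min^-1). The default
#'   is chosen so the Arrhenius law passes through
#'   k = 0.0228 min^-1 at 120 degrees C.
#' @param temperatures Holding temperatures, degrees C.
#' @param time_grid Sampling times, minutes (first element 0).
#' @param noise_cv Coefficient of variation of measurement noise (< 0.5).
#' @param noise_model `"multiplicative-lognormal"` (default;
#'   spectrophotometric error scales with signal) or
#'   `"additive-gaussian"`.
#' @param replicates Replicate series per temperature (>= 1).
#' @param seed Integer seed; mandatory for any stochastic output.
#' @param stable_below Temperatures strictly below this threshold get a
#'   true rate constant of 0 (thermostable); `NULL` disables.
#' @param c0 True initial concentration (arbitrary units).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(ea_true = 55.75,
                             ln_a_true = log(0.0228) +
                               55.75e3 / (GAS_CONSTANT * (120 + 273.15)),
                             temperatures = seq(80, 180, by = 10),
                             time_grid = c(0, 2, 5, 7, 10, 20, 30, 40),
                             noise_cv = 0.05,
                             noise_model = c("multiplicative-lognormal",
                                             "additive-gaussian"),
                             replicates = 3,
                             seed = NULL,
                             stable_below = 120,
                             c0 = 1) {
  noise_model <- match.arg(noise_model)
  if (ea_true <= 0) stop("parameter error: ea_true must be > 0",
                         call. = FALSE)
  if (noise_cv < 0 || noise_cv >= 0.5) {
    stop("parameter error: noise_cv must be in [0, 0.5)", call. = FALSE)
  }
  if (replicates < 1) stop("parameter error: replicates must be >= 1",
                           call. = FALSE)
  if (noise_cv > 0 && is.null(seed)) {
    stop("parameter error: seed is mandatory for stochastic output",
         call. = FALSE)
  }
  structure(list(ea_true = ea_true, ln_a_true = ln_a_true,
                 temperatures = temperatures, time_grid = time_grid,
                 noise_cv = noise_cv, noise_model = noise_model,
                 replicates = as.integer(replicates), seed = seed,
                 stable_below = stable_below, c0 = c0),
            class = "generator_config")
}

#' True Arrhenius rate constant at a temperature
#'
#' Forward model `k = exp(ln_A - Ea * 1000 / (R * T_K))`, zeroed below
#' the configured thermostability threshold.
#'
#' @param config A [generator_config()].
#' @param temperature Temperature in degrees C (above absolute zero).
#' @return Rate constant(s), min^-1.
#' @export
arrhenius_k <- function(config, temperature) {
  stopifnot(inherits(config, "generator_config"))
  if (any(temperature <= -273.15)) {
    stop("parameter error: temperature below absolute zero", call. = FALSE)
  }
  k <- exp(config$ln_a_true -
             config$ea_true * 1000 / (GAS_CONSTANT * (temperature + 273.15)))
  if (!is.null(config$stable_below)) {
    k[temperature < config$stable_below] <- 0
  }
  k
}

# Multiplicative lognormal factors with unit mean and the requested CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Additive gaussian noise; nonpositive results are resampled (bounded
# retries) and the retry count is recorded on the result.
perturb <- function(true_values, cv, model) {
  retries <- 0L
  if (cv == 0) {
    vals <- true_values
  } else if (model == "multiplicative-lognormal") {
    vals <- true_values * lognormal_noise(length(true_values), cv)
  } else {
    sd_abs <- cv * true_values
    vals <- stats::rnorm(length(true_values), true_values, sd_abs)
    for (i in seq_len(10L)) {
      bad <- vals <= 0
      if (!any(bad)) break
      retries <- retries + sum(bad)
      vals[bad] <- stats::rnorm(sum(bad), true_values[bad], sd_abs[bad])
    }
    vals[vals <= 0] <- .Machine$double.eps
  }
  attr(vals, "resampled") <- retries
  vals
}

#' Simulate first-order decay series with known truth
#'
#' Generates `C(t) = C0 * exp(-k(T) * t)` on the configured time grid
#' for every temperature and replicate, perturbed by the configured
#' noise model. Output is deterministic given the seed. The true rate
#' constants are returned alongside the data, never embedded in them.
#'
#' @param config A [generator_config()].
#' @return List with `series` (list of [decay_series()]) and `truth`
#'   (data frame `temperature_c`, `k_true`; plus the config as an
#'   attribute).
#' @export
simulate_decay <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  series <- list()
  for (tt in config$temperatures) {
    k <- arrhenius_k(config, tt)
    true_vals <- config$c0 * exp(-k * config$time_grid)
    for (r in seq_len(config$replicates)) {
      vals <- perturb(true_vals, config$noise_cv, config$noise_model)
      series[[length(series) + 1L]] <- decay_series(
        tt, config$time_grid, as.numeric(vals),
        replicate_id = sprintf("T%g_rep%d", tt, r))
    }
  }
  truth <- data.frame(temperature_c = config$temperatures,
                      k_true = arrhenius_k(config, config$temperatures))
  structure(list(series = series, truth = truth), config = config)
}

#' Simulate a sequential gastric -> intestinal digestion experiment
#'
#' TAC follows phase-wise first-order decay on a 30-min grid over 2 h
#' per phase, with the standard 5 mL + 10 mL dilution applied at the
#' phase switch. The DPPH percent loss is coupled to the TAC percent
#' loss through a linear coefficient plus optional gaussian noise.
#'
#' @param k_gastric,k_intestinal Phase rate constants, min^-1 (>= 0).
#' @param loss_coupling Slope linking DPPH percent loss to TAC percent
#'   loss (default 0.9; antioxidant activity falls slightly slower than
#'   the pigment that drives it).
#' @param noise_cv Coefficient of variation of measurement noise.
#' @param seed Integer seed (mandatory when `noise_cv > 0`).
#' @param pretreatment Label carried on the output courses.
#' @param tac0 Initial TAC entering the gastric phase (default 10 mg
#'   C3G equivalents, the standard digestion loading).
#' @param dpph0 Initial antioxidant activity (default 85.72 Trolox
#'   equivalents, a typical untreated purple maize extract).
#' @param times Sampling grid per phase, minutes.
#' @return List with `gastric` and `intestinal` [digestion_course()]s
#'   and `truth` (the generating parameters).
#' @export
simulate_digestion <- function(k_gastric, k_intestinal,
                               loss_coupling = 0.9, noise_cv = 0,
                               seed = NULL, pretreatment = "untreated",
                               tac0 = 10, dpph0 = 85.72,
                               times = seq(0, 120, by = 30)) {
  if (k_gastric < 0 || k_intestinal < 0) {
    stop("parameter error: rates must be >= 0", call. = FALSE)
  }
  if (noise_cv > 0 && is.null(seed)) {
    stop("parameter error: seed is mandatory for stochastic output",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  make_phase <- function(phase, start_tac, start_dpph, k) {
    tac_true <- start_tac * exp(-k * times)
    tac <- as.numeric(perturb(tac_true, noise_cv,
                              "multiplicative-lognormal"))
    tac[1] <- start_tac  # phase-initial reading defines the baseline
    tac_loss <- 100 * (1 - tac / tac[1])
    dpph_loss <- loss_coupling * tac_loss +
      if (noise_cv > 0) stats::rnorm(length(times), 0, 100 * noise_cv)
      else 0
    dpph_loss[1] <- 0
    dpph <- pmax(start_dpph * (1 - dpph_loss / 100), 0)
    digestion_course(pretreatment, phase, times, tac, dpph,
                     dilution_applied = (phase == "intestinal"))
  }

  gastric <- make_phase("gastric", tac0, dpph0, k_gastric)
  n <- length(times)
  intestinal <- make_phase(
    "intestinal",
    apply_intestinal_dilution(gastric$tac_values[n]),
    apply_intestinal_dilution(gastric$dpph_values[n]),
    k_intestinal)

  list(gastric = gastric, intestinal = intestinal,
       truth = list(k_gastric = k_gastric, k_intestinal = k_intestinal,
                    loss_coupling = loss_coupling, noise_cv = noise_cv,
                    tac0 = tac0, dpph0 = dpph0, seed = seed))
}

#' Simulate pH-differential absorbance readings for a target TAC
#'
#' Inverts the pH-differential equation: back-solves the net absorbance
#' that yields `target_tac` under `params`, splits it into a plausible
#' quadruple (all signal at 520 nm / pH 1.0, small matched haze terms),
#' and adds replicate noise. If the required absorbance exceeds
#' `max_abs`, the generator raises the dilution factor to the smallest
#' integer that brings it back into range, mirroring what an analyst
#' would do at the bench.
#'
#' @param target_tac Target TAC, mg C3G equivalents per g dry weight.
#' @param params A [ph_differential_params()].
#' @param noise_cv Coefficient of variation of replicate noise.
#' @param seed Integer seed (mandatory when `noise_cv > 0`).
#' @param replicates Number of replicate quadruples.
#' @param max_abs Largest net absorbance considered reliable
#'   (default 1.0, the photometric linear range).
#' @return List with `quadruples` (list of [absorbance_quadruple()]),
#'   `params` (possibly with an increased dilution factor), and
#'   `abs_target` (the noiseless net absorbance).
#' @export
simulate_assay_inputs <- function(target_tac, params = ph_differential_params(),
                                  noise_cv = 0, seed = NULL,
                                  replicates = 3, max_abs = 1.0) {
  stopifnot(inherits(params, "ph_differential_params"))
  if (target_tac < 0) {
    stop("parameter error: target_tac must be >= 0", call. = FALSE)
  }
  if (noise_cv > 0 && is.null(seed)) {
    stop("parameter error: seed is mandatory for stochastic output",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  abs_for <- function(p) {
    target_tac * p$epsilon * p$path_length * p$dry_mass /
      (p$mol_weight * p$dilution_factor * p$final_volume * MG_PER_G_SCALE)
  }
  abs_target <- abs_for(params)
  if (abs_target > max_abs) {
    needed <- ceiling(params$dilution_factor * abs_target / max_abs)
    params <- ph_differential_params(
      epsilon = params$epsilon, path_length = params$path_length,
      mol_weight = params$mol_weight, dilution_factor = needed,
      final_volume = params$final_volume, dry_mass = params$dry_mass)
    abs_target <- abs_for(params)
    if (abs_target > max_abs + 1e-9) {
      stop("infeasible target: no dilution factor keeps absorbance in range",
           call. = FALSE)
    }
  }
  haze <- 0.02  # identical 700 nm haze in both buffers; cancels in the net
  quadruples <- lapply(seq_len(replicates), function(i) {
    a <- abs_target * as.numeric(lognormal_noise(1, noise_cv))
    absorbance_quadruple(a520_ph1 = a + haze, a700_ph1 = haze,
                         a520_ph45 = haze, a700_ph45 = haze)
  })
  list(quadruples = quadruples, params = params, abs_target = abs_target)
}

#' Simulate Trolox calibration standards
#'
#' Forward model of [fit_trolox_calibration()]: standards on
#' `response = slope * concentration + intercept` with optional
#' gaussian response noise.
#'
#' @param slope,intercept True line parameters.
#' @param concentrations Standard concentrations, mmol/L (default the
#'   conventional 0-10 mmol/L series).
#' @param noise_sd Gaussian response noise standard deviation.
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @return Data frame `concentration_mmol`, `response`.
#' @export
simulate_trolox_standards <- function(slope, intercept,
                                      concentrations = seq(0, 10, by = 2),
                                      noise_sd = 0, seed = NULL) {
  if (noise_sd > 0 && is.null(seed)) {
    stop("parameter error: seed is mandatory for stochastic output",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  resp <- slope * concentrations + intercept +
    if (noise_sd > 0) stats::rnorm(length(concentrations), 0, noise_sd) else 0
  data.frame(concentration_mmol = concentrations, response = resp)
}
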