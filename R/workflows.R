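# End-to-end workflow helpers: the standard toy study setup (model +
# modules + media + regulations + simulator closure), the five-parameter
# vector of the study's calibration, building a calibration problem from a
# culture time series, and the train/validate fit report.

#' Standard toy study setup
#'
#' Builds the toy model with both proteolytic modules (baseline-medium
#' protein and whey protein) attached, the three media, the default
#' regulations and carrying-capacity template, and the five-parameter
#' simulator closure used for calibration.
#'
#' @param config a [toy_config()].
#' @param chi ATP cost per proteolysis event for both modules.
#' @param T_GLM,Hillcoef,K_cc carrying-capacity template values.
#' @param dt,horizon,B0,uptake_bound simulation settings.
#' @param media optional named list of `medium` objects (default
#'   [make_media()]).
#' @return list with `model`, `media`, `regulations`, `cc`, `observables`,
#'   `modules` and `simulator`.
#' @export
standard_toy_setup <- function(config = toy_config(), chi = DEFAULT_CHI,
                               T_GLM = 0.9, Hillcoef = 2, K_cc = 1,
                               dt = 0.25, horizon = 24,
                               B0 = od_to_biomass(0.02), uptake_bound = 10,
                               media = NULL) {
  model <- make_toy_model(config)
  # restrict module stoichiometry to the amino acids the config carries so
  # reduced toy networks stay attachable
  restrict <- function(comp) {
    cts <- comp$counts
    cts[!names(cts) %in% config$amino_acids] <- 0
    protein_composition(comp$name, cts)
  }
  modules <- list(glm = build_proteolytic_module(
                    restrict(glm_protein_composition()), chi = chi),
                  whey = build_proteolytic_module(
                    restrict(whey_composition()), chi = chi))
  for (m in modules) model <- attach_module(model, m)
  media <- media %||% make_media()
  regulations <- default_regulations()
  cc <- carrying_capacity_params(T_GLM = T_GLM, Hillcoef = Hillcoef,
                                 K = K_cc, lambda = 1, WP_initial = 0)
  list(model = model, media = media, regulations = regulations, cc = cc,
       modules = modules,
       observables = c("biomass", "ac_e", "ppa_e", "glc_e", "lcts_e"),
       simulator = standard_simulator(model, media, regulations, cc,
                                      dt = dt, horizon = horizon, B0 = B0,
                                      uptake_bound = uptake_bound))
}

#' The study's five calibrated parameters
#'
#' Glycine exchange upper bound, asparagine exchange lower bound, the bound
#' magnitude shared by the remaining amino acids, and the logistic lambda
#' in the baseline and high-whey media.
#'
#' @param start optional start vector (length 5).
#' @return parameter data.frame for [calibration_problem()].
#' @export
standard_parameters <- function(start = c(2, -1, 3, 1, 1)) {
  data.frame(name = c("gly_ub", "asn_lb", "aa_bound",
                      "lambda_GLM", "lambda_P20"),
             lower = c(0.05, -8, 0.2, 0.2, 0.2),
             upper = c(10, -0.01, 10, 3, 3),
             start = start)
}

#' Build a calibration problem from a culture time series
#'
#' Aggregates replicates into per-(medium, time, observable) means and SDs.
#'
#' @param series a [culture_series()].
#' @param media training medium names.
#' @param observables observed variables entering the objective.
#' @param parameters parameter data.frame (default [standard_parameters()]).
#' @param sd_floor lower floor on replicate SDs (keeps weights finite for
#'   noise-free series).
#' @param max_evals evaluation budget.
#' @return a [calibration_problem()].
#' @export
calibration_problem_from_series <- function(series, media, observables,
                                            parameters = standard_parameters(),
                                            sd_floor = 0.01,
                                            max_evals = 100000) {
  if (!inherits(series, "culture_series")) series <- culture_series(series)
  miss <- setdiff(observables,
                  unique(series$variable))
  if (length(miss))
    stop("series lacks observable(s): ", paste(miss, collapse = ", "))
  data <- list()
  for (med in media) {
    sub <- series[series$medium == med & series$variable %in% observables, ]
    if (!nrow(sub)) stop("no data for training medium ", med)
    times <- sort(unique(sub$time))
    mn <- sd_ <- matrix(NA_real_, length(times), length(observables),
                        dimnames = list(NULL, observables))
    for (v in observables) {
      for (i in seq_along(times)) {
        vals <- sub$value[sub$variable == v & sub$time == times[i]]
        mn[i, v] <- mean(vals)
        sd_[i, v] <- if (length(vals) > 1) sd(vals) else 0
      }
    }
    sd_ <- pmax(sd_, sd_floor)
    data[[med]] <- list(times = times, mean = mn, sd = sd_)
  }
  calibration_problem(parameters, observables, data, max_evals = max_evals)
}

#' Train/validate report for a calibrated model
#'
#' Pools every (observable, time point) pair of the held-out medium and
#' reports the coefficient of determination plus the fraction of
#' predictions within a 10 percent relative error band, alongside the same
#' quantities on the training media.
#'
#' @param fit a `dfba_fit`.
#' @param series the full [culture_series()] (training + validation media).
#' @param validate_medium held-out medium name.
#' @param simulator the fit's simulator (defaults to `fit$simulator`).
#' @return list with theta, objective diagnostics, `training_r2`,
#'   `validation_r2` and the 10 percent-band fractions.
#' @export
calibration_report <- function(fit, series, validate_medium,
                               simulator = NULL) {
  simulator <- simulator %||% fit$simulator
  obs_vars <- fit$problem$observables
  pool <- function(media) {
    obs <- pred <- c()
    for (med in media) {
      sub <- series[series$medium == med & series$variable %in% obs_vars, ]
      times <- sort(unique(sub$time))
      traj <- simulator(fit$theta, med)
      pm <- if (inherits(traj, "dfba_trajectory"))
        trajectory_at(traj, times, obs_vars) else traj
      for (v in obs_vars) {
        m <- vapply(times, function(t0)
          mean(sub$value[sub$variable == v & sub$time == t0]), 0)
        obs <- c(obs, m)
        pred <- c(pred, pm[, v])
      }
    }
    goodness_of_fit(pred, obs)
  }
  gtrain <- pool(names(fit$problem$data))
  gval <- pool(validate_medium)
  list(theta = as.list(fit$theta),
       objective = fit$objective_value,
       n_evals = fit$n_evals,
       converged = fit$converged,
       training_r2 = gtrain$r_squared,
       training_frac_within_10pct = gtrain$frac_within_band,
       validation_medium = validate_medium,
       validation_r2 = gval$r_squared,
       validation_frac_within_10pct = gval$frac_within_band)
}
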