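# Weighted least-squares calibration of the simulator.
#
# Objective: f(theta) = sum over observables j (pooled across training
# media) of ||m(theta)_j - m_exp,j||^2 / ||sigma_exp,j||^2, where m(theta)_j
# is the simulated observable sampled (linear interpolation) at the
# experimental time points and sigma_exp,j the replicate-SD vector. The
# study's parameter vector has five coordinates: glycine exchange upper
# bound, asparagine exchange lower bound, a bound magnitude shared by the
# remaining amino acids, and the logistic multiplier lambda in the baseline
# and in the high-whey medium.

#' Define a calibration problem
#'
#' @param parameters data.frame with columns `name`, `lower`, `upper`,
#'   `start` (start inside the box).
#' @param observables character vector of observed variables (must include
#'   only variables the simulator produces), e.g.
#'   `c("biomass", "ac_e", "ppa_e", "glc_e", "lcts_e")`.
#' @param data named list (one entry per training medium); each entry a
#'   list with `times` and matrices `mean` and `sd`
#'   (`length(times)` x `length(observables)`, `sd > 0`).
#' @param max_evals objective evaluation budget (default 1e5).
#' @return object of class `calibration_problem`.
#' @export
calibration_problem <- function(parameters, observables, data,
                                max_evals = 100000) {
  parameters <- as.data.frame(parameters)
  stopifnot(all(c("name", "lower", "upper", "start") %in% names(parameters)))
  if (any(parameters$start < parameters$lower |
          parameters$start > parameters$upper))
    stop("start values must lie inside the box bounds")
  for (med in names(data)) {
    d <- data[[med]]
    stopifnot(is.numeric(d$times),
              identical(dim(d$mean), c(length(d$times), length(observables))),
              identical(dim(d$sd), dim(d$mean)))
    if (any(d$sd <= 0)) stop("replicate SDs must be > 0 (medium ", med, ")")
    colnames(data[[med]]$mean) <- colnames(data[[med]]$sd) <- observables
  }
  structure(list(parameters = parameters, observables = observables,
                 data = data, max_evals = max_evals),
            class = "calibration_problem")
}

# weighted residual vector: concatenated (pred - obs) / ||sigma_j|| so that
# sum of squares equals the objective
calibration_residuals <- function(theta, problem, simulator) {
  res <- c()
  for (med in names(problem$data)) {
    d <- problem$data[[med]]
    pred <- tryCatch(simulator(theta, med), error = function(e) NULL)
    if (is.null(pred)) return(NULL)
    pm <- if (inherits(pred, "dfba_trajectory"))
      trajectory_at(pred, d$times, problem$observables) else pred
    for (j in seq_along(problem$observables)) {
      wj <- sqrt(sum(d$sd[, j]^2))
      res <- c(res, (pm[, j] - d$mean[, j]) / wj)
    }
  }
  res
}

#' Calibration objective (Eq.-style weighted sum of squares)
#'
#' @param theta parameter vector (within the problem's box bounds).
#' @param problem a [calibration_problem()].
#' @param simulator function `(theta, medium_name)` returning either a
#'   `dfba_trajectory` or a matrix of observables at the training times.
#' @return non-negative scalar; `Inf` when the simulator aborts.
#' @export
objective <- function(theta, problem, simulator) {
  r <- calibration_residuals(theta, problem, simulator)
  if (is.null(r) || any(!is.finite(r))) return(Inf)
  sum(r^2)
}

#' Calibrate the simulator by bounded least squares
#'
#' Deterministic bounded Levenberg-Marquardt minimisation
#' ([minpack.lm::nls.lm]) of the weighted least-squares objective, with an
#' optional seeded multi-start. The evaluation count (residual and
#' jacobian calls) is capped at the problem's `max_evals`.
#'
#' @param problem a [calibration_problem()].
#' @param simulator see [objective()].
#' @param max_evals overrides the problem's evaluation budget.
#' @param seed integer seed driving the multi-start draws.
#' @param n_starts number of starts (1 = the supplied start only).
#' @param epsfcn forward-difference step scale for the numerical jacobian;
#'   the default 1e-4 (about a 1 percent relative step) keeps derivative
#'   estimates stable across the piecewise-linear kinks an LP-embedded
#'   simulator produces.
#' @return object of class `dfba_fit`.
#' @export
dfba_calibrate <- function(problem, simulator, max_evals = NULL, seed = 1,
                           n_starts = 1, epsfcn = 1e-4) {
  stopifnot(inherits(problem, "calibration_problem"))
  max_evals <- max_evals %||% problem$max_evals
  par <- problem$parameters
  nm <- par$name
  trace_env <- new.env()
  trace_env$n <- 0L
  trace_env$trace <- list()
  count_resid <- function(theta) {
    trace_env$n <- trace_env$n + 1L
    r <- calibration_residuals(theta, problem, simulator)
    f <- if (is.null(r) || any(!is.finite(r))) Inf else sum(r^2)
    trace_env$trace[[trace_env$n]] <- c(eval = trace_env$n, f = f)
    if (!is.finite(f))                       # optimizer-safe sentinel
      r <- rep(1e6, length(unlist(lapply(problem$data, function(d)
        length(d$times))) ) * length(problem$observables))
    r
  }
  set.seed(seed)
  starts <- list(par$start)
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- par$lower + runif(length(nm)) * (par$upper - par$lower)

  f0 <- objective(par$start, problem, simulator)
  trace_env$n <- trace_env$n + 1L
  trace_env$trace[[trace_env$n]] <- c(eval = trace_env$n, f = f0)
  best <- list(theta = setNames(par$start, nm), f = f0, converged = FALSE)
  budget_left <- function() max_evals - trace_env$n
  for (st in starts) {
    if (budget_left() < length(nm) + 2) break
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, lower = par$lower, upper = par$upper,
        fn = count_resid,
        control = minpack.lm::nls.lm.control(
          maxfev = max(budget_left(), 1), maxiter = 200, ptol = 1e-10,
          ftol = 1e-12, epsfcn = epsfcn)),
      error = function(e) NULL)
    if (is.null(fit)) next
    f <- sum(fit$fvec^2)
    if (f < best$f)
      best <- list(theta = setNames(as.numeric(fit$par), nm), f = f,
                   converged = fit$info %in% 1:4)
  }
  tr <- as.data.frame(do.call(rbind, trace_env$trace))
  tr$best <- cummin(ifelse(is.finite(tr$f), tr$f, NA))
  structure(list(theta = best$theta, objective_value = best$f,
                 converged = best$converged, n_evals = trace_env$n,
                 trace = tr, problem = problem, simulator = simulator,
                 seed = seed),
            class = "dfba_fit")
}

#' @export
print.dfba_fit <- function(x, ...) {
  cat("<dfba_fit>\n  parameters:\n")
  print(round(x$theta, 5))
  cat(sprintf("  objective: %.6g after %d evaluations (%s)\n",
              x$objective_value, x$n_evals,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.dfba_fit <- function(object, ...) object$theta

#' @export
summary.dfba_fit <- function(object, ...) {
  par <- object$problem$parameters
  tab <- data.frame(name = par$name, lower = par$lower, upper = par$upper,
                    start = par$start, estimate = unname(object$theta))
  out <- list(parameters = tab, objective = object$objective_value,
              n_evals = object$n_evals, converged = object$converged,
              media = names(object$problem$data),
              observables = object$problem$observables)
  class(out) <- "summary.dfba_fit"
  out
}

#' @export
print.summary.dfba_fit <- function(x, ...) {
  cat("Calibrated dFBA model\n\nParameters:\n")
  print(x$parameters, row.names = FALSE)
  cat(sprintf("\nTraining media: %s\nObservables: %s\n",
              paste(x$media, collapse = ", "),
              paste(x$observables, collapse = ", ")))
  cat(sprintf("Objective %.6g after %d evaluations (%s)\n",
              x$objective, x$n_evals,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict observables from a calibrated model
#' @param object a `dfba_fit`.
#' @param medium medium name understood by the fit's simulator.
#' @param times sampling times (h); default the training times.
#' @param ... ignored.
#' @return matrix `length(times)` x observables.
#' @export
predict.dfba_fit <- function(object, medium, times = NULL, ...) {
  d <- object$problem$data[[medium]]
  times <- times %||% (if (!is.null(d)) d$times else
    stop("supply 'times' for a medium outside the training set"))
  pred <- object$simulator(object$theta, medium)
  if (inherits(pred, "dfba_trajectory"))
    trajectory_at(pred, times, object$problem$observables)
  else pred
}

#' @export
residuals.dfba_fit <- function(object, ...) {
  calibration_residuals(object$theta, object$problem, object$simulator)
}

#' @export
fitted.dfba_fit <- function(object, ...) {
  sapply(names(object$problem$data), function(med)
    predict(object, med), simplify = FALSE)
}

#' Observed-versus-predicted plot for a calibrated model
#' @param x a `dfba_fit`.
#' @param ... ignored.
#' @export
plot.dfba_fit <- function(x, ...) {
  obs <- pred <- c()
  for (med in names(x$problem$data)) {
    d <- x$problem$data[[med]]
    pm <- predict(x, med)
    obs <- c(obs, as.numeric(d$mean)); pred <- c(pred, as.numeric(pm))
  }
  plot(obs, pred, xlab = "observed", ylab = "predicted",
       main = "calibration fit", pch = 19, col = "grey30")
  abline(0, 1, col = "red")
  invisible(x)
}

#' Standard five-parameter simulator factory
#'
#' Builds the `(theta, medium)` closure the study's calibration uses:
#' `theta = (gly_ub, asn_lb, aa_bound, lambda_baseline, lambda_highwhey)`.
#' Glycine's exchange upper bound and asparagine's lower bound are set
#' directly, every other amino-acid exchange gets bounds `(-aa_bound,
#' +aa_bound)`, and the logistic lambda is chosen per medium (the baseline
#' value for any medium other than `highwhey_medium`).
#'
#' @param model base model with proteolytic modules attached.
#' @param media named list of `medium` objects.
#' @param regulations list of [kinetic_regulation()].
#' @param cc_base [carrying_capacity_params()] template; `WP_initial` and
#'   `lambda` are filled per medium.
#' @param wp_species species name holding whey protein (g/L) in the media.
#' @param highwhey_medium medium name using the second lambda.
#' @param dt,horizon,B0,uptake_bound passed to [simulate_dfba()].
#' @return function `(theta, medium_name) -> dfba_trajectory`.
#' @export
standard_simulator <- function(model, media, regulations, cc_base,
                               wp_species = "whey_protein_e",
                               highwhey_medium = "P20",
                               dt = 0.25, horizon = 24, B0 = 0.01,
                               uptake_bound = 10) {
  aa_ex <- model$exchanges[intersect(paste0(amino_acids(), "_e"),
                                     names(model$exchanges))]
  gly <- unname(aa_ex["gly_e"]); asn <- unname(aa_ex["asn_e"])
  others <- setdiff(unname(aa_ex), c(gly, asn))
  function(theta, medium_name) {
    med <- media[[medium_name]]
    if (is.null(med)) stop("unknown medium: ", medium_name)
    ov <- list()
    if (!is.na(gly)) ov[[gly]] <- c(lb = 0, ub = theta[1])
    if (!is.na(asn)) ov[[asn]] <- c(lb = theta[2], ub = 1000)
    for (r in others) ov[[r]] <- c(lb = -theta[3], ub = theta[3])
    cc <- cc_base
    cc$WP_initial <- if (wp_species %in% names(med$concentrations))
      unname(med$concentrations[wp_species]) else 0
    cc$lambda <- if (identical(medium_name, highwhey_medium))
      theta[5] else theta[4]
    simulate_dfba(model, med, regulations = regulations, cc = cc,
                  dt = dt, horizon = horizon, B0 = B0,
                  uptake_bound = uptake_bound, bounds_override = ov)
  }
}
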