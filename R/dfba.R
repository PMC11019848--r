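# The regulated dFBA loop.
#
# Each step: (1) recompute exchange lower bounds from the current broth
# state (availability bound for every open exchange; Monod/Contois factor
# where a regulation targets the exchange); (2) solve FBA; (3) advance
# biomass with the semi-explicit exact-logistic step; (4) advance each
# tracked extracellular concentration with the semi-implicit scheme, using
# the flux and the biomass at the step's start. Infeasible FBA means the
# culture is starved: mu = 0, all fluxes 0, state carried forward.

#' Simulate regulated dynamic FBA
#'
#' @param model a `metabolic_model`.
#' @param med a `medium` supplying initial concentrations.
#' @param regulations list of [kinetic_regulation()] objects (targets named
#'   by exchange reaction id).
#' @param cc a [carrying_capacity_params()].
#' @param dt time step (h); constant, with a final partial step when it
#'   does not divide `horizon`.
#' @param horizon simulated duration (h).
#' @param B0 inoculum biomass (gDW/L), > 0.
#' @param uptake_bound passed to [apply_medium()]: magnitude opened for
#'   medium species (scalar or named per-species).
#' @param close_uptake exchange reaction ids whose uptake is forced shut
#'   (lower bound 0) for the whole run, e.g. amino-acid knockouts.
#' @param bounds_override named list (reaction id -> `c(lb, ub)`) applied
#'   after the medium, e.g. amino-acid exchange bounds: these become the
#'   static intrinsic limits the availability bound is combined with.
#' @param secondary FBA tie-breaking, see [fba()].
#' @param scheme `"semi_implicit"` (the positivity-preserving default) or
#'   `"naive_explicit"`, a comparator running classical dFBA with static
#'   uptake bounds and forward-Euler updates; it can (and on hard steps
#'   does) drive concentrations negative, which is exactly what the
#'   default scheme exists to prevent.
#' @return object of class `dfba_trajectory`: time grid, biomass, tracked
#'   concentrations (mM), per-step growth rate and exchange fluxes.
#' @export
simulate_dfba <- function(model, med, regulations = list(),
                          cc = carrying_capacity_params(T_GLM = 1),
                          dt = 0.1, horizon = 24, B0 = 0.01,
                          uptake_bound = 10,
                          close_uptake = character(0),
                          bounds_override = list(),
                          secondary = c("none", "min_total_flux"),
                          scheme = c("semi_implicit", "naive_explicit")) {
  secondary <- match.arg(secondary)
  scheme <- match.arg(scheme)
  naive <- scheme == "naive_explicit"
  if (B0 <= 0) stop("B0 must be > 0")
  if (dt <= 0 || horizon < 0) stop("dt > 0 and horizon >= 0 required")
  model <- suppressWarnings(apply_medium(model, med, "close", uptake_bound))
  for (rid in names(bounds_override)) {
    bo <- bounds_override[[rid]]
    model <- set_bounds(model, rid,
                        lb = if (!is.na(bo[1])) bo[1],
                        ub = if (length(bo) > 1 && !is.na(bo[2])) bo[2])
  }
  if (length(close_uptake))
    model <- set_bounds(model, close_uptake, lb = 0)

  ex_rxn <- model$exchanges                  # met -> rxn
  ex_met <- names(ex_rxn)
  conc <- setNames(numeric(length(ex_met)), ex_met)
  mm <- medium_mM(med)
  shared <- intersect(names(mm), ex_met)
  conc[shared] <- mm[shared]

  if (!is.null(names(regulations)) && all(nzchar(names(regulations))))
    names(regulations) <- NULL
  reg_rxn <- vapply(regulations, `[[`, "", "reaction")
  missing_reg <- setdiff(reg_rxn, model$rxns$id)
  if (length(missing_reg))
    stop("regulation targets unknown reaction(s): ",
         paste(missing_reg, collapse = ", "))

  ts <- seq(0, horizon, by = dt)
  if (length(ts) == 0 || ts[length(ts)] < horizon - 1e-9)
    ts <- c(ts, horizon)
  n_pt <- length(ts)

  lb_static <- setNames(model$rxns$lb, model$rxns$id)
  ex_idx <- match(unname(ex_rxn), model$rxns$id)

  biomass <- numeric(n_pt); biomass[1] <- B0
  conc_mat <- matrix(NA_real_, n_pt, length(ex_met),
                     dimnames = list(NULL, ex_met))
  conc_mat[1, ] <- conc
  mu <- rep(NA_real_, n_pt)
  flux_mat <- matrix(NA_real_, n_pt, length(ex_met),
                     dimnames = list(NULL, unname(ex_rxn)))
  status <- character(n_pt)

  for (k in seq_len(n_pt - 1)) {
    dtk <- ts[k + 1] - ts[k]
    B <- biomass[k]
    # availability-limited lower bounds for all open exchanges (the naive
    # comparator keeps the static bounds, as classical dFBA does)
    lb_now <- if (naive) lb_static[ex_idx]
              else pmax(-conc / (B * dtk), lb_static[ex_idx])
    names(lb_now) <- unname(ex_rxn)
    for (r in regulations) {
      met <- ex_met[match(r$reaction, unname(ex_rxn))]
      if (is.na(met)) next                     # regulated non-exchange: skip
      ci <- max(conc[met], 0)
      lin <- if (is.null(r$lin)) lb_static[r$reaction] else r$lin
      base <- if (naive) lin else max(-ci / (B * dtk), lin)
      fac <- if (r$kind == "monod") ci / (r$K + ci)
             else ci / (r$K * B + ci)
      if (ci == 0) fac <- 0
      lb_now[r$reaction] <- base * fac
    }
    model$rxns$lb[ex_idx] <- pmin(lb_now, model$rxns$ub[ex_idx])
    sol <- fba(model, secondary = secondary)
    if (sol$status == "optimal") {
      mu_k <- max(sol$objective, 0)
      vex <- sol$fluxes[unname(ex_rxn)]
    } else {
      mu_k <- 0
      vex <- setNames(numeric(length(ex_rxn)), unname(ex_rxn))
    }
    mu[k] <- mu_k
    flux_mat[k, ] <- vex
    biomass[k + 1] <- biomass_step(B, mu_k, cc, dtk)
    conc_new <- if (naive) conc + vex * B * dtk
                else vapply(seq_along(conc), function(i)
                  metabolite_step(conc[i], vex[i], B, dtk), 0)
    names(conc_new) <- ex_met
    if (!naive && (any(conc_new < 0) || biomass[k + 1] < 0))
      stop("positivity breach at t = ", ts[k + 1], "; state: ",
           paste(sprintf("%s=%.3g", ex_met[conc_new < 0],
                         conc_new[conc_new < 0]), collapse = ", "))
    conc <- conc_new
    conc_mat[k + 1, ] <- conc
    status[k] <- sol$status
  }
  structure(list(time = ts, biomass = biomass, conc = conc_mat,
                 mu = mu, exchange_flux = flux_mat, status = status,
                 medium = med$name, model_id = model$id,
                 params = list(dt = dt, horizon = horizon, B0 = B0,
                               cc = cc, regulations = regulations,
                               uptake_bound = uptake_bound,
                               close_uptake = close_uptake,
                               bounds_override = bounds_override)),
            class = "dfba_trajectory")
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cat(sprintf("<dfba_trajectory: medium %s, %d steps over %g h>\n",
              x$medium, length(x$time) - 1, max(x$time)))
  cat(sprintf("  biomass: %.4g -> %.4g gDW/L\n",
              x$biomass[1], x$biomass[length(x$biomass)]))
  invisible(x)
}

#' Tidy data.frame view of a trajectory
#' @param x a `dfba_trajectory`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns time, variable, value, unit, medium.
#' @export
as.data.frame.dfba_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  mets <- colnames(x$conc)
  out <- rbind(
    data.frame(time = x$time, variable = "biomass", value = x$biomass,
               unit = "gDW/L"),
    do.call(rbind, lapply(mets, function(m)
      data.frame(time = x$time, variable = m, value = x$conc[, m],
                 unit = "mM"))))
  out$medium <- x$medium
  rownames(out) <- NULL
  out
}

#' Interpolate a trajectory at arbitrary times
#' @param traj a `dfba_trajectory`.
#' @param times numeric vector within the simulated horizon.
#' @param variables variable names (`"biomass"` or tracked metabolite ids).
#' @return matrix `length(times)` x `length(variables)`.
#' @export
trajectory_at <- function(traj, times, variables) {
  sapply(variables, function(v) {
    y <- if (v == "biomass") traj$biomass else {
      if (!v %in% colnames(traj$conc))
        stop("trajectory does not track '", v, "'")
      traj$conc[, v]
    }
    approx(traj$time, y, xout = times, rule = 2)$y
  })
}

#' @export
plot.dfba_trajectory <- function(x, variables = NULL, ...) {
  if (is.null(variables)) {
    keep <- apply(x$conc, 2, function(z) diff(range(z)) > 1e-9)
    variables <- head(colnames(x$conc)[keep], 5)
  }
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
  plot(x$time, x$biomass, type = "l", lwd = 2, xlab = "time (h)",
       ylab = "biomass (gDW/L)", main = x$medium)
  if (length(variables)) {
    matplot(x$time, x$conc[, variables, drop = FALSE], type = "l", lty = 1,
            xlab = "time (h)", ylab = "concentration (mM)", main = "metabolites")
    legend("topright", legend = variables, col = seq_along(variables),
           lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Final biomass of a trajectory (gDW/L)
#' @param traj a `dfba_trajectory`.
#' @export
final_biomass <- function(traj) traj$biomass[length(traj$biomass)]

#' Amino-acid limitation scan
#'
#' Re-simulates the culture with the uptake of each amino acid (or each
#' unordered pair) closed and ranks the sets by the drop in final biomass.
#'
#' @param model a `metabolic_model` (modules already attached as desired).
#' @param med a `medium`.
#' @param depth `"single"` or `"pair"`.
#' @param scan amino-acid codes to scan; default every amino acid with an
#'   exchange in the model.
#' @param ... simulation arguments passed to [simulate_dfba()].
#' @return data.frame (class `aa_scan`) with columns `set`,
#'   `final_biomass`, `delta` (baseline minus variant), sorted by
#'   decreasing impact.
#' @export
aa_limitation_scan <- function(model, med, depth = c("single", "pair"),
                               scan = NULL, ...) {
  depth <- match.arg(depth)
  aa_ex <- model$exchanges[intersect(paste0(amino_acids(), "_e"),
                                     names(model$exchanges))]
  if (!length(aa_ex)) stop("model has no amino-acid exchanges")
  if (!is.null(scan)) aa_ex <- aa_ex[paste0(scan, "_e")]
  aa <- sub("_e$", "", names(aa_ex))
  sets <- if (depth == "single") as.list(aa)
          else combn(aa, 2, simplify = FALSE)
  base <- final_biomass(simulate_dfba(model, med, ...))
  res <- vapply(sets, function(s) {
    final_biomass(simulate_dfba(model, med,
                                close_uptake = unname(aa_ex[paste0(s, "_e")]),
                                ...))
  }, 0)
  out <- data.frame(set = vapply(sets, paste, "", collapse = "+"),
                    final_biomass = res,
                    delta = base - res)
  out <- out[order(-out$delta, out$set), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  class(out) <- c("aa_scan", "data.frame")
  out
}

#' Compare growth across proteolytic-module subsets
#'
#' Simulates every subset of the supplied modules (2^k conditions) on the
#' same medium.
#'
#' @param model base `metabolic_model` without the modules.
#' @param med a `medium`.
#' @param modules named list of `proteolytic_module` objects.
#' @param ... passed to [simulate_dfba()].
#' @return list with `trajectories` (named by subset label) and `summary`
#'   data.frame (subset, final biomass, final tracked-product levels).
#' @export
module_knockout_compare <- function(model, med, modules, ...) {
  k <- length(modules)
  labels <- names(modules) %||% paste0("module", seq_len(k))
  subsets <- unlist(lapply(0:k, function(m) combn(k, m, simplify = FALSE)),
                    recursive = FALSE)
  trajs <- list()
  for (sub in subsets) {
    m2 <- model
    for (i in sub) m2 <- attach_module(m2, modules[[i]])
    lab <- if (length(sub)) paste(labels[sub], collapse = "+") else "none"
    trajs[[lab]] <- simulate_dfba(m2, med, ...)
  }
  summ <- data.frame(
    subset = names(trajs),
    final_biomass = vapply(trajs, final_biomass, 0))
  for (p in intersect(c("ac_e", "ppa_e", "succ_e"), colnames(trajs[[1]]$conc)))
    summ[[p]] <- vapply(trajs, function(tr) tr$conc[nrow(tr$conc), p], 0)
  rownames(summ) <- NULL
  list(trajectories = trajs, summary = summ)
}
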