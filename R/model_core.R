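# Constraint-based model container and FBA.
#
# A metabolic_model is a plain list: a metabolite table, a reaction table
# with flux bounds (mmol gDW^-1 h^-1; the biomass reaction in h^-1), the
# stoichiometric matrix S (metabolites x reactions) and a single objective
# reaction.  Exchange reactions follow the COBRA export convention: one
# extracellular metabolite with coefficient -1, negative flux = uptake.

#' Construct a constraint-based metabolic model
#'
#' @param id model identifier.
#' @param mets data.frame with columns `id` and optionally `compartment`
#'   (inferred from an `_e`/`_c` id suffix when absent).
#' @param rxns data.frame with columns `id`, `lb`, `ub`.
#' @param S numeric matrix, metabolites by reactions, dimnames matching
#'   `mets$id` and `rxns$id`.
#' @param objective id of the single objective reaction.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, mets, rxns, S, objective) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  rownames(mets) <- rownames(rxns) <- NULL
  if (is.null(mets$compartment))
    mets$compartment <- ifelse(grepl("_e$", mets$id), "e", "c")
  S <- as.matrix(S)
  dimnames(S) <- list(mets$id, rxns$id)
  m <- structure(list(id = id, mets = mets, rxns = rxns, S = S,
                      objective = objective),
                 class = "metabolic_model")
  m$exchanges <- detect_exchanges(m)
  validate_model(m)
  m
}

validate_model <- function(model) {
  with(model, {
    if (anyDuplicated(mets$id)) stop("duplicate metabolite ids")
    if (anyDuplicated(rxns$id)) stop("duplicate reaction ids")
    if (any(rxns$lb > rxns$ub))
      stop("lower bound exceeds upper bound for reaction(s): ",
           paste(rxns$id[rxns$lb > rxns$ub], collapse = ", "))
    if (length(objective) != 1L || !objective %in% rxns$id)
      stop("model must designate exactly one objective reaction")
    if (!identical(dim(S), c(nrow(mets), nrow(rxns))))
      stop("stoichiometric matrix dimensions do not match tables")
  })
  invisible(model)
}

#' Map each extracellular metabolite to its exchange reaction
#'
#' An exchange reaction touches exactly one metabolite, extracellular, with
#' coefficient -1 (export convention: negative flux = uptake).
#'
#' @param model a `metabolic_model`.
#' @return named character vector, metabolite id -> reaction id.
#' @export
detect_exchanges <- function(model) {
  S <- model$S
  extra <- model$mets$id[model$mets$compartment == "e"]
  out <- character(0)
  for (j in seq_len(ncol(S))) {
    nz <- which(S[, j] != 0)
    if (length(nz) == 1L && S[nz, j] == -1 && rownames(S)[nz] %in% extra)
      out[rownames(S)[nz]] <- colnames(S)[j]
  }
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, %d exchanges>\n",
              x$id, nrow(x$mets), nrow(x$rxns), length(x$exchanges)))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Add a reaction to a model
#'
#' New metabolites referenced by `stoich` are appended (compartment from the
#' `_e`/`_c` id suffix).
#'
#' @param model a `metabolic_model`.
#' @param id new unique reaction id.
#' @param stoich named numeric vector of stoichiometric coefficients
#'   (negative = consumed).
#' @param lb,ub flux bounds, `lb <= ub`.
#' @param objective set this reaction as the model objective.
#' @return the augmented `metabolic_model`.
#' @export
add_reaction <- function(model, id, stoich, lb = -1000, ub = 1000,
                         objective = FALSE) {
  if (id %in% model$rxns$id) stop("duplicate reaction id: ", id)
  if (lb > ub) stop("lower bound exceeds upper bound")
  stoich <- stoich[stoich != 0]
  new_mets <- setdiff(names(stoich), model$mets$id)
  if (length(new_mets)) {
    model$mets <- rbind(model$mets,
                        data.frame(id = new_mets,
                                   compartment = ifelse(grepl("_e$", new_mets),
                                                        "e", "c")))
    model$S <- rbind(model$S,
                     matrix(0, length(new_mets), ncol(model$S),
                            dimnames = list(new_mets, colnames(model$S))))
  }
  col <- setNames(numeric(nrow(model$mets)), model$mets$id)
  col[names(stoich)] <- stoich
  model$S <- cbind(model$S, matrix(col, ncol = 1, dimnames = list(NULL, id)))
  model$rxns <- rbind(model$rxns, data.frame(id = id, lb = lb, ub = ub))
  if (objective) model$objective <- id
  model$exchanges <- detect_exchanges(model)
  validate_model(model)
  model
}

#' Remove a reaction (and any metabolites it orphans)
#' @param model a `metabolic_model`.
#' @param id reaction id to drop.
#' @return the reduced model.
#' @export
remove_reaction <- function(model, id) {
  j <- match(id, model$rxns$id)
  if (is.na(j)) stop("no such reaction: ", id)
  if (identical(model$objective, id)) stop("cannot remove the objective reaction")
  model$S <- model$S[, -j, drop = FALSE]
  model$rxns <- model$rxns[-j, , drop = FALSE]
  rownames(model$rxns) <- NULL
  orphan <- rowSums(model$S != 0) == 0
  if (any(orphan)) {
    model$S <- model$S[!orphan, , drop = FALSE]
    model$mets <- model$mets[!orphan, , drop = FALSE]
    rownames(model$mets) <- NULL
  }
  model$exchanges <- detect_exchanges(model)
  model
}

#' Set flux bounds on a reaction
#' @param model a `metabolic_model`.
#' @param id reaction id.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the model.
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  j <- match(id, model$rxns$id)
  if (any(is.na(j))) stop("no such reaction: ", paste(id[is.na(j)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lb[j] <- lb
  if (!is.null(ub)) model$rxns$ub[j] <- ub
  if (any(model$rxns$lb[j] > model$rxns$ub[j]))
    stop("lower bound exceeds upper bound")
  model
}

#' Growth media
#'
#' A medium maps extracellular species to initial concentrations with
#' explicit units and molar masses so g/L and mM interconvert.
#'
#' @param name free-text medium label (e.g. "GLM").
#' @param concentrations named non-negative numeric vector.
#' @param unit single unit or named vector per species, `"g/L"` or `"mM"`.
#' @param molar_mass named numeric vector (g/mol); required for every
#'   species declared in g/L.
#' @return object of class `medium`.
#' @export
medium <- function(name, concentrations, unit = "mM", molar_mass = numeric(0)) {
  if (any(concentrations < 0)) stop("medium concentrations must be >= 0")
  if (length(unit) == 1L)
    unit <- setNames(rep(unit, length(concentrations)), names(concentrations))
  stopifnot(all(unit %in% c("g/L", "mM")))
  need <- names(concentrations)[unit[names(concentrations)] == "g/L"]
  miss <- setdiff(need, names(molar_mass))
  if (length(miss))
    stop("missing molar mass for g/L species: ", paste(miss, collapse = ", "))
  structure(list(name = name, concentrations = concentrations,
                 unit = unit, molar_mass = molar_mass),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium '%s': %d species>\n", x$name, length(x$concentrations)))
  print(data.frame(species = names(x$concentrations),
                   concentration = unname(x$concentrations),
                   unit = unname(x$unit[names(x$concentrations)])))
  invisible(x)
}

#' Medium concentrations in mM
#' @param med a `medium`.
#' @return named numeric vector, all species converted to mM.
#' @export
medium_mM <- function(med) {
  conc <- med$concentrations
  gl <- med$unit[names(conc)] == "g/L"
  conc[gl] <- conc[gl] / med$molar_mass[names(conc)[gl]] * 1000
  conc
}

#' Apply a medium to a model's exchange bounds
#'
#' Exchange lower bounds of species present in the medium are opened to the
#' uptake limit; with `absent_policy = "close"` every other exchange lower
#' bound is set to 0. Upper bounds are untouched. Species with no exchange
#' reaction are reported in a warning and in the `"unmapped"` attribute.
#'
#' @param model a `metabolic_model`.
#' @param med a `medium`.
#' @param absent_policy `"close"` (default) or `"keep"`.
#' @param uptake_bound magnitude of the opened lower bound
#'   (mmol gDW^-1 h^-1); scalar or named per-species vector.
#' @return the model with updated exchange lower bounds.
#' @export
apply_medium <- function(model, med, absent_policy = c("close", "keep"),
                         uptake_bound = 10) {
  absent_policy <- match.arg(absent_policy)
  present <- names(med$concentrations)[med$concentrations > 0]
  unmapped <- setdiff(present, names(model$exchanges))
  if (length(unmapped))
    warning("medium species with no exchange reaction: ",
            paste(unmapped, collapse = ", "))
  mapped <- intersect(present, names(model$exchanges))
  if (absent_policy == "close") {
    absent <- setdiff(names(model$exchanges), mapped)
    model <- set_bounds(model, unname(model$exchanges[absent]), lb = 0)
  }
  if (length(mapped)) {
    lim <- if (length(uptake_bound) == 1L && is.null(names(uptake_bound)))
      setNames(rep(uptake_bound, length(mapped)), mapped)
    else uptake_bound[mapped]
    lim[is.na(lim)] <- 10
    model <- set_bounds(model, unname(model$exchanges[mapped]), lb = -abs(lim))
  }
  attr(model, "unmapped") <- unmapped
  model
}

#' Flux balance analysis
#'
#' Maximises the objective flux subject to steady state (`S v = 0`) and the
#' flux bounds. With `secondary = "min_total_flux"` a second LP picks, among
#' the optima, the flux vector minimising the total absolute flux
#' (a deterministic, parsimonious snapshot).
#'
#' @param model a `metabolic_model`.
#' @param secondary `"none"` or `"min_total_flux"`.
#' @return object of class `flux_distribution`: named `fluxes`, `objective`
#'   (the FBA growth rate when the objective is biomass), `status`.
#' @export
fba <- function(model, secondary = c("none", "min_total_flux")) {
  secondary <- match.arg(secondary)
  S <- model$S
  n <- ncol(S)
  obj <- as.numeric(colnames(S) == model$objective)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), model$rxns$lb, model$rxns$ub,
                  maximize = TRUE)
  if (sol$status != "optimal") {
    return(structure(list(fluxes = setNames(rep(NA_real_, n), colnames(S)),
                          objective = NA_real_, status = sol$status),
                     class = "flux_distribution"))
  }
  v <- sol$solution
  if (secondary == "min_total_flux") {
    mu <- sol$objective
    lb <- model$rxns$lb; ub <- model$rxns$ub
    M <- max(abs(c(lb, ub)), 1)
    # variables z = (p, n) >= 0 with v = p - n; minimise sum(p + n)
    Aeq <- rbind(cbind(S, -S), c(obj, -obj))
    beq <- c(rep(0, nrow(S)), mu)
    Ale <- rbind(cbind(diag(n), -diag(n)),    # v <= ub
                 cbind(-diag(n), diag(n)))    # -v <= -lb
    ble <- c(ub, -lb)
    sol2 <- solve_lp(rep(1, 2 * n), Aeq, beq,
                     rep(0, 2 * n), rep(M, 2 * n),
                     maximize = FALSE, Ale = Ale, ble = ble)
    if (sol2$status == "optimal")
      v <- sol2$solution[seq_len(n)] - sol2$solution[n + seq_len(n)]
  }
  v <- setNames(v, colnames(S))
  structure(list(fluxes = v, objective = sum(obj * v), status = "optimal"),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution: status %s, objective %s>\n",
              x$status,
              if (is.na(x$objective)) "NA" else format(x$objective)))
  invisible(x)
}
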