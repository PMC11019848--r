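# Model and medium serialisation.
#
# JSON dialect (fixture format):
#   { "id": ..., "objective": "...",
#     "metabolites": [{"id": "...", "compartment": "e"|"c"}, ...],
#     "reactions":   [{"id": "...", "lb": num, "ub": num,
#                      "metabolites": {"met": coef, ...}}, ...] }
# Media files: YAML (species: {concentration, unit, molar_mass}) or
# two/three-column TSV (species, concentration, unit).

#' Read a metabolic model from disk
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to disk
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (format == "json") write_model_json(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  for (f in c("id", "metabolites", "reactions", "objective"))
    if (is.null(doc[[f]])) stop("model JSON missing field '", f, "'")
  mets <- data.frame(
    id = vapply(doc$metabolites, `[[`, "", "id"),
    compartment = vapply(doc$metabolites, function(m)
      if (is.null(m$compartment)) NA_character_ else m$compartment, ""))
  if (anyNA(mets$compartment))
    mets$compartment <- ifelse(grepl("_e$", mets$id), "e", "c")
  rids <- vapply(doc$reactions, `[[`, "", "id")
  rxns <- data.frame(
    id = rids,
    lb = vapply(doc$reactions, function(r) {
      if (is.null(r$lb)) stop("reaction '", r$id, "' lacks flux bounds")
      as.numeric(r$lb)
    }, 0),
    ub = vapply(doc$reactions, function(r) {
      if (is.null(r$ub)) stop("reaction '", r$id, "' lacks flux bounds")
      as.numeric(r$ub)
    }, 0))
  S <- matrix(0, nrow(mets), length(rids), dimnames = list(mets$id, rids))
  for (k in seq_along(doc$reactions)) {
    st <- doc$reactions[[k]]$metabolites
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction '", rids[k], "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    S[names(st), k] <- unlist(st)
  }
  metabolic_model(doc$id, mets, rxns, S, doc$objective)
}

write_model_json <- function(model, path) {
  rx <- lapply(seq_len(nrow(model$rxns)), function(j) {
    st <- model$S[, j]
    st <- st[st != 0]
    list(id = model$rxns$id[j], lb = model$rxns$lb[j], ub = model$rxns$ub[j],
         metabolites = as.list(st))
  })
  doc <- list(id = model$id,
              objective = model$objective,
              metabolites = lapply(seq_len(nrow(model$mets)), function(i)
                list(id = model$mets$id[i],
                     compartment = model$mets$compartment[i])),
              reactions = rx)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
}

#' Read a medium definition
#'
#' YAML layout: top-level `name`, then `species:` mapping each species to
#' `concentration`, `unit` and optionally `molar_mass`. TSV layout: columns
#' species, concentration, unit (molar masses must then be supplied).
#'
#' @param path YAML or TSV file.
#' @param molar_mass named vector merged over any file-level molar masses.
#' @return a `medium`.
#' @export
read_medium <- function(path, molar_mass = numeric(0)) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    sp <- doc$species
    conc <- vapply(sp, function(s) as.numeric(s$concentration), 0)
    unit <- vapply(sp, function(s) if (is.null(s$unit)) "mM" else s$unit, "")
    mm <- unlist(lapply(sp, function(s) s$molar_mass))
    names(conc) <- names(unit) <- names(sp)
    medium(doc$name %||% basename(path), conc, unit,
           c(molar_mass, mm)[!duplicated(c(names(molar_mass), names(mm)))])
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    unit <- if ("unit" %in% names(tab)) tab$unit else "mM"
    medium(sub("\\.[^.]+$", "", basename(path)),
           setNames(tab$concentration, tab$species),
           setNames(rep(unit, length.out = nrow(tab)), tab$species),
           molar_mass)
  }
}

#' Write a medium definition as YAML
#' @param med a `medium`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  sp <- lapply(names(med$concentrations), function(s) {
    out <- list(concentration = unname(med$concentrations[s]),
                unit = unname(med$unit[s]))
    if (s %in% names(med$molar_mass))
      out$molar_mass <- unname(med$molar_mass[s])
    out
  })
  names(sp) <- names(med$concentrations)
  yaml::write_yaml(list(name = med$name, species = sp), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
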