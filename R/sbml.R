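# SBML Level 3 Version 1 + fbc version 2 read/write, via xml2.
#
# Covers the constraint-based subset: compartments, species, reactions with
# fbc flux-bound parameters, and the active maximisation objective.  Ids are
# written with the conventional M_/R_ prefixes and stripped on read.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x)
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  pid <- function(v) sprintf("par_bnd_%d", match(v, bounds))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">'), SBML_NS, FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>',
    sprintf('      <compartment id="%s" constant="true"/>',
            unique(model$mets$compartment)),
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf(paste0('      <species id="M_%s" compartment="%s" ',
                   'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                   'constant="false"/>'),
            esc(model$mets$id), model$mets$compartment),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="%s" value="%s" constant="true"/>',
            pid(bounds), format(bounds, digits = 17, scientific = FALSE)),
    '    </listOfParameters>',
    '    <listOfReactions>')
  for (j in seq_len(nrow(model$rxns))) {
    st <- model$S[, j]
    reac <- st[st < 0]; prod <- st[st > 0]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(model$rxns$id[j]),
      if (model$rxns$lb[j] < 0) "true" else "false",
      pid(model$rxns$lb[j]), pid(model$rxns$ub[j])))
    if (length(reac))
      lines <- c(lines, '        <listOfReactants>',
                 sprintf(paste0('          <speciesReference species="M_%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(reac)),
                         format(-unname(reac), digits = 17)),
                 '        </listOfReactants>')
    if (length(prod))
      lines <- c(lines, '        <listOfProducts>',
                 sprintf(paste0('          <speciesReference species="M_%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(names(prod)),
                         format(unname(prod), digits = 17)),
                 '        </listOfProducts>')
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines,
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                   'fbc:coefficient="1"/>'), esc(model$objective)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure: ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mod, "xml_missing")) stop("SBML parse failure: no <model>")
  strip <- function(x, pre) sub(paste0("^", pre), "", x)

  sp <- xml2::xml_find_all(mod, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    compartment = xml2::xml_attr(sp, "compartment"))

  pars <- xml2::xml_find_all(mod, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))

  rx <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("SBML parse failure: no reactions")
  rids <- strip(xml2::xml_attr(rx, "id"), "R_")
  lbp <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
  ubp <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
  if (anyNA(lbp) || anyNA(ubp))
    stop("SBML reaction(s) lacking fbc flux bounds: ",
         paste(rids[is.na(lbp) | is.na(ubp)], collapse = ", "))
  bad <- !(lbp %in% names(pval)) | !(ubp %in% names(pval))
  if (any(bad))
    stop("SBML flux-bound parameter(s) undefined for: ",
         paste(rids[bad], collapse = ", "))
  rxns <- data.frame(id = rids, lb = unname(pval[lbp]), ub = unname(pval[ubp]))

  S <- matrix(0, nrow(mets), length(rids), dimnames = list(mets$id, rids))
  for (k in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[k]],
                                 sprintf("./s:%s/s:speciesReference", side), ns)
      if (!length(refs)) next
      ids <- strip(xml2::xml_attr(refs, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sign <- if (side == "listOfReactants") -1 else 1
      S[ids, k] <- S[ids, k] + sign * coef
    }
  }

  fo <- xml2::xml_find_first(
    mod, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing"))
    stop("SBML model has no objective")
  objective <- strip(xml2::xml_attr(fo, "fbc:reaction", ns = ns), "R_")
  metabolic_model(xml2::xml_attr(mod, "id"), mets, rxns, S, objective)
}
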