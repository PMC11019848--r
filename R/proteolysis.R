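# Proteolytic pseudo-reactions.
#
# A proteolytic module converts one mole of substrate protein plus chi mol
# ATP (full hydrolysis: ATP + H2O -> ADP + Pi + H) into its constituent
# free amino acids:
#     Protein + chi ATP + chi H2O -> sum_i R_i AA_i + chi ADP + chi Pi + chi H
# R_i are the residue counts of the (mean) substrate composition; chi is
# the ATP-equivalent cost of synthesising the proteases that do the work.

# the 20 proteinogenic amino acids: average residue mass (g/mol, residue =
# free amino acid - water) and carbon count, used for molar masses and for
# the toy network's carbon bookkeeping
AA_TABLE <- data.frame(
  aa = c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his",
         "ile", "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp",
         "tyr", "val"),
  residue_mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12,
                   57.05, 137.14, 113.16, 113.16, 128.17, 131.19, 147.18,
                   97.12, 87.08, 101.10, 186.21, 163.18, 99.13),
  carbons = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5))
WATER_MASS <- 18.02

#' Names of the 20 proteinogenic amino acids
#' @return character vector of lower-case three-letter codes.
#' @export
amino_acids <- function() AA_TABLE$aa

#' Protein amino-acid composition
#'
#' Residue counts may be non-integer so that mean compositions are
#' representable. The molar mass, when not supplied, is computed from the
#' residues as `sum(counts * residue_mass) + water` (one water per chain).
#'
#' @param name protein name.
#' @param counts named non-negative numeric vector over three-letter
#'   amino-acid codes; missing residues count 0.
#' @param molar_mass optional molar mass (g/mol).
#' @return object of class `protein_composition`.
#' @export
protein_composition <- function(name, counts, molar_mass = NULL) {
  bad <- setdiff(names(counts), AA_TABLE$aa)
  if (length(bad)) stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("residue counts must be >= 0")
  full <- setNames(numeric(20), AA_TABLE$aa)
  full[names(counts)] <- counts
  if (sum(full) <= 0) stop("composition must have at least one positive count")
  if (is.null(molar_mass))
    molar_mass <- sum(full * AA_TABLE$residue_mass) + WATER_MASS
  if (molar_mass <= 0) stop("molar mass must be positive")
  structure(list(name = name, counts = full, molar_mass = molar_mass),
            class = "protein_composition")
}

#' @export
print.protein_composition <- function(x, ...) {
  cat(sprintf("<protein_composition '%s': %.1f residues, %.1f g/mol>\n",
              x$name, sum(x$counts), x$molar_mass))
  invisible(x)
}

#' Mean residue composition of several proteins
#'
#' The whey-protein substrate, for instance, is taken as the residue-wise
#' arithmetic mean of beta-lactoglobulin and alpha-lactalbumin.
#'
#' @param components non-empty list of `protein_composition` objects.
#' @return a `protein_composition` with averaged counts.
#' @export
mean_composition <- function(components) {
  if (!length(components)) stop("mean_composition() needs at least one composition")
  cts <- rowMeans(vapply(components, function(p) p$counts,
                         numeric(20)))
  protein_composition(paste(vapply(components, `[[`, "", "name"),
                            collapse = "+"),
                      cts)
}

#' Read protein compositions from CSV
#'
#' Expected columns: `protein` plus one column per three-letter amino-acid
#' code (extra columns ignored).
#'
#' @param path CSV file.
#' @return named list of `protein_composition` objects.
#' @export
read_compositions <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  names(tab) <- tolower(names(tab))
  aa_cols <- intersect(AA_TABLE$aa, names(tab))
  if (!length(aa_cols)) stop("no amino-acid columns found in ", path)
  out <- lapply(seq_len(nrow(tab)), function(i)
    protein_composition(tab$protein[i],
                        unlist(tab[i, aa_cols])))
  setNames(out, tab$protein)
}

#' Amino-acid ATP biosynthesis cost table
#' @param costs named non-negative numeric vector over all 20 amino acids
#'   (mol ATP per mol residue).
#' @return object of class `aa_cost_table`.
#' @export
aa_cost_table <- function(costs) {
  miss <- setdiff(AA_TABLE$aa, names(costs))
  if (length(miss))
    stop("cost table missing amino acid(s): ", paste(miss, collapse = ", "))
  if (any(costs < 0)) stop("costs must be >= 0")
  structure(list(costs = costs[AA_TABLE$aa]), class = "aa_cost_table")
}

#' Read an amino-acid cost table (CSV with columns aa, cost; or YAML map)
#' @param path file path.
#' @return an `aa_cost_table`.
#' @export
read_cost_table <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    aa_cost_table(unlist(doc))
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    names(tab) <- tolower(names(tab))
    aa_cost_table(setNames(tab$cost, tab$aa))
  }
}

#' ATP cost of synthesising one protein
#'
#' Sum over residues of count x per-residue ATP cost, optionally rescaled
#' by a normalisation factor (so the cost can be expressed per protein,
#' per residue, or in any other convention a cost table assumes).
#'
#' @param composition a `protein_composition`.
#' @param costs an `aa_cost_table`.
#' @param normalization multiplicative factor applied to the raw sum.
#' @return mol ATP per mol protein.
#' @export
protease_cost <- function(composition, costs, normalization = 1) {
  stopifnot(inherits(composition, "protein_composition"),
            inherits(costs, "aa_cost_table"))
  sum(composition$counts * costs$costs) * normalization
}

#' Mean ATP cost over a set of proteases
#' @param proteases non-empty list of `protein_composition` objects.
#' @inheritParams protease_cost
#' @return arithmetic-mean cost (the module's chi when averaged over the
#'   organism's nutrition proteases).
#' @export
mean_protease_cost <- function(proteases, costs, normalization = 1) {
  if (!length(proteases)) stop("mean_protease_cost() needs at least one protease")
  mean(vapply(proteases, protease_cost, 0, costs = costs,
              normalization = normalization))
}

# chi shipped as default: the study's reported average ATP cost of protease
# biosynthesis, 23 mol ATP per mol protease
DEFAULT_CHI <- 23

#' Build a proteolytic pseudo-reaction
#'
#' @param protein substrate `protein_composition` (residue counts become the
#'   product stoichiometry R_i).
#' @param chi ATP cost per mole of degraded protein (default 23).
#' @param id_prefix prefix of the generated reaction id.
#' @return object of class `proteolytic_module` with fields `substrate`
#'   (species id), `R` (named amino-acid stoichiometry), `chi`, `id`,
#'   `molar_mass`.
#' @export
build_proteolytic_module <- function(protein, chi = DEFAULT_CHI,
                                     id_prefix = "PROT") {
  stopifnot(inherits(protein, "protein_composition"))
  if (chi < 0) stop("chi must be >= 0")
  R <- protein$counts[protein$counts > 0]
  sub_id <- paste0(gsub("[^A-Za-z0-9]+", "_", tolower(protein$name)), "_e")
  structure(list(substrate = sub_id,
                 substrate_name = protein$name,
                 R = R, chi = chi,
                 id = paste0(id_prefix, "_", gsub("[^A-Za-z0-9]+", "_",
                                                  tolower(protein$name))),
                 molar_mass = protein$molar_mass),
            class = "proteolytic_module")
}

#' @export
print.proteolytic_module <- function(x, ...) {
  lhs <- sprintf("%s + %g atp", x$substrate, x$chi)
  rhs <- paste(sprintf("%g %s", unname(x$R), paste0(names(x$R), "_e")),
               collapse = " + ")
  cat(sprintf("<proteolytic_module %s>\n  %s -> %s\n", x$id, lhs, rhs))
  invisible(x)
}

#' Reaction stoichiometry of a proteolytic module
#'
#' @param module a `proteolytic_module`.
#' @param energy named mapping for the energy species ids (`atp`, `adp`,
#'   `pi`, `h2o`, `h`).
#' @return named stoichiometric vector (negative = consumed).
#' @export
module_stoichiometry <- function(module,
                                 energy = c(atp = "atp_c", adp = "adp_c",
                                            pi = "pi_c", h2o = "h2o_c",
                                            h = "h_c")) {
  st <- setNames(-1, module$substrate)
  st[paste0(names(module$R), "_e")] <- unname(module$R)
  if (module$chi > 0) {
    st[energy[["atp"]]] <- -module$chi
    st[energy[["h2o"]]] <- -module$chi
    st[energy[["adp"]]] <- module$chi
    st[energy[["pi"]]] <- module$chi
    st[energy[["h"]]] <- module$chi
  }
  st
}

#' Attach a proteolytic module to a model
#'
#' Adds the extracellular protein species, its exchange reaction (closed
#' until a medium supplies the protein) and the proteolytic reaction.
#' The model must already carry extracellular species and exchanges for the
#' produced amino acids and the energy species used by ATP hydrolysis.
#'
#' @param model a `metabolic_model`.
#' @param module a `proteolytic_module`.
#' @param energy energy-species id mapping, see [module_stoichiometry()].
#' @return the augmented model.
#' @export
attach_module <- function(model, module,
                          energy = c(atp = "atp_c", adp = "adp_c",
                                     pi = "pi_c", h2o = "h2o_c", h = "h_c")) {
  aa_sp <- paste0(names(module$R), "_e")
  miss <- setdiff(aa_sp, model$mets$id)
  if (length(miss))
    stop("model lacks extracellular amino acid(s): ",
         paste(miss, collapse = ", "))
  no_ex <- setdiff(aa_sp, names(model$exchanges))
  if (length(no_ex))
    stop("model lacks exchange reaction(s) for: ",
         paste(no_ex, collapse = ", "))
  if (module$chi > 0) {
    miss_e <- setdiff(unname(energy), model$mets$id)
    if (length(miss_e))
      stop("model lacks energy species: ", paste(miss_e, collapse = ", "),
           "; map them via the 'energy' argument")
  }
  if (module$substrate %in% model$mets$id)
    stop("protein species already present: ", module$substrate)
  model <- add_reaction(model, paste0("EX_", module$substrate),
                        setNames(-1, module$substrate), lb = 0, ub = 1000)
  model <- add_reaction(model, module$id, module_stoichiometry(module, energy),
                        lb = 0, ub = 1000)
  model
}
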