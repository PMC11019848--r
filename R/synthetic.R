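# Synthetic study system: a toy anaerobic gut-bacterium network, the
# study's media (glucose-limited baseline GLM and its whey-supplemented
# variants P2/P20), protein-composition fixtures, and noisy culture
# experiments with the study's sampling design (0/6/12/24 h, 3 replicates,
# Gaussian measurement noise truncated at zero).
#
# The toy network is a stand-in for a genome-scale reconstruction: lumped
# anaerobic glucose/lactose/pyruvate fermentation to acetate, propionate
# (via succinate) and CO2, a generic amino-acid precursor pool feeding a
# biomass reaction with ATP demand, per-amino-acid uptake and catabolism,
# and full energy bookkeeping (ATP/ADP/Pi/H2O/H) so proteolytic modules
# attach cleanly. Glycine is deliberately left without catabolic or
# anabolic use: proteolysis forces its secretion, mirroring the observed
# extracellular glycine accumulation and giving its exchange upper bound a
# role in calibration.

#' Toy network configuration
#'
#' @param amino_acids amino acids given extracellular species + exchanges.
#' @param uptake_aas subset usable as biomass precursor (default all but
#'   glycine).
#' @param catabolism_aas subset catabolisable to SCFA + ammonium (default
#'   all but glycine).
#' @param glucose,lactose,pyruvate include these catabolic subsystems.
#' @param atp_per_glc ATP yield of the acetogenic glucose branch.
#' @param biomass_aap,biomass_atp precursor (mmol) and ATP (mmol) demand
#'   per gDW of biomass.
#' @param maintenance non-growth ATP maintenance flux (forced lower bound).
#' @param seed,jitter optional seeded relative jitter on catabolic ATP
#'   yields (model realism knob; 0 = fully deterministic).
#' @return list of class `toy_config`.
#' @export
toy_config <- function(amino_acids = proteodfba::amino_acids(),
                       uptake_aas = setdiff(amino_acids, "gly"),
                       catabolism_aas = setdiff(amino_acids, "gly"),
                       glucose = TRUE, lactose = TRUE, pyruvate = TRUE,
                       atp_per_glc = 3, biomass_aap = 7, biomass_atp = 25,
                       maintenance = 0.3, seed = 1, jitter = 0) {
  cfg <- list(amino_acids = amino_acids,
              uptake_aas = intersect(uptake_aas, amino_acids),
              catabolism_aas = intersect(catabolism_aas, amino_acids),
              glucose = glucose, lactose = lactose, pyruvate = pyruvate,
              atp_per_glc = atp_per_glc, biomass_aap = biomass_aap,
              biomass_atp = biomass_atp, maintenance = maintenance,
              seed = seed, jitter = jitter)
  class(cfg) <- "toy_config"
  cfg
}

# amino acids fermented to succinate (4C backbone); the rest go to acetate
SUCC_AAS <- c("asp", "asn", "glu", "gln", "pro", "arg")

#' Build the toy gut-bacterium metabolic model
#'
#' Grows on glucose plus mineral nitrogen, faster when free amino acids
#' are supplied (direct precursor use saves the ATP of de novo synthesis),
#' secretes acetate, propionate and succinate, and carries every species a
#' proteolytic module needs.
#'
#' @param config a [toy_config()].
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(config = toy_config()) {
  stopifnot(inherits(config, "toy_config"))
  if (!config$glucose && !config$lactose && !config$pyruvate &&
      !length(config$catabolism_aas))
    stop("toy config excludes every carbon source")
  aa <- config$amino_acids
  carb <- setNames(AA_TABLE$carbons, AA_TABLE$aa)

  mets <- c("glc_e", if (config$lactose) "lcts_e",
            if (config$pyruvate) "pyr_e",
            "succ_e", "ac_e", "ppa_e", "co2_e", "nh4_e",
            paste0(aa, "_e"),
            "atp_c", "adp_c", "pi_c", "h2o_c", "h_c", "aap_c")
  rxn <- list(); bounds <- list()
  add <- function(id, st, lb = 0, ub = 1000) {
    rxn[[id]] <<- st
    bounds[[id]] <<- c(lb, ub)
  }
  for (m in grep("_e$", mets, value = TRUE))
    add(paste0("EX_", m), setNames(-1, m))
  jit <- function(x) {
    if (config$jitter <= 0) return(x)
    x * (1 + config$jitter * (runif(length(x)) * 2 - 1))
  }
  if (config$jitter > 0) set.seed(config$seed)
  energy <- function(n) c(adp_c = -n, pi_c = -n, atp_c = n, h2o_c = n)
  if (config$glucose) {
    y <- jit(config$atp_per_glc)
    add("CAT_GLC_AC", c(glc_e = -1, ac_e = 2, co2_e = 2, energy(y)))
    add("CAT_GLC_SUCC", c(glc_e = -1, co2_e = -2, succ_e = 2, energy(2)))
  }
  add("CAT_SUCC_PPA", c(succ_e = -1, ppa_e = 1, co2_e = 1, energy(0.25)))
  if (config$lactose)
    add("CAT_LCTS", c(lcts_e = -1, h2o_c = -1, glc_e = 2))
  if (config$pyruvate)
    add("CAT_PYR", c(pyr_e = -1, ac_e = 1, co2_e = 1, energy(1)))
  # de novo precursor synthesis from glucose + mineral N, ATP-expensive
  add("SYN_AAP", c(glc_e = -1, nh4_e = -1.4, atp_c = -4, h2o_c = -4,
                   aap_c = 1.4, adp_c = 4, pi_c = 4))
  for (a in intersect(config$uptake_aas, aa))
    add(paste0("UPT_", a),
        setNames(c(-1, carb[a] / 4.3), c(paste0(a, "_e"), "aap_c")))
  for (a in intersect(config$catabolism_aas, aa)) {
    C <- carb[a]
    st <- setNames(-1, paste0(a, "_e"))
    if (a %in% SUCC_AAS) {
      st["succ_e"] <- 1
      if (C > 4) st["co2_e"] <- C - 4
    } else {
      st["ac_e"] <- (C - 1) / 2
      st["co2_e"] <- 1
    }
    st["nh4_e"] <- 1
    add(paste0("CAT_", a), c(st, energy(jit(1))))
  }
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      lb = config$maintenance)
  add("BIOMASS", c(aap_c = -config$biomass_aap,
                   atp_c = -config$biomass_atp,
                   h2o_c = -config$biomass_atp,
                   adp_c = config$biomass_atp, pi_c = config$biomass_atp,
                   h_c = config$biomass_atp))
  add("DM_h", c(h_c = -1))
  add("SK_h2o", c(h2o_c = -1), lb = -1000)

  rids <- names(rxn)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(rxn)) S[names(rxn[[j]]), j] <- rxn[[j]]
  metabolic_model("toy_gut_bacterium",
                  data.frame(id = mets),
                  data.frame(id = rids,
                             lb = vapply(bounds, `[`, 0, 1),
                             ub = vapply(bounds, `[`, 0, 2)),
                  S, objective = "BIOMASS")
}

#' Three-reaction linear chain fixture
#'
#' Exchange -> transport -> biomass with yield `yield` gDW per mmol
#' glucose; with the exchange uptake bound at `uptake` the FBA growth rate
#' is `yield * uptake` exactly (hand-solvable LP).
#'
#' @param yield biomass yield (gDW/mmol), default 0.1.
#' @param uptake uptake bound magnitude (mmol gDW^-1 h^-1), default 10.
#' @return a `metabolic_model` with 3 reactions.
#' @export
make_chain_model <- function(yield = 0.1, uptake = 10) {
  mets <- c("glc_e", "glc_c")
  rids <- c("EX_glc_e", "GLCt", "BIOMASS")
  S <- matrix(0, 2, 3, dimnames = list(mets, rids))
  S["glc_e", "EX_glc_e"] <- -1
  S["glc_e", "GLCt"] <- -1; S["glc_c", "GLCt"] <- 1
  S["glc_c", "BIOMASS"] <- -1 / yield
  metabolic_model("chain_toy", data.frame(id = mets),
                  data.frame(id = rids, lb = c(-uptake, 0, 0),
                             ub = c(1000, 1000, 1000)),
                  S, objective = "BIOMASS")
}

#' Bundled protein-composition fixtures
#'
#' Representative (synthetic) residue compositions for beta-lactoglobulin,
#' alpha-lactalbumin and the baseline-medium protein pool (bactopeptone +
#' meat extract stand-in), shipped as an editable CSV under `extdata`.
#'
#' @return named list of `protein_composition` objects.
#' @export
default_compositions <- function() {
  read_compositions(system.file("extdata",
                                "protein_compositions_synthetic.csv",
                                package = "proteodfba"))
}

#' Whey-protein substrate composition
#'
#' Residue-wise mean of the beta-lactoglobulin and alpha-lactalbumin
#' fixtures, renamed so the substrate species id is `whey_protein_e`.
#' @return a `protein_composition` named `"whey_protein"`.
#' @export
whey_composition <- function() {
  comps <- default_compositions()
  m <- mean_composition(comps[c("beta_lg", "alpha_la")])
  protein_composition("whey_protein", m$counts)
}

#' Baseline-medium protein composition (renamed `glm_protein`)
#' @return a `protein_composition` named `"glm_protein"`.
#' @export
glm_protein_composition <- function() {
  comps <- default_compositions()
  protein_composition("glm_protein", comps[["glm_protein"]]$counts)
}

#' Bundled per-residue ATP biosynthesis cost table
#'
#' Representative (synthetic) aerobic ATP-equivalent biosynthesis costs per
#' amino-acid residue, shipped as an editable CSV under `extdata`.
#' @return an `aa_cost_table`.
#' @export
default_cost_table <- function() {
  read_cost_table(system.file("extdata", "aa_atp_cost_synthetic.csv",
                              package = "proteodfba"))
}

#' The study's media fixtures
#'
#' Glucose 5 g/L in all media; lactose 0.16 / 0.19 / 0.36 g/L and total
#' protein 7.28 / 8.51 / 21.87 g/L in GLM / P2 / P20 (post-filtration
#' values). Total protein splits into the baseline pool (`glm_protein_e`,
#' 7.28 g/L everywhere) and whey (`whey_protein_e`, total minus baseline).
#' Sodium pyruvate and succinate at 1 g/L, L-cysteine 0.5 g/L; a synthetic
#' mineral-nitrogen pool (`nh4_e`) stands in for the undisclosed free
#' amino-nitrogen of the peptones.
#'
#' @param glm_protein_mass,whey_protein_mass molar masses (g/mol); default
#'   computed from the bundled compositions.
#' @param nh4_gL mineral-nitrogen pool (g/L).
#' @param aa_gL free amino-acid pool carried by the peptones (g/L,
#'   identical in the three media): a scalar applied to every amino acid,
#'   or a named vector overriding single amino acids (e.g.
#'   `c(asn = 0.3)`); the exact free amino-acid content of
#'   bactopeptone/meat extract is not published, so this is a configurable
#'   stand-in.
#' @return named list of three `medium` objects (GLM, P2, P20).
#' @export
make_media <- function(glm_protein_mass = NULL, whey_protein_mass = NULL,
                       nh4_gL = 0.5, aa_gL = 0.05) {
  glm_protein_mass <- glm_protein_mass %||% glm_protein_composition()$molar_mass
  whey_protein_mass <- whey_protein_mass %||% whey_composition()$molar_mass
  aa_sp <- paste0(AA_TABLE$aa, "_e")
  aa_mm <- setNames(AA_TABLE$residue_mass + WATER_MASS, aa_sp)
  mm <- c(glc_e = 180.16, lcts_e = 342.30, pyr_e = 88.06, succ_e = 118.09,
          nh4_e = 18.04, aa_mm,
          glm_protein_e = glm_protein_mass,
          whey_protein_e = whey_protein_mass)
  lactose <- c(GLM = 0.16, P2 = 0.19, P20 = 0.36)
  protein_total <- c(GLM = 7.28, P2 = 8.51, P20 = 21.87)
  out <- lapply(names(lactose), function(nm) {
    base_gL <- if (is.null(names(aa_gL))) aa_gL[1] else 0.05
    aa_conc <- setNames(rep(base_gL, length(aa_sp)), aa_sp)
    if (!is.null(names(aa_gL)))
      aa_conc[paste0(names(aa_gL), "_e")] <- aa_gL
    aa_conc["cys_e"] <- aa_conc["cys_e"] + 0.5    # L-cysteine HCl in GLM
    conc <- c(glc_e = 5, lcts_e = lactose[[nm]],
              glm_protein_e = protein_total[["GLM"]],
              whey_protein_e = protein_total[[nm]] - protein_total[["GLM"]],
              pyr_e = 1, succ_e = 1, nh4_e = nh4_gL, aa_conc)
    medium(nm, conc, unit = "g/L", molar_mass = mm)
  })
  setNames(out, names(lactose))
}

#' Default kinetic regulations for the toy model
#'
#' Monod on glucose uptake; Contois on lactose and on both protein pools
#' (hydrolysis needs cell-substrate contact).
#'
#' @param K_glc,K_lcts,K_prot half-saturation constants.
#' @param lin_glc,lin_lcts,lin_prot intrinsic uptake bounds (negative).
#' @return list of [kinetic_regulation()] objects.
#' @export
default_regulations <- function(K_glc = 0.5, K_lcts = 2, K_prot = 0.4,
                                lin_glc = -10, lin_lcts = -2,
                                lin_prot = -0.05) {
  list(kinetic_regulation("EX_glc_e", "monod", K = K_glc, lin = lin_glc),
       kinetic_regulation("EX_lcts_e", "contois", K = K_lcts, lin = lin_lcts),
       kinetic_regulation("EX_glm_protein_e", "contois", K = K_prot,
                          lin = lin_prot),
       kinetic_regulation("EX_whey_protein_e", "contois", K = K_prot,
                          lin = lin_prot))
}

#' Measurement-noise specification
#'
#' Emulates the study's sampling design: 0, 6, 12, 24 h, three independent
#' replicates, Gaussian noise truncated at zero.
#'
#' @param sd per-variable SD: scalar or named vector; interpreted as
#'   relative (fraction of the true value) when `relative = TRUE`.
#' @param relative logical.
#' @param replicates number of replicates (>= 1).
#' @param times sampling times (h).
#' @param seed integer seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.05, relative = TRUE, replicates = 3,
                       times = c(0, 6, 12, 24), seed = 1) {
  if (any(sd < 0)) stop("noise SDs must be >= 0")
  if (replicates < 1) stop("need >= 1 replicate")
  structure(list(sd = sd, relative = relative, replicates = replicates,
                 times = times, seed = seed),
            class = "noise_spec")
}

#' Simulate a noisy culture experiment
#'
#' Runs the simulator for the ground truth, samples it at the noise spec's
#' times, and adds seeded Gaussian noise per replicate (clipped at zero).
#'
#' @param model a `metabolic_model`.
#' @param med a `medium`.
#' @param regulations,cc,... passed to [simulate_dfba()].
#' @param noise a [noise_spec()].
#' @param variables sampled variables; default biomass plus every tracked
#'   metabolite that changes during the run.
#' @return list (class `synthetic_experiment`) with `series` (a
#'   [culture_series()]) and `truth` (the noise-free `dfba_trajectory`).
#' @export
synthetic_experiment <- function(model, med, regulations = list(),
                                 cc = carrying_capacity_params(T_GLM = 1),
                                 noise = noise_spec(), variables = NULL, ...) {
  truth <- simulate_dfba(model, med, regulations = regulations, cc = cc, ...)
  if (is.null(variables)) {
    moving <- colnames(truth$conc)[apply(truth$conc, 2,
                                         function(z) diff(range(z)) > 1e-9)]
    variables <- c("biomass", moving)
  }
  samp <- trajectory_at(truth, noise$times, variables)
  sdv <- if (length(noise$sd) == 1L)
    setNames(rep(noise$sd, length(variables)), variables) else noise$sd
  set.seed(noise$seed)
  rows <- list()
  for (rep_i in seq_len(noise$replicates)) {
    for (v in seq_along(variables)) {
      truevals <- samp[, v]
      s <- if (noise$relative) sdv[[variables[v]]] * abs(truevals)
           else rep(sdv[[variables[v]]], length(truevals))
      vals <- pmax(truevals + rnorm(length(truevals), 0, s), 0)
      rows[[length(rows) + 1]] <- data.frame(
        time = noise$times, medium = med$name, replicate = rep_i,
        variable = variables[v], value = vals)
    }
  }
  series <- culture_series(do.call(rbind, rows))
  structure(list(series = series, truth = truth, variables = variables,
                 noise = noise),
            class = "synthetic_experiment")
}

#' Synthetic protease composition set
#'
#' Generates `n` protease-like residue compositions (chain lengths drawn
#' around a typical bacterial extracellular protease, residue frequencies
#' from a generic bacterial proteome profile). A clearly synthetic stand-in
#' for an organism's real nutrition-protease sequences.
#'
#' @param n number of proteases.
#' @param mean_length mean chain length (residues).
#' @param seed integer seed.
#' @return list of `protein_composition` objects.
#' @export
synthetic_proteases <- function(n = 31, mean_length = 450, seed = 1) {
  freq <- c(ala = 0.089, arg = 0.049, asn = 0.041, asp = 0.054, cys = 0.012,
            gln = 0.038, glu = 0.061, gly = 0.074, his = 0.021, ile = 0.058,
            leu = 0.095, lys = 0.052, met = 0.022, phe = 0.040, pro = 0.042,
            ser = 0.059, thr = 0.054, trp = 0.013, tyr = 0.032, val = 0.069)
  freq <- freq / sum(freq)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    len <- max(100, round(rnorm(1, mean_length, 80)))
    cts <- as.numeric(stats::rmultinom(1, len, freq[AA_TABLE$aa]))
    protein_composition(sprintf("synthetic_protease_%02d", i),
                        setNames(cts, AA_TABLE$aa))
  })
}

#' Write a ready-to-run fixture workspace
#'
#' Writes the toy model (JSON and SBML), the three media (YAML), and
#' copies of the composition and cost CSVs into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param config a [toy_config()].
#' @return invisibly, the paths written.
#' @export
make_fixture_workspace <- function(dir, config = toy_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- make_toy_model(config)
  paths <- c(file.path(dir, "toy_model.json"), file.path(dir, "toy_model.xml"))
  save_model(model, paths[1]); save_model(model, paths[2])
  media <- make_media()
  for (nm in names(media)) {
    p <- file.path(dir, paste0("medium_", nm, ".yaml"))
    write_medium(media[[nm]], p)
    paths <- c(paths, p)
  }
  for (f in c("protein_compositions_synthetic.csv",
              "aa_atp_cost_synthetic.csv")) {
    p <- file.path(dir, f)
    file.copy(system.file("extdata", f, package = "proteodfba"), p,
              overwrite = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
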