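# Toy network generator, media fixtures and synthetic culture experiments.

test_that("the media carry the study's printed concentrations", {
  media <- make_media()
  gl <- function(med, sp) unname(med$concentrations[sp])
  expect_equal(gl(media$GLM, "glc_e"), 5)
  expect_equal(gl(media$P2, "glc_e"), 5)
  expect_equal(gl(media$P20, "glc_e"), 5)
  expect_equal(vapply(media, gl, 0, "lcts_e"),
               c(GLM = 0.16, P2 = 0.19, P20 = 0.36))
  # total protein = baseline pool + whey split
  tot <- vapply(media, function(m)
    gl(m, "glm_protein_e") + gl(m, "whey_protein_e"), 0)
  expect_equal(tot, c(GLM = 7.28, P2 = 8.51, P20 = 21.87))
  expect_equal(gl(media$GLM, "whey_protein_e"), 0)
  expect_true(all(vapply(media, gl, 0, "pyr_e") == 1))
  expect_true(all(vapply(media, gl, 0, "succ_e") == 1))
  # everything converts to mM
  expect_true(all(is.finite(medium_mM(media$P20))))
})

test_that("the toy model is deterministic and structurally sound", {
  m1 <- make_toy_model()
  m2 <- make_toy_model()
  expect_identical(m1$S, m2$S)
  expect_identical(m1$rxns, m2$rxns)
  # every amino acid has an extracellular species and exchange
  expect_true(all(paste0(amino_acids(), "_e") %in% names(m1$exchanges)))
  expect_true(all(c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c") %in% m1$mets$id))
  # a config with no carbon source is rejected
  expect_error(make_toy_model(toy_config(glucose = FALSE, lactose = FALSE,
                                         pyruvate = FALSE,
                                         catabolism_aas = character(0))),
               "carbon source")
})

test_that("the toy model grows on glucose and faster with amino acids", {
  m <- make_toy_model(small_toy_config())
  glc_only <- medium("glc", c(glc_e = 20, nh4_e = 20), "mM")
  mu_glc <- fba(apply_medium(m, glc_only))$objective
  expect_gt(mu_glc, 0.05)
  with_aa <- medium("glc_aa", c(glc_e = 20, nh4_e = 20, glu_e = 5,
                                ala_e = 5, leu_e = 5), "mM")
  mu_aa <- fba(apply_medium(m, with_aa))$objective
  expect_gt(mu_aa, mu_glc * 1.05)
  # disabling the glucose subsystem starves a glucose-only culture
  m_noglc <- make_toy_model(toy_config(amino_acids = c("ala", "glu"),
                                       glucose = FALSE, lactose = FALSE,
                                       pyruvate = FALSE))
  sol <- fba(apply_medium(m_noglc, glc_only))
  expect_true(sol$status != "optimal" || sol$objective <= 1e-9)
})

test_that("the toy model round-trips through SBML", {
  m <- make_toy_model(small_toy_config())
  p <- withr::local_tempfile(fileext = ".xml")
  save_model(m, p)
  back <- load_model(p)
  expect_equal(back$S[rownames(m$S), colnames(m$S)], m$S, tolerance = 1e-12)
  expect_equal(fba(suppressWarnings(apply_medium(back, make_media()$GLM)))$objective,
               fba(suppressWarnings(apply_medium(m, make_media()$GLM)))$objective,
               tolerance = 1e-9)
})

test_that("secreted fermentation products appear during simulated growth", {
  setup <- standard_toy_setup(small_toy_config())
  tr <- simulate_dfba(setup$model, setup$media$GLM,
                      regulations = setup$regulations, cc = setup$cc,
                      dt = 0.5, horizon = 12, B0 = od_to_biomass(0.02))
  last <- nrow(tr$conc)
  expect_gt(tr$conc[last, "ac_e"], 1)
  expect_gt(final_biomass(tr), 10 * tr$biomass[1])
  # glucose is consumed, protein pool shrinks
  expect_lt(tr$conc[last, "glc_e"], tr$conc[1, "glc_e"])
  expect_lt(tr$conc[last, "glm_protein_e"], tr$conc[1, "glm_protein_e"])
})

test_that("zero-noise experiments sample the trajectory exactly", {
  setup <- standard_toy_setup(small_toy_config())
  exp0 <- synthetic_experiment(setup$model, setup$media$GLM,
                               regulations = setup$regulations,
                               cc = setup$cc,
                               noise = noise_spec(sd = 0, replicates = 2),
                               dt = 0.5, horizon = 24)
  truth_at <- trajectory_at(exp0$truth, c(0, 6, 12, 24), "biomass")
  got <- exp0$series[exp0$series$variable == "biomass" &
                       exp0$series$replicate == 1, ]
  expect_equal(got$value[order(got$time)], as.numeric(truth_at),
               tolerance = 1e-12)
  # replicates are identical when noise-free
  got2 <- exp0$series[exp0$series$variable == "biomass" &
                        exp0$series$replicate == 2, ]
  expect_equal(got$value, got2$value)
})

test_that("experiment noise is seeded, reproducible and correctly scaled", {
  setup <- standard_toy_setup(small_toy_config())
  run <- function(seed, reps = 3)
    synthetic_experiment(setup$model, setup$media$GLM,
                         regulations = setup$regulations, cc = setup$cc,
                         noise = noise_spec(sd = 0.05, replicates = reps,
                                            seed = seed),
                         dt = 0.5, horizon = 24)
  a <- run(11); b <- run(11); c3 <- run(12)
  expect_identical(a$series$value, b$series$value)
  expect_false(identical(a$series$value, c3$series$value))
  # law of large numbers: with 200 replicates the empirical SD of a
  # positive observable approaches 5 % relative
  big <- run(5, reps = 200)
  bio24 <- big$series$value[big$series$variable == "biomass" &
                              big$series$time == 24]
  truth24 <- unname(trajectory_at(big$truth, 24, "biomass")[1])
  expect_equal(sd(bio24) / (0.05 * truth24), 1, tolerance = 0.15)
})

test_that("an injected medium effect survives the full estimation pipeline", {
  setup <- standard_toy_setup(small_toy_config())
  series <- NULL
  for (nm in c("GLM", "P2", "P20")) {
    cc <- setup$cc
    cc$WP_initial <- unname(setup$media[[nm]]$concentrations["whey_protein_e"])
    ex <- synthetic_experiment(setup$model, setup$media[[nm]],
                               regulations = setup$regulations, cc = cc,
                               noise = noise_spec(sd = 0.03, seed = 3),
                               dt = 0.5, horizon = 24)
    series <- rbind(series, ex$series)
  }
  rates <- rate_table(culture_series(series))
  est <- fit_effects(rates[rates$metabolite %in%
                             c("ac_e", "glc_e", "gly_e", "ppa_e"), ])
  # the whey-supplemented media push proteolysis products: the P20
  # substrate effect on at least one fermentation variable is flagged
  p20 <- est[est$term == "mediumP20" & est$type == "substrate", ]
  expect_true(any(p20$significant))
})

test_that("synthetic proteases are reproducible protease-sized compositions", {
  ps <- synthetic_proteases(n = 31, seed = 9)
  expect_length(ps, 31)
  lens <- vapply(ps, function(p) sum(p$counts), 0)
  expect_true(all(lens >= 100))
  expect_equal(mean(lens), 450, tolerance = 0.1)
  ps2 <- synthetic_proteases(n = 31, seed = 9)
  expect_identical(vapply(ps, function(p) p$molar_mass, 0),
                   vapply(ps2, function(p) p$molar_mass, 0))
})

test_that("fixture workspaces are complete and reloadable", {
  dir <- withr::local_tempdir()
  paths <- make_fixture_workspace(dir, toy_config())
  expect_true(all(file.exists(file.path(
    dir, c("toy_model.json", "toy_model.xml", "medium_GLM.yaml",
           "medium_P2.yaml", "medium_P20.yaml",
           "protein_compositions_synthetic.csv",
           "aa_atp_cost_synthetic.csv")))))
  m <- load_model(file.path(dir, "toy_model.json"))
  med <- read_medium(file.path(dir, "medium_P20.yaml"))
  expect_equal(unname(med$concentrations["whey_protein_e"]), 21.87 - 7.28)
  expect_s3_class(suppressWarnings(apply_medium(m, med)), "metabolic_model")
})
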