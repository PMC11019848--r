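# The regulated dFBA engine.

batch_sim <- function(dt, horizon = 6, m0 = 10, uptake = 10, B0 = 0.01) {
  m <- make_chain_model(yield = 0.1, uptake = uptake)
  med <- medium("batch", c(glc_e = m0), "mM")
  cc <- carrying_capacity_params(T_GLM = 1e6, Hillcoef = 2, K = 1, lambda = 1)
  simulate_dfba(m, med, cc = cc, dt = dt, horizon = horizon, B0 = B0,
                uptake_bound = uptake)
}

test_that("unregulated batch growth matches the closed-form solution", {
  # constant uptake V at yield Y: mu = Y V; B = B0 e^{mu t},
  # m = m0 - (V B0 / mu)(e^{mu t} - 1)
  mu <- 1; B0 <- 0.01; m0 <- 10; V <- 10
  tr <- batch_sim(dt = 0.01)
  T0 <- 4
  B_ex <- B0 * exp(mu * T0)
  m_ex <- m0 - V * B0 / mu * (exp(mu * T0) - 1)
  expect_equal(approx(tr$time, tr$biomass, T0)$y, B_ex, tolerance = 0.02)
  expect_equal(approx(tr$time, tr$conc[, "glc_e"], T0)$y, m_ex,
               tolerance = 0.02)
  # depletion time against the closed form, within 2 %
  thr <- 0.1
  t_dep <- tr$time[min(which(tr$conc[, "glc_e"] < thr))]
  t_ex <- log(1 + mu * (m0 - thr) / (V * B0)) / mu
  expect_equal(t_dep, t_ex, tolerance = 0.02)
})

test_that("halving the step halves the concentration error (first order)", {
  mu <- 1; B0 <- 0.01; m0 <- 10; V <- 10
  m_ex <- m0 - V * B0 / mu * (exp(mu * 4) - 1)
  err <- vapply(c(0.02, 0.01), function(dt) {
    tr <- batch_sim(dt = dt)
    abs(approx(tr$time, tr$conc[, "glc_e"], 4)$y - m_ex)
  }, 0)
  expect_gt(err[1] / err[2], 1.6)
  expect_lt(err[1] / err[2], 2.6)
})

test_that("glucose-to-biomass bookkeeping closes to within 1 %", {
  tr <- batch_sim(dt = 0.005, horizon = 4)
  produced <- tr$biomass[length(tr$biomass)] - tr$biomass[1]
  consumed <- unname(tr$conc[1, "glc_e"] - tr$conc[nrow(tr$conc), "glc_e"])
  expect_equal(produced, 0.1 * consumed, tolerance = 0.01)
})

test_that("an exhausted medium gives flat biomass and flat concentrations", {
  m <- make_toy_model(small_toy_config())
  med <- medium("blank", c(glc_e = 0), "mM")
  tr <- simulate_dfba(m, med, dt = 0.5, horizon = 4, B0 = 0.02)
  expect_equal(diff(range(tr$biomass)), 0, tolerance = 1e-12)
  expect_true(all(apply(tr$conc, 2, function(z) diff(range(z)) == 0)))
})

test_that("simulation is deterministic and keeps constant steps plus a partial tail", {
  m <- make_toy_model(small_toy_config())
  med <- make_media()$GLM
  regs <- Filter(function(r) r$reaction %in% m$rxns$id, default_regulations())
  args <- list(m, med, regulations = regs,
               cc = carrying_capacity_params(T_GLM = 0.9),
               dt = 0.4, horizon = 1.9, B0 = 0.01)
  t1 <- suppressWarnings(do.call(simulate_dfba, args))
  t2 <- suppressWarnings(do.call(simulate_dfba, args))
  expect_identical(t1$biomass, t2$biomass)
  expect_identical(t1$conc, t2$conc)
  steps <- diff(t1$time)
  expect_true(all(abs(steps[-length(steps)] - 0.4) < 1e-12))
  expect_lt(steps[length(steps)], 0.4)
  expect_true(all(diff(t1$time) > 0))
})

test_that("positivity holds across randomized conditions where the naive scheme fails", {
  n_draws <- 40
  set.seed(42)
  neg_seen <- FALSE
  for (i in seq_len(n_draws)) {
    m0 <- runif(1, 0.05, 5)
    uptake <- runif(1, 2, 15)
    dt <- runif(1, 0.05, 1)
    B0 <- runif(1, 0.005, 0.5)
    model <- make_chain_model(yield = runif(1, 0.05, 0.3), uptake = uptake)
    med <- medium("draw", c(glc_e = m0), "mM")
    cc <- carrying_capacity_params(T_GLM = runif(1, 0.5, 5),
                                   Hillcoef = runif(1, 1, 3),
                                   K = runif(1, 0.5, 4),
                                   lambda = runif(1, 0.3, 2),
                                   WP_initial = runif(1, 0, 20))
    tr <- simulate_dfba(model, med, cc = cc, dt = dt, horizon = 3, B0 = B0,
                        uptake_bound = uptake)
    expect_true(all(tr$conc >= 0))
    expect_true(all(tr$biomass > 0))
    naive <- simulate_dfba(model, med, cc = cc, dt = dt, horizon = 3,
                           B0 = B0, uptake_bound = uptake,
                           scheme = "naive_explicit")
    if (any(naive$conc < 0)) neg_seen <- TRUE
  }
  # the forward-Euler comparator with static bounds does go negative
  expect_true(neg_seen)
})

test_that("amino-acid limitation scan ranks the sole nitrogen source first", {
  cfg <- small_toy_config(aas = c("ala", "leu"))
  model <- make_toy_model(cfg)
  # alanine is the only nitrogen/precursor source: no ammonium supplied
  med <- medium("glc_ala", c(glc_e = 10, ala_e = 5), "mM")
  scan <- aa_limitation_scan(model, med, depth = "single",
                             cc = carrying_capacity_params(T_GLM = 2),
                             dt = 0.5, horizon = 6, B0 = 0.01)
  expect_identical(scan$set[1], "ala")
  expect_gt(scan$delta[1], 0)
  # leucine is absent from the medium: closing it changes nothing
  expect_equal(scan$delta[scan$set == "leu"], 0, tolerance = 1e-9)
})

test_that("pair scans enumerate all unordered pairs", {
  cfg <- small_toy_config(aas = c("ala", "leu", "glu", "asp"))
  model <- make_toy_model(cfg)
  med <- medium("glc", c(glc_e = 2, nh4_e = 5), "mM")
  scan <- aa_limitation_scan(model, med, depth = "pair",
                             cc = carrying_capacity_params(T_GLM = 2),
                             dt = 1, horizon = 2, B0 = 0.01)
  expect_equal(nrow(scan), choose(4, 2))
  expect_true(all(grepl("\\+", scan$set)))
})

test_that("module knockouts span all subsets and gate growth on protein", {
  cfg <- small_toy_config()
  model <- make_toy_model(cfg)
  modules <- list(
    glm = build_proteolytic_module(
      restrict_composition(glm_protein_composition(), cfg$amino_acids),
      chi = 5),
    whey = build_proteolytic_module(
      restrict_composition(whey_composition(), cfg$amino_acids), chi = 5))
  med <- medium("protein_only", c(whey_protein_e = 0.5, glm_protein_e = 0.2),
                "mM")
  res <- suppressWarnings(module_knockout_compare(
    model, med, modules,
    cc = carrying_capacity_params(T_GLM = 2), dt = 0.5, horizon = 8,
    B0 = 0.01))
  expect_setequal(res$summary$subset, c("none", "glm", "whey", "glm+whey"))
  # protein is the sole carbon source: without modules the culture is inert
  none <- res$trajectories[["none"]]
  expect_equal(diff(range(none$biomass)), 0, tolerance = 1e-12)
  both <- res$trajectories[["glm+whey"]]
  expect_gt(final_biomass(both), final_biomass(none))
  # amino-acid catabolism feeds acetate only when proteolysis runs
  expect_gt(both$conc[nrow(both$conc), "ac_e"],
            none$conc[nrow(none$conc), "ac_e"] + 0.1)
})

test_that("a mid-run positivity breach would abort with a diagnostic", {
  # direct check of the guard: the implicit scheme cannot produce one, so
  # drive the metabolite step with an impossible state instead
  expect_error(metabolite_step(-0.1, -1, 1, 0.1), ">= 0")
})
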