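# Per-capita flux estimation, the substrate-effect screen, the calibration
# objective and goodness of fit.

make_series <- function(times, biomass, mets, medium = "GLM", replicate = 1) {
  rows <- data.frame(time = times, medium = medium, replicate = replicate,
                     variable = "biomass", value = biomass)
  for (v in names(mets))
    rows <- rbind(rows, data.frame(time = times, medium = medium,
                                   replicate = replicate, variable = v,
                                   value = mets[[v]]))
  culture_series(rows)
}

test_that("od_to_biomass applies the 0.43 conversion linearly", {
  expect_equal(od_to_biomass(1.0), 0.43)
  expect_equal(od_to_biomass(0), 0)
  expect_equal(od_to_biomass(2.0), 0.86)
  expect_equal(od_to_biomass(1, coefficient = 0.5), 0.5)
  expect_error(od_to_biomass(-0.1), ">= 0")
})

test_that("rate_table reproduces hand-computed normalized rates", {
  s <- make_series(times = c(0, 2, 8),
                   biomass = c(1, 1, 1.5),
                   mets = list(met_a = c(1, 2, 2), met_b = c(4, 4, 1)))
  # intervals recomputed by hand from r = dm / (dt * mean(b))
  rt <- rate_table(s)
  get <- function(met, iv) rt$rate[rt$metabolite == met & rt$interval == iv]
  expect_equal(get("met_a", "t0t2"), (2 - 1) / (2 * 1))          # 0.5
  expect_equal(get("met_a", "t2t8"), 0)
  expect_equal(get("met_b", "t2t8"), (1 - 4) / (6 * 1.25))       # -0.4
  # sign convention: negative = consumption
  expect_lt(get("met_b", "t2t8"), 0)
})

test_that("rate_table is antisymmetric under time reversal", {
  set.seed(7)
  times <- c(0, 6, 12, 18)    # uniform spacing so reversal pairs intervals
  b <- runif(4, 0.2, 1)
  m <- runif(4, 0, 5)
  fwd <- rate_table(make_series(times, b, list(x = m)))
  rev_ <- rate_table(make_series(times, rev(b), list(x = rev(m))))
  expect_equal(sort(rev_$rate), sort(-fwd$rate), tolerance = 1e-12)
})

test_that("rate_table rejects zero bacterial load", {
  s <- make_series(c(0, 6), biomass = c(0, 0), mets = list(x = c(1, 2)))
  expect_error(rate_table(s), "zero bacterial load")
})

simulate_rates <- function(seed, n_mets = 8, effect_met = NULL,
                           effect = 0, sigma = 0.1, reps = 3) {
  set.seed(seed)
  intervals <- c("t0t6", "t6t12", "t12t24")
  media <- c("GLM", "P2", "P20")
  grid <- expand.grid(metabolite = paste0("m", seq_len(n_mets)),
                      interval = intervals, medium = media,
                      replicate = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  R_t <- setNames(rnorm(3, 0, 1), intervals)
  grid$rate <- R_t[grid$interval] + rnorm(nrow(grid), 0, sigma)
  if (!is.null(effect_met))
    grid$rate <- grid$rate +
      ifelse(grid$metabolite == effect_met & grid$medium == "P20", effect, 0)
  class(grid) <- c("rate_table", "data.frame")
  grid
}

test_that("fit_effects recovers an injected substrate effect", {
  rates <- simulate_rates(1, effect_met = "m1", effect = 1.0, sigma = 0.01)
  est <- fit_effects(rates, fdr = 0.05)
  row <- est[est$metabolite == "m1" & est$term == "mediumP20", ]
  expect_lt(abs(row$estimate - 1.0), 3 * row$se)
  expect_true(row$significant)
  # reference medium effect is exactly zero by construction
  glm_rows <- est[est$term == "mediumGLM", ]
  expect_true(all(glm_rows$estimate == 0))
  # q-values never undercut p-values
  ok <- !is.na(est$q)
  expect_true(all(est$q[ok] >= est$p[ok] - 1e-12))
})

test_that("identical rates produce zero effects and no flags", {
  rates <- simulate_rates(2, sigma = 0)
  rates$rate <- 1
  est <- suppressWarnings(fit_effects(rates))
  sub <- est[est$type == "substrate", ]
  expect_true(all(abs(sub$estimate) < 1e-12))
  expect_false(any(est$significant))
})

test_that("BH q-values equal an independent step-up implementation", {
  rates <- simulate_rates(3, effect_met = "m2", effect = 0.3, sigma = 0.1)
  est <- fit_effects(rates)
  tested <- est[est$type == "substrate" & !is.na(est$p), ]
  p <- tested$p
  # brute-force BH: q_(i) = min_{j >= i} m p_(j) / j, in the sorted order
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_manual <- numeric(m); q_manual[o] <- pmin(q_sorted, 1)
  expect_equal(tested$q, q_manual, tolerance = 1e-12)
})

test_that("missing design cells raise an explicit error", {
  rates <- simulate_rates(4)
  rates <- rates[!(rates$metabolite == "m1" & rates$interval == "t6t12" &
                     rates$medium == "P2"), ]
  expect_error(fit_effects(rates), "t6t12.*P2|P2.*t6t12")
})

# a tiny closed-form simulator standing in for dFBA in objective tests
line_simulator <- function(theta, med) {
  t <- c(0, 6, 12, 24)
  cbind(a = theta[1] * t, b = theta[2] + 0 * t)
}
line_problem <- function(sd_a = 1, sd_b = 1) {
  t <- c(0, 6, 12, 24)
  calibration_problem(
    data.frame(name = c("slope", "level"), lower = c(0, 0),
               upper = c(10, 10), start = c(1, 1)),
    c("a", "b"),
    list(GLM = list(times = t,
                    mean = cbind(a = 2 * t, b = rep(3, 4)),
                    sd = cbind(a = rep(sd_a, 4), b = rep(sd_b, 4)))))
}

test_that("objective is an exactly recomputable weighted sum of squares", {
  prob <- line_problem()
  theta <- c(1.5, 2)
  f <- objective(theta, prob, line_simulator)
  # independent straight-line recomputation
  t <- c(0, 6, 12, 24)
  ra <- (1.5 * t - 2 * t) / sqrt(sum(rep(1, 4)^2))
  rb <- (2 - 3) / sqrt(sum(rep(1, 4)^2))
  expect_equal(f, sum(ra^2) + sum(rep(rb, 4)^2), tolerance = 1e-12)
  # zero at the truth
  expect_lt(objective(c(2, 3), prob, line_simulator), 1e-12)
  # doubling every SD quarters the objective
  expect_equal(objective(theta, line_problem(2, 2), line_simulator), f / 4,
               tolerance = 1e-12)
  # simulator failure becomes an optimizer-safe sentinel
  boom <- function(theta, med) stop("nope")
  expect_identical(objective(theta, prob, boom), Inf)
})

test_that("calibration recovers the truth and respects its budget", {
  prob <- line_problem()
  fit <- dfba_calibrate(prob, line_simulator, seed = 1)
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lte(fit$n_evals, prob$max_evals)
  # best-so-far trace is non-increasing
  expect_true(all(diff(fit$trace$best[!is.na(fit$trace$best)]) <= 1e-12))
  # budget of one evaluation returns the start point
  fit1 <- dfba_calibrate(prob, line_simulator, max_evals = 1, seed = 1)
  expect_equal(unname(coef(fit1)), c(1, 1))
  expect_false(fit1$converged)
  # the model-object surface behaves
  expect_s3_class(summary(fit), "summary.dfba_fit")
  expect_equal(dim(predict(fit, "GLM")), c(4L, 2L))
  expect_equal(sum(residuals(fit)^2), fit$objective_value, tolerance = 1e-9)
})

test_that("goodness_of_fit matches hand-computed R2 and edge cases", {
  expect_equal(goodness_of_fit(c(1, 2, 4), c(1, 2, 3))$r_squared, 0.5)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 3))$r_squared, 1)
  expect_equal(goodness_of_fit(rep(2, 3), c(1, 2, 3))$r_squared, 0)
  expect_error(goodness_of_fit(c(1, 2), c(5, 5)), "zero variance")
  g <- goodness_of_fit(c(1.05, 2.5), c(1, 2))
  expect_equal(g$relative_residuals, c(0.05, 0.25))
  expect_equal(g$frac_within_band, 0.5)
})
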