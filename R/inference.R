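# Per-capita flux estimation from sparse culture time series, and the
# fixed-effects screen for substrate-dependent production rates.
#
# For a metabolite m measured at consecutive times t0 < t1 with bacterial
# load b, the biomass-normalised production rate over the interval is
#     r = (m(t1) - m(t0)) / ((t1 - t0) * (b(t0) + b(t1)) / 2)
# (mM per gDW/L per h; positive = production, negative = consumption).
# Rates are then modelled per metabolite as
#     r ~ R_interval + D_medium + eps,  D_baseline = 0,
# and substrate effects are screened at a Benjamini-Hochberg FDR.

#' Convert optical density to biomass
#' @param od optical density (600 nm), >= 0.
#' @param coefficient OD-to-gDW/L conversion (default 0.43).
#' @return biomass in gDW/L.
#' @export
od_to_biomass <- function(od, coefficient = 0.43) {
  if (any(od < 0)) stop("OD must be >= 0")
  coefficient * od
}

#' Culture time series container
#'
#' @param data data.frame with columns `time`, `medium`, `replicate`,
#'   `variable`, `value` (long format); the biomass variable must be named
#'   `"biomass"` (gDW/L).
#' @return the validated data.frame with class `culture_series`.
#' @export
culture_series <- function(data) {
  need <- c("time", "medium", "replicate", "variable", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"biomass" %in% data$variable)
    stop("series must contain a 'biomass' variable")
  structure(as.data.frame(data), class = c("culture_series", "data.frame"))
}

#' Biomass-normalised production rates per interval
#'
#' @param series a [culture_series()] (or compatible data.frame).
#' @return data.frame (class `rate_table`) with columns `metabolite`,
#'   `interval` (e.g. `"t0t6"`), `medium`, `replicate`, `rate`.
#' @export
rate_table <- function(series) {
  if (!inherits(series, "culture_series")) series <- culture_series(series)
  out <- list()
  for (med in unique(series$medium)) {
    for (rep in unique(series$replicate[series$medium == med])) {
      sub <- series[series$medium == med & series$replicate == rep, ]
      b <- sub[sub$variable == "biomass", ]
      b <- b[order(b$time), ]
      if (nrow(b) < 2) stop("need >= 2 time points per (medium, replicate)")
      for (met in setdiff(unique(sub$variable), "biomass")) {
        mm <- sub[sub$variable == met, ]
        mm <- mm[order(mm$time), ]
        mm <- mm[mm$time %in% b$time, ]
        for (k in seq_len(nrow(mm) - 1)) {
          t0 <- mm$time[k]; t1 <- mm$time[k + 1]
          bmean <- (b$value[b$time == t0] + b$value[b$time == t1]) / 2
          if (bmean <= 0)
            stop("zero bacterial load over interval ", t0, "-", t1,
                 " (", med, ", replicate ", rep, ")")
          out[[length(out) + 1]] <- data.frame(
            metabolite = met,
            interval = sprintf("t%gt%g", t0, t1),
            medium = med, replicate = rep,
            rate = (mm$value[k + 1] - mm$value[k]) / ((t1 - t0) * bmean))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rate_table", "data.frame")
  res
}

#' Fixed-effects screen for substrate-dependent production rates
#'
#' Fits, per metabolite, `rate ~ interval + medium` with the reference
#' medium's effect fixed at zero, tests each non-reference medium
#' coefficient (two-sided t test) and applies Benjamini-Hochberg correction
#' across the substrate-effect family.
#'
#' @param rates a [rate_table()].
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @param reference reference medium level (default `"GLM"` if present).
#' @param scope `"pooled"` corrects across all metabolites jointly;
#'   `"per_metabolite"` corrects within each metabolite.
#' @return data.frame (class `effect_estimates`) with one row per
#'   (metabolite, term): estimate, standard error, p, BH-adjusted q,
#'   significance flag; substrate rows carry `type = "substrate"`.
#'   Residual variances are in `attr(, "sigma2")`.
#' @export
fit_effects <- function(rates, fdr = 0.05, reference = NULL,
                        scope = c("pooled", "per_metabolite")) {
  scope <- match.arg(scope)
  if (is.null(reference))
    reference <- if ("GLM" %in% rates$medium) "GLM" else
      sort(unique(rates$medium))[1]
  if (!reference %in% rates$medium) stop("reference medium not in data")
  rows <- list(); sigma2 <- c()
  for (met in unique(rates$metabolite)) {
    d <- rates[rates$metabolite == met, ]
    cells <- table(d$interval, d$medium)
    if (any(cells == 0)) {
      missing <- which(cells == 0, arr.ind = TRUE)
      stop("missing (interval, medium) cell(s) for '", met, "': ",
           paste(sprintf("(%s, %s)", rownames(cells)[missing[, 1]],
                         colnames(cells)[missing[, 2]]), collapse = ", "))
    }
    d$medium <- stats::relevel(factor(d$medium), ref = reference)
    d$interval <- factor(d$interval)
    fit <- lm(rate ~ interval + medium, data = d)
    sm <- summary(fit)$coefficients
    sigma2[met] <- summary(fit)$sigma^2
    terms <- rownames(sm)
    med_terms <- grep("^medium", terms)
    rows[[met]] <- data.frame(
      metabolite = met,
      term = c(terms, paste0("medium", reference)),
      type = c(ifelse(seq_along(terms) %in% med_terms, "substrate", "interval"),
               "substrate"),
      estimate = c(sm[, 1], 0),
      se = c(sm[, 2], NA),
      p = c(ifelse(seq_along(terms) %in% med_terms, sm[, 4], NA), NA))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- NA_real_
  test <- res$type == "substrate" & !is.na(res$p)
  if (scope == "pooled") {
    res$q[test] <- p.adjust(res$p[test], method = "BH")
  } else {
    for (met in unique(res$metabolite)) {
      i <- test & res$metabolite == met
      res$q[i] <- p.adjust(res$p[i], method = "BH")
    }
  }
  res$significant <- !is.na(res$q) & res$q < fdr
  attr(res, "sigma2") <- sigma2
  attr(res, "fdr") <- fdr
  attr(res, "reference") <- reference
  class(res) <- c("effect_estimates", "data.frame")
  res
}

#' Pooled coefficient of determination and relative residuals
#'
#' @param predictions,observations equal-length numeric vectors, pooled
#'   over observables and time points.
#' @param log compute R^2 on log10 scale (positive pairs only).
#' @param band relative-error band reported as a coverage fraction
#'   (default 0.10).
#' @return list with `r_squared`, `relative_residuals`
#'   (`(pred - obs)/obs`), and `frac_within_band`.
#' @export
goodness_of_fit <- function(predictions, observations, log = FALSE,
                            band = 0.10) {
  if (length(predictions) != length(observations))
    stop("predictions and observations must pair up")
  keep <- is.finite(predictions) & is.finite(observations)
  p <- predictions[keep]; o <- observations[keep]
  rel <- (p - o) / ifelse(o == 0, NA, o)
  if (log) {
    pos <- p > 0 & o > 0
    p <- log10(p[pos]); o <- log10(o[pos])
  }
  if (var(o) == 0) stop("observations have zero variance; R^2 undefined")
  r2 <- 1 - sum((p - o)^2) / sum((o - mean(o))^2)
  list(r_squared = r2,
       relative_residuals = rel,
       frac_within_band = mean(abs(rel) <= band, na.rm = TRUE))
}
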