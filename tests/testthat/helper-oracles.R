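# Shared fixtures and independent oracles.

# Brute-force FBA oracle for small models (<= ~10 reactions): enumerate the
# vertices of {S v = 0, lb <= v <= ub} by fixing every choice of
# (n - rank(S)) variables at a bound and solving for the rest; return the
# best feasible objective. Completely independent of the simplex code.
vertex_enum_fba <- function(model, tol = 1e-8) {
  S <- unname(model$S)
  lb <- model$rxns$lb; ub <- model$rxns$ub
  obj <- as.numeric(model$rxns$id == model$objective)
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  rows <- qr(t(S))$pivot[seq_len(r)]    # independent rows of S
  Sr <- S[rows, , drop = FALSE]
  k <- n - r
  best <- -Inf; best_v <- NULL
  fixed_sets <- if (k == 0) list(integer(0)) else
    combn(n, k, simplify = FALSE)
  for (fx in fixed_sets) {
    free <- setdiff(seq_len(n), fx)
    A <- Sr[, free, drop = FALSE]
    if (length(free) != r || abs(det(A)) < 1e-12) next
    sides <- expand.grid(rep(list(c(1, 2)), length(fx)))
    if (k == 0) sides <- data.frame(row.names = 1)
    for (si in seq_len(nrow(sides))) {
      v <- numeric(n)
      if (k > 0)
        v[fx] <- ifelse(unlist(sides[si, ]) == 1, lb[fx], ub[fx])
      rhs <- -if (k > 0) Sr[, fx, drop = FALSE] %*% v[fx] else
        matrix(0, r, 1)
      v[free] <- solve(A, rhs)
      if (any(v < lb - tol) || any(v > ub + tol)) next
      if (max(abs(S %*% v)) > tol) next
      val <- sum(obj * v)
      if (val > best) { best <- val; best_v <- v }
    }
  }
  list(objective = best, v = best_v)
}

# small branched fixture: glucose -> intermediate -> biomass or byproduct,
# 7 reactions, used for oracle cross-checks
make_branched_model <- function(uptake = 8) {
  mets <- c("glc_e", "a_c", "b_e")
  rids <- c("EX_glc_e", "GLCt", "A2BIO", "A2B", "EX_b_e")
  S <- matrix(0, 3, 5, dimnames = list(mets, rids))
  S["glc_e", "EX_glc_e"] <- -1
  S["glc_e", "GLCt"] <- -1; S["a_c", "GLCt"] <- 1
  S["a_c", "A2BIO"] <- -5
  S["a_c", "A2B"] <- -1; S["b_e", "A2B"] <- 1
  S["b_e", "EX_b_e"] <- -1
  metabolic_model("branched_toy", data.frame(id = mets),
                  data.frame(id = rids,
                             lb = c(-uptake, 0, 0, 0.5, 0),
                             ub = c(1000, 1000, 1000, 1000, 1000)),
                  S, objective = "A2BIO")
}

# reduced toy configuration used where simulation speed matters
small_toy_config <- function(aas = c("gly", "asn", "glu", "ala", "leu",
                                     "asp")) {
  toy_config(amino_acids = aas)
}

# restrict a composition to a reduced amino-acid set
restrict_composition <- function(comp, aas) {
  cts <- comp$counts
  cts[!names(cts) %in% aas] <- 0
  protein_composition(comp$name, cts)
}

expect_steady_state <- function(model, sol, tol = 1e-6) {
  expect_lt(max(abs(model$S %*% sol$fluxes)), tol)
}

`%|0|%` <- function(a, b) if (is.na(a)) b else a
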