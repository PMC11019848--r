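# Dense LP solver: bounded-variable two-phase primal simplex.
#
# solve_lp() optimises c'v subject to Aeq v = beq, optional Ale v <= ble,
# and lb <= v <= ub.  FBA LPs are small (tens to a few hundred columns)
# but highly degenerate; Bland's rule guarantees termination and a fresh
# LU factorisation of the basis every iteration keeps the pivoting
# numerically well behaved at these sizes.

LP_TOL <- 1e-9
LP_BIG <- 1e30

# minimise cvec'x s.t. A x = b, l <= x <= u (entries of l/u may be +-Inf)
simplex_bounded <- function(cvec, A, b, l, u, maximize = FALSE) {
  if (maximize) cvec <- -cvec
  m <- nrow(A); n <- ncol(A)
  l <- ifelse(is.finite(l), l, -LP_BIG)
  u <- ifelse(is.finite(u), u, LP_BIG)
  if (any(l > u + LP_TOL)) return(list(status = "infeasible"))

  # nonbasic start at the bound nearer zero
  x <- ifelse(abs(l) <= abs(u), l, u)
  at_upper0 <- abs(l) > abs(u)
  r <- b - as.numeric(A %*% x)
  sgn <- ifelse(r >= 0, 1, -1)

  # artificials: columns sgn_i * e_i, start basic at |r_i| >= 0
  Afull <- cbind(A, diag(sgn, m))
  lf <- c(l, rep(0, m))
  xf <- c(x, abs(r))
  at_upper <- c(at_upper0, rep(FALSE, m))
  basis <- n + seq_len(m)
  max_iter <- 100 * (n + m) + 1000

  run_phase <- function(cost, uf, basis, xf, at_upper) {
    for (it in seq_len(max_iter)) {
      Bmat <- Afull[, basis, drop = FALSE]
      y <- tryCatch(solve(t(Bmat), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(ncol(Afull)), basis)
      d <- cost[nonbasic] - as.numeric(y %*% Afull[, nonbasic, drop = FALSE])
      low <- !at_upper[nonbasic]
      enter_ok <- (low & d < -LP_TOL) | (!low & d > LP_TOL)
      if (!any(enter_ok))
        return(list(status = "optimal", basis = basis, xf = xf,
                    at_upper = at_upper))
      j <- min(nonbasic[enter_ok])                       # Bland's rule
      sig <- if (!at_upper[j]) 1 else -1                 # entering direction
      w <- tryCatch(solve(Bmat, Afull[, j]), error = function(e) NULL)
      if (is.null(w)) return(list(status = "singular"))
      wi <- sig * w                                      # x_B change: -wi * t
      xB <- xf[basis]
      t_dec <- ifelse(wi > LP_TOL, (xB - lf[basis]) / wi, Inf)
      t_inc <- ifelse(wi < -LP_TOL, (uf[basis] - xB) / (-wi), Inf)
      t_basic <- pmin(t_dec, t_inc)
      t_enter <- uf[j] - lf[j]
      tmax <- min(t_enter, suppressWarnings(min(t_basic)))
      if (tmax >= LP_BIG / 2) return(list(status = "unbounded"))
      tmax <- max(tmax, 0)
      cand <- which(t_basic <= tmax + LP_TOL)
      xf[basis] <- xB - wi * tmax
      xf[j] <- xf[j] + sig * tmax
      if (!length(cand)) {                # entering flips to its other bound
        at_upper[j] <- !at_upper[j]
        xf[j] <- if (at_upper[j]) uf[j] else lf[j]
      } else {
        leave <- cand[which.min(basis[cand])]            # Bland again
        lv <- basis[leave]
        to_upper <- t_inc[leave] < t_dec[leave]
        xf[lv] <- if (to_upper) uf[lv] else lf[lv]
        at_upper[lv] <- to_upper
        basis[leave] <- j
      }
    }
    list(status = "iteration_limit")
  }

  uf1 <- c(u, rep(LP_BIG, m))
  ph1 <- run_phase(c(rep(0, n), rep(1, m)), uf1, basis, xf, at_upper)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  if (sum(ph1$xf[n + seq_len(m)]) > 1e-6) return(list(status = "infeasible"))

  uf2 <- c(u, rep(0, m))                  # pin artificials at zero
  xf2 <- ph1$xf
  xf2[n + seq_len(m)] <- 0
  ph2 <- run_phase(c(cvec, rep(0, m)), uf2, ph1$basis, xf2, ph1$at_upper)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  xsol <- ph2$xf[seq_len(n)]
  obj <- sum(cvec * xsol)
  list(status = "optimal", x = xsol,
       objective = if (maximize) -obj else obj)
}

# Front-end used by fba(): maximise/minimise obj'v with equality rows and
# optional <= rows (turned into slacks).
solve_lp <- function(obj, Aeq, beq, lb, ub, maximize = TRUE,
                     Ale = NULL, ble = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) stop("lower bound exceeds upper bound")
  A <- Aeq; b <- beq; cvec <- obj
  l <- lb; u <- ub
  if (!is.null(Ale) && nrow(Ale)) {
    k <- nrow(Ale)
    A <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), k)),
               cbind(Ale, diag(k)))
    b <- c(beq, ble)
    cvec <- c(obj, rep(0, k))
    l <- c(lb, rep(0, k))
    u <- c(ub, rep(Inf, k))
  }
  res <- simplex_bounded(cvec, A, b, l, u, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  list(status = "optimal", objective = res$objective,
       solution = res$x[seq_len(n)])
}
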