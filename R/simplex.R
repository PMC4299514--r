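# Dense two-phase primal simplex for bounded-variable linear programs.
#
# Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
#
# Written for the small, often highly degenerate LPs that arise in
# flux-balance analysis (conserved cofactor pools make the stoichiometric
# matrix rank-deficient, and knockouts pin many variables to zero).
# Bland's rule guarantees termination under degeneracy; the basis system
# is re-solved from scratch every iteration, which is cheap at this scale
# (tens of variables) and avoids accumulated factorization error.

#' Solve a bounded-variable linear program
#'
#' Minimises or maximises the linear objective subject to \code{A x = b} and
#' \code{lb <= x <= ub} with a two-phase primal simplex using Bland's
#' anti-cycling rule. Infinite bounds are supported.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense equality-constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n); may contain \code{-Inf}/\code{Inf}.
#' @param maximize logical; maximise instead of minimise.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter iteration cap (error if exceeded; never hit in practice
#'   with Bland's rule on problems of this size).
#'
#' @return list with \code{status} (one of optimal, infeasible, unbounded),
#'   \code{x} (solution, NA unless optimal) and \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  m <- nrow(A)
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  if (m == 0L) {  # separable: optimum at bounds
    x <- ifelse(cc > 0, lb, ifelse(cc < 0, ub, ifelse(is.finite(lb), lb, 0)))
    if (any(!is.finite(x) & cc != 0))
      return(list(status = "unbounded", x = rep(NA_real_, n),
                  objective = if (maximize) Inf else -Inf))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }

  # Augment with one artificial per row; artificials carry phase-1 cost.
  ntot <- n + m
  Afull <- cbind(A, diag(1, m))
  lbf <- c(pmin(lb, ub), rep(0, m))
  ubf <- c(ub, rep(Inf, m))

  # Start: structural variables nonbasic at their finite bound nearest zero
  # (free variables sit at 0 and are treated as nonbasic "at value").
  x <- numeric(ntot)
  at_upper <- logical(ntot)
  start_val <- ifelse(is.finite(lbf[seq_len(n)]) & is.finite(ubf[seq_len(n)]),
                      ifelse(abs(lbf[seq_len(n)]) <= abs(ubf[seq_len(n)]), lbf[seq_len(n)], ubf[seq_len(n)]),
                      ifelse(is.finite(lbf[seq_len(n)]), lbf[seq_len(n)],
                             ifelse(is.finite(ubf[seq_len(n)]), ubf[seq_len(n)], 0)))
  x[seq_len(n)] <- start_val
  at_upper[seq_len(n)] <- is.finite(ubf[seq_len(n)]) & start_val == ubf[seq_len(n)] &
    !(is.finite(lbf[seq_len(n)]) & lbf[seq_len(n)] == ubf[seq_len(n)])

  r <- as.numeric(b - A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Afull[, n + seq_len(m)] <- diag(sgn, nrow = m, ncol = m)
  x[n + seq_len(m)] <- abs(r)
  basis <- n + seq_len(m)

  run_phase <- function(cphase, basis, x, at_upper, lbf, ubf, allow_enter) {
    for (it in seq_len(max_iter)) {
      Bmat <- Afull[, basis, drop = FALSE]
      xb <- tryCatch(solve(Bmat, b - Afull[, -basis, drop = FALSE] %*% x[-basis]),
                     error = function(e) NULL)
      if (is.null(xb)) return(list(ok = FALSE))
      x[basis] <- as.numeric(xb)
      y <- tryCatch(solve(t(Bmat), cphase[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(ok = FALSE))
      nb <- setdiff(seq_len(ntot), basis)
      nb <- nb[allow_enter[nb] & (ubf[nb] - lbf[nb]) > tol]
      if (length(nb) == 0L)
        return(list(ok = TRUE, basis = basis, x = x, at_upper = at_upper, optimal = TRUE))
      d <- cphase[nb] - as.numeric(crossprod(y, Afull[, nb, drop = FALSE]))
      elig <- (!at_upper[nb] & d < -tol) | (at_upper[nb] & d > tol)
      if (!any(elig))
        return(list(ok = TRUE, basis = basis, x = x, at_upper = at_upper, optimal = TRUE))
      j <- nb[elig][1L]                       # Bland: smallest index
      sigma <- if (at_upper[j]) -1 else 1     # direction of change of x_j
      w <- as.numeric(solve(Bmat, Afull[, j]))
      # step limits: entering variable's own opposite bound ...
      t_self <- if (is.finite(ubf[j]) && is.finite(lbf[j])) ubf[j] - lbf[j] else Inf
      # ... and each basic variable hitting a bound: x_B - sigma*t*w in [lb, ub]
      delta <- -sigma * w
      t_basic <- rep(Inf, length(basis))
      pos <- delta > tol
      negd <- delta < -tol
      t_basic[pos]  <- (ubf[basis[pos]] - x[basis[pos]]) / delta[pos]
      t_basic[negd] <- (lbf[basis[negd]] - x[basis[negd]]) / delta[negd]
      t_basic[t_basic < 0] <- 0
      tmax <- min(t_self, t_basic)
      if (!is.finite(tmax))
        return(list(ok = TRUE, basis = basis, x = x, at_upper = at_upper,
                    optimal = FALSE, unbounded = TRUE))
      x[j] <- x[j] + sigma * tmax
      x[basis] <- x[basis] + delta * tmax
      if (t_self <= min(t_basic)) {
        at_upper[j] <- !at_upper[j]           # bound flip, basis unchanged
      } else {
        blockers <- which(abs(t_basic - min(t_basic)) <= tol & is.finite(t_basic))
        leave_pos <- blockers[which.min(basis[blockers])]  # Bland on leaving
        lv <- basis[leave_pos]
        at_upper[lv] <- delta[leave_pos] > 0
        x[lv] <- if (at_upper[lv]) ubf[lv] else lbf[lv]
        basis[leave_pos] <- j
        at_upper[j] <- FALSE
      }
    }
    stop("simplex iteration limit reached")
  }

  # Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(1, m))
  allow1 <- c(rep(TRUE, n), rep(FALSE, m))
  ph1 <- run_phase(c1, basis, x, at_upper, lbf, ubf, allow1)
  if (!ph1$ok) return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  if (sum(ph1$x[n + seq_len(m)]) > 1e-7)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  # Pin artificials at zero for phase 2 (kept to preserve basis size under
  # rank deficiency).
  ubf[n + seq_len(m)] <- 0
  x <- ph1$x; x[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, x, ph1$at_upper, lbf, ubf, allow1)
  if (!ph2$ok) return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  if (isTRUE(ph2$unbounded))
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = if (maximize) Inf else -Inf))
  sol <- ph2$x[seq_len(n)]
  val <- sum(obj * sol)
  list(status = "optimal", x = sol, objective = val)
}
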