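# Independent brute-force LP oracle: enumerates all basic feasible points
# (vertices) of {v : A v = b, lb <= v <= ub} by fixing every subset of
# n - rank(A) variables at a bound and solving the remaining square system.
# Completely separate from the package's simplex; used to verify every
# fixture optimum. Only viable for small models (<= ~14 reactions).

oracle_vertices <- function(A, b, lb, ub, tol = 1e-7) {
  n <- ncol(A)
  r <- qr(A)$rank
  nfix <- n - r
  verts <- list()
  add_vertex <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    if (max(abs(A %*% v - b)) > tol * max(1, max(abs(b)))) return()
    verts[[length(verts) + 1L]] <<- pmin(pmax(v, lb), ub)
  }
  if (nfix == 0L) {
    v <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(v)) add_vertex(v)
  } else {
    for (idx in utils::combn(n, nfix, simplify = FALSE)) {
      free <- setdiff(seq_len(n), idx)
      bounds_grid <- expand.grid(rep(list(c("lb", "ub")), nfix),
                                 stringsAsFactors = FALSE)
      for (gi in seq_len(nrow(bounds_grid))) {
        fixed_vals <- ifelse(unlist(bounds_grid[gi, ]) == "lb", lb[idx], ub[idx])
        if (any(!is.finite(fixed_vals))) next
        rhs <- b - A[, idx, drop = FALSE] %*% fixed_vals
        Af <- A[, free, drop = FALSE]
        sol <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
        if (is.null(sol)) next
        if (max(abs(Af %*% sol - rhs)) > tol * max(1, max(abs(rhs)))) next
        v <- numeric(n); v[idx] <- fixed_vals; v[free] <- sol
        add_vertex(v)
      }
    }
  }
  if (!length(verts)) return(NULL)
  do.call(rbind, verts)
}

# Optimum of a flux-balance LP by vertex enumeration. `fixed` mirrors the
# package API: named list of c(value, tol) pinning reactions.
oracle_optimum <- function(model, target = model$objective,
                           sense = c("max", "min"), fixed = list()) {
  sense <- match.arg(sense)
  A <- model$S
  b <- rep(0, nrow(A))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  for (rid in names(fixed)) {
    j <- match(rid, model$reactions$id)
    row <- rep(0, ncol(A)); row[j] <- 1
    A <- rbind(A, row)
    b <- c(b, fixed[[rid]][1])
  }
  ub[!is.finite(ub)] <- 1e6   # fixtures are bounded in practice
  V <- oracle_vertices(A, b, lb, ub)
  if (is.null(V)) return(NA_real_)
  j <- match(target, model$reactions$id)
  if (sense == "max") max(V[, j]) else min(V[, j])
}
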