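## Thin wrapper around boot::simplex giving a single entry point for all
## linear programmes in the package:
##
##   minimise  c'x   subject to  A_eq x = b_eq,  A_ub x <= b_ub,  x >= 0.
##
## boot::simplex requires non-negative right-hand sides, so rows are sign-
## flipped as needed (<= rows with negative rhs become >= rows).
lp_min <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                   eps = 1e-10) {
  n <- length(obj)
  A1 <- NULL; b1 <- NULL   # <=
  A2 <- NULL; b2 <- NULL   # >=
  A3 <- NULL; b3 <- NULL   # ==
  if (!is.null(A_eq) && nrow(A_eq) > 0L) {
    stopifnot(ncol(A_eq) == n, nrow(A_eq) == length(b_eq))
    ## boot::simplex breaks down on linearly dependent equality rows (mass
    ## balance plus fixed-flux rows are usually rank deficient), so keep an
    ## independent subset; if the dropped rows are not implied by it, the
    ## system is inconsistent outright.
    qa <- qr(t(A_eq))
    if (qa$rank < nrow(A_eq)) {
      r_aug <- qr(t(cbind(A_eq, b_eq)))$rank
      if (r_aug > qa$rank)
        return(list(status = "infeasible", x = NULL, objval = NA_real_,
                    message = "inconsistent equality rows"))
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      A_eq <- A_eq[keep, , drop = FALSE]
      b_eq <- b_eq[keep]
    }
    sgn <- ifelse(b_eq < 0, -1, 1)
    A3 <- A_eq * sgn
    b3 <- b_eq * sgn
  }
  if (!is.null(A_ub) && nrow(A_ub) > 0L) {
    stopifnot(ncol(A_ub) == n, nrow(A_ub) == length(b_ub))
    neg <- b_ub < 0
    if (any(!neg)) { A1 <- A_ub[!neg, , drop = FALSE]; b1 <- b_ub[!neg] }
    if (any(neg))  { A2 <- -A_ub[neg, , drop = FALSE]; b2 <- -b_ub[neg] }
  }
  res <- tryCatch(
    boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = FALSE, eps = eps,
                  n.iter = max(200L, 20L * (n + length(b1) + length(b2) +
                                              length(b3)))),
    error = function(e) e)
  if (!inherits(res, "error") && res$solved %in% c(1, -1)) {
    status <- if (res$solved == 1) "optimal" else "infeasible"
    x <- if (status == "optimal") as.numeric(res$soln[seq_len(n)]) else NULL
    return(list(status = status, x = x,
                objval = if (status == "optimal") unname(res$value)
                         else NA_real_,
                message = NULL))
  }
  ## boot::simplex occasionally breaks down on degenerate bases (notably at
  ## feasibility thresholds); fall back on a Bland-rule two-phase simplex,
  ## which is slower but cannot cycle
  simplex_bland(obj, A1, b1, A2, b2, A3, b3)
}

## Two-phase dense simplex with Bland's anti-cycling rule on the standard
## form min c'x, Ax = b, x >= 0 (b >= 0). Constraints arrive in the same
## three groups boot::simplex uses: A1 x <= b1, A2 x >= b2, A3 x = b3, all
## with non-negative right-hand sides.
simplex_bland <- function(obj, A1, b1, A2, b2, A3, b3, tol = 1e-11) {
  n <- length(obj)
  rows <- list(); rhs <- numeric(); n_slack <- 0L
  slack_sign <- numeric()
  add <- function(a, b, sgn) {
    rows[[length(rows) + 1L]] <<- a
    rhs <<- c(rhs, b)
    slack_sign <<- c(slack_sign, sgn)
  }
  if (!is.null(A1)) for (i in seq_along(b1)) add(A1[i, ], b1[i], +1)
  if (!is.null(A2)) for (i in seq_along(b2)) add(A2[i, ], b2[i], -1)
  if (!is.null(A3)) for (i in seq_along(b3)) add(A3[i, ], b3[i], 0)
  m <- length(rows)
  k <- sum(slack_sign != 0)
  A <- matrix(0, m, n + k)
  sl <- 0L
  for (i in seq_len(m)) {
    A[i, seq_len(n)] <- rows[[i]]
    if (slack_sign[i] != 0) {
      sl <- sl + 1L
      A[i, n + sl] <- slack_sign[i]
    }
  }
  b <- rhs
  nv <- n + k
  ## phase 1: artificial basis
  Tb <- cbind(A, diag(m), b)
  basis <- nv + seq_len(m)
  cost1 <- c(rep(0, nv), rep(1, m))
  run_phase <- function(Tb, basis, cost, n_total) {
    repeat {
      cb <- cost[basis]
      red <- cost[seq_len(n_total)] -
        as.numeric(crossprod(cb, Tb[, seq_len(n_total), drop = FALSE]))
      ent <- which(red < -tol)
      if (length(ent) == 0L) return(list(T = Tb, basis = basis))
      j <- min(ent)                               # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) return(list(unbounded = TRUE))
      ratio <- Tb[pos, ncol(Tb)] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      i <- cand[which.min(basis[cand])]           # Bland tie-break
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(nrow(Tb))) if (r != i && abs(Tb[r, j]) > 0)
        Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      basis[i] <- j
    }
  }
  ph1 <- run_phase(Tb, basis, cost1, nv + m)
  if (isTRUE(ph1$unbounded))
    return(list(status = "failed", x = NULL, objval = NA_real_,
                message = "phase-1 unbounded (internal error)"))
  Tb <- ph1$T; basis <- ph1$basis
  p1_obj <- sum(Tb[, ncol(Tb)] * (basis > nv))
  if (p1_obj > 1e-8)
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                message = NULL))
  ## drive leftover artificials out of the basis where possible
  for (i in which(basis > nv)) {
    row <- Tb[i, seq_len(nv)]
    j <- which(abs(row) > tol)
    if (length(j) == 0L) next                     # redundant row
    j <- j[1]
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    for (r in seq_len(nrow(Tb))) if (r != i && abs(Tb[r, j]) > 0)
      Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    basis[i] <- j
  }
  keep <- basis <= nv
  Tb2 <- cbind(Tb[keep, seq_len(nv), drop = FALSE],
               Tb[keep, ncol(Tb)])
  basis2 <- basis[keep]
  cost2 <- c(obj, rep(0, k))
  ph2 <- run_phase(Tb2, basis2, cost2, nv)
  if (isTRUE(ph2$unbounded))
    return(list(status = "failed", x = NULL, objval = NA_real_,
                message = "objective unbounded below"))
  Tb2 <- ph2$T; basis2 <- ph2$basis
  x <- numeric(nv)
  x[basis2] <- Tb2[, ncol(Tb2)]
  x <- pmax(x, 0)
  list(status = "optimal", x = x[seq_len(n)],
       objval = sum(obj * x[seq_len(n)]), message = NULL)
}
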