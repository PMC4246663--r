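## ---------------------------------------------------------------------
## Exact rational arithmetic on numerator/denominator pairs.
##
## Numerators and denominators are stored in doubles, which represent
## integers exactly up to 2^53; every fixture the oracle runs on has small
## rational coefficients, and each operation reduces by the gcd, so the
## arithmetic below is exact. Used only by the brute-force vertex
## enumeration oracle - the production path solves with the LP.
## ---------------------------------------------------------------------

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  max(a, 1)
}

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- rat_gcd(num, den)
  c(num / g, den / g)
}

## convert a double that is a ratio of small integers to exact num/den
as_rat <- function(x, max_den = 1e6) {
  if (x == round(x)) return(rat(x, 1))
  for (d in 2:max_den) {
    n <- x * d
    if (abs(n - round(n)) < 1e-9 * max(1, abs(n))) return(rat(round(n), d))
  }
  stop("coefficient ", x, " is not a small rational")
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_sub <- function(a, b) rat(a[1] * b[2] - b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  if (b[1] == 0) stop("rational division by zero")
  rat(a[1] * b[2], a[2] * b[1])
}
rat_is_zero <- function(a) a[1] == 0
rat_sign <- function(a) sign(a[1])
rat_to_num <- function(a) a[1] / a[2]

## Exact Gauss-Jordan solve of a square rational system; returns NULL when
## singular. A and b are lists-of-lists of rat pairs.
rat_solve <- function(A, b) {
  n <- length(b)
  for (col in seq_len(n)) {
    piv <- NULL
    for (row in col:n) if (!rat_is_zero(A[[row]][[col]])) { piv <- row; break }
    if (is.null(piv)) return(NULL)
    if (piv != col) {
      tmp <- A[[piv]]; A[[piv]] <- A[[col]]; A[[col]] <- tmp
      tmp <- b[[piv]]; b[[piv]] <- b[[col]]; b[[col]] <- tmp
    }
    pv <- A[[col]][[col]]
    for (j in seq_len(n)) A[[col]][[j]] <- rat_div(A[[col]][[j]], pv)
    b[[col]] <- rat_div(b[[col]], pv)
    for (row in seq_len(n)) {
      if (row == col) next
      f <- A[[row]][[col]]
      if (rat_is_zero(f)) next
      for (j in seq_len(n))
        A[[row]][[j]] <- rat_sub(A[[row]][[j]], rat_mul(f, A[[col]][[j]]))
      b[[row]] <- rat_sub(b[[row]], rat_mul(f, b[[col]]))
    }
  }
  b
}

## Exact rational RREF returning the independent row indices of [A | b];
## signals infeasibility when a row reduces to 0 = nonzero.
rat_independent_rows <- function(A, b) {
  m <- length(A); n <- length(A[[1]])
  keep <- integer()
  pivot_cols <- integer()
  for (row in seq_len(m)) {
    r <- A[[row]]; rb <- b[[row]]
    for (k in seq_along(keep)) {
      pc <- pivot_cols[k]
      f <- r[[pc]]
      if (rat_is_zero(f)) next
      base <- A[[keep[k]]]
      for (j in seq_len(n)) r[[j]] <- rat_sub(r[[j]], rat_mul(f, base[[j]]))
      rb <- rat_sub(rb, rat_mul(f, b[[keep[k]]]))
    }
    pc <- NULL
    for (j in seq_len(n)) if (!rat_is_zero(r[[j]])) { pc <- j; break }
    if (is.null(pc)) {
      if (!rat_is_zero(rb)) return(list(infeasible = TRUE))
      next
    }
    pv <- r[[pc]]
    for (j in seq_len(n)) r[[j]] <- rat_div(r[[j]], pv)
    rb <- rat_div(rb, pv)
    A[[row]] <- r; b[[row]] <- rb
    keep <- c(keep, row); pivot_cols <- c(pivot_cols, pc)
  }
  list(infeasible = FALSE, rows = keep, A = A[keep], b = b[keep])
}

#' Brute-force minimal-total-flux by vertex enumeration
#'
#' Independent oracle for [minimize_total_flux()]: builds the same
#' split-flux standard form (equalities plus slack variables for the
#' inequality rows), enumerates every basic solution of the polytope in
#' exact rational arithmetic, keeps the feasible ones, and returns the
#' minimum-objective vertex. A polytope in standard form with non-negative
#' variables has a vertex whenever it is non-empty, so an empty feasible
#' vertex set means infeasible.
#'
#' @param net a `metabolic_network` whose split problem has at most
#'   `max_vars` variables.
#' @param constraints a `leaf_constraints`.
#' @param max_vars dimension cap (enumeration is combinatorial).
#' @return list with `status` (`"optimal"` / `"infeasible"`), `objective`
#'   (sum of split fluxes) and `net_flux`.
#' @export
brute_force_min_flux <- function(net, constraints, max_vars = 14L) {
  sys <- build_lp_system(net, constraints)
  n_flux <- ncol(sys$split$S)
  A <- sys$A_eq
  b <- sys$b_eq
  if (!is.null(sys$A_ub) && nrow(sys$A_ub) > 0L) {
    k <- nrow(sys$A_ub)
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(sys$A_ub, diag(k)))
    b <- c(b, sys$b_ub)
  }
  n <- ncol(A)
  if (n > max_vars)
    stop("split problem has ", n, " variables; oracle capped at ", max_vars)

  Ar <- lapply(seq_len(nrow(A)), function(i) lapply(A[i, ], as_rat))
  br <- lapply(b, as_rat)
  red <- rat_independent_rows(Ar, br)
  if (isTRUE(red$infeasible))
    return(list(status = "infeasible", objective = NA_real_, net_flux = NULL))
  Ar <- red$A; br <- red$b
  m <- length(Ar)

  best <- NULL
  best_obj <- NULL
  zero <- rat(0)
  combs <- utils::combn(n, m)
  for (ci in seq_len(ncol(combs))) {
    cols <- combs[, ci]
    Asub <- lapply(Ar, function(row) row[cols])
    x_b <- rat_solve(Asub, br)
    if (is.null(x_b)) next
    if (any(vapply(x_b, rat_sign, numeric(1)) < 0)) next
    x <- rep(list(zero), n)
    x[cols] <- x_b
    obj <- Reduce(rat_add, x[seq_len(n_flux)], zero)
    if (is.null(best_obj) || rat_sign(rat_sub(obj, best_obj)) < 0) {
      best_obj <- obj
      best <- x
    }
  }
  if (is.null(best))
    return(list(status = "infeasible", objective = NA_real_, net_flux = NULL))
  w <- vapply(best[seq_len(n_flux)], rat_to_num, numeric(1))
  map <- sys$split$map
  v <- w[map$fwd]
  has_b <- !is.na(map$bwd)
  v[has_b] <- v[has_b] - w[map$bwd[has_b]]
  names(v) <- map$reaction
  list(status = "optimal", objective = rat_to_num(best_obj), net_flux = v)
}

#' Random small branched network with a known topology
#'
#' Deterministic in the seed: a nutrient-to-product chain
#' `x_S -> M1 -> ... -> Mk -> x_P` with random integer stoichiometry on the
#' internal steps plus random shortcut edges (`Mi -> Mj`, `i < j`), some
#' reversible. The output transporter is tagged so a fixed export rate of 1
#' poses a non-trivial minimal-flux problem; used with
#' [brute_force_min_flux()] as the enumeration oracle.
#'
#' @param seed integer seed.
#' @param n_reactions total reaction count, between 3 and 8.
#' @return list with `net`, `nutrients`, `outputs` and `constraints` (a
#'   ready-made `leaf_constraints` fixing the export at 1 with a free
#'   photon-less boundary - the photon transporter is a dummy fixed at 0).
#' @export
random_branched_network <- function(seed, n_reactions = 6L) {
  stopifnot(n_reactions >= 3L, n_reactions <= 8L)
  set.seed(seed)
  n_chain <- n_reactions - sample(0:(n_reactions - 3L), 1L)
  k <- n_chain - 1L                    # internal metabolites M1..Mk
  mets <- paste0("M", seq_len(max(k, 1L)))
  rx <- list()
  rx[["uptake"]] <- list(stoich = c(x_S = -1, M1 = 1), reversible = FALSE,
                         tags = "transporter")
  if (k >= 2L) for (i in seq_len(k - 1L)) {
    coef <- sample(1:2, 2L, replace = TRUE)
    st <- stats::setNames(c(-coef[1], coef[2]), c(mets[i], mets[i + 1L]))
    rx[[paste0("step", i)]] <- list(stoich = st,
                                    reversible = stats::runif(1) < 0.3)
  }
  rx[["export"]] <- list(stoich = stats::setNames(c(-1, 1),
                                                  c(mets[k], "x_P")),
                         reversible = FALSE,
                         tags = c("transporter", "output_transporter"))
  n_short <- n_reactions - length(rx)
  for (s in seq_len(max(0L, n_short))) {
    if (k < 3L) { # no room for a true shortcut: add a parallel step
      i <- 1L; j <- min(2L, k)
    } else {
      is <- seq_len(k - 2L)
      i <- is[sample.int(length(is), 1L)]
      js <- (i + 2L):k
      j <- js[sample.int(length(js), 1L)]
    }
    if (i == j) next
    coef <- sample(1:2, 2L, replace = TRUE)
    st <- stats::setNames(c(-coef[1], coef[2]), c(mets[i], mets[j]))
    rx[[paste0("short", s)]] <- list(stoich = st,
                                     reversible = stats::runif(1) < 0.2)
  }
  net <- metabolic_network(rx)
  out <- output_scenario(c(export = 1), r = 0, carbon_rate = 0)
  ## NA photon flux: no light axis, the nutrient uptake stays free
  constraints <- leaf_constraints(out, photon_flux = NA)
  list(net = net, nutrients = "uptake", outputs = "export",
       constraints = constraints)
}
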