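#' Split reversible reactions into irreversible forward/backward pairs
#'
#' The minimal-total-flux objective is the 1-norm of the flux vector, which a
#' linear programme represents by decomposing each reversible flux into
#' non-negative forward and backward components (the backward column is the
#' negated stoichiometry). The mapping recombines net flux = forward -
#' backward.
#'
#' @param net a `metabolic_network`.
#' @return list with `S` (stoichiometry matrix of the split network, internal
#'   metabolites x columns), `map` (data frame: reaction, fwd, bwd column
#'   indices, NA bwd for irreversible reactions) and `reaction_ids`.
#' @export
split_reversible <- function(net) {
  N <- stoichiometric_matrix(net)
  rev <- vapply(net$reactions, function(r) r$reversible, logical(1))
  n <- ncol(N)
  cols <- vector("list", n + sum(rev))
  fwd <- integer(n); bwd <- rep(NA_integer_, n)
  k <- 0L
  for (j in seq_len(n)) {
    k <- k + 1L; fwd[j] <- k; cols[[k]] <- N[, j]
  }
  for (j in which(rev)) {
    k <- k + 1L; bwd[j] <- k; cols[[k]] <- -N[, j]
  }
  S <- do.call(cbind, cols)
  rownames(S) <- rownames(N)
  colnames(S) <- c(colnames(N),
                   if (any(rev)) paste0(colnames(N)[rev], "__rev"))
  list(S = S,
       map = data.frame(reaction = colnames(N), fwd = fwd, bwd = bwd,
                        stringsAsFactors = FALSE),
       reaction_ids = colnames(N))
}

## Row vector over split columns representing the NET flux of a reaction.
net_flux_row <- function(split, id, n_cols) {
  i <- match(id, split$map$reaction)
  if (is.na(i)) stop("no reaction '", id, "' in network")
  row <- numeric(n_cols)
  row[split$map$fwd[i]] <- 1
  if (!is.na(split$map$bwd[i])) row[split$map$bwd[i]] <- -1
  row
}

#' Constraint set for a leaf-cell flux optimisation
#'
#' Bundles the scan-point settings applied on top of mass balance and
#' irreversibility: a fixed (equality) photon uptake, the cap on the summed
#' rubisco carboxylase + oxygenase rate, a fixed maintenance ATPase flux, the
#' rule that cyclic photophosphorylation may not exceed the non-cyclic rate,
#' and the fixed export-transporter fluxes of an [output_scenario()]. Photon
#' uptake is an equality, not an upper bound: excess light must be absorbed
#' by the network, which is what makes the high-light dissipation regime
#' observable.
#'
#' @param output an `output_scenario`.
#' @param photon_flux non-negative photon uptake (model flux units).
#' @param rubisco_cap positive cap on carboxylase + oxygenase flux
#'   (default `Inf` = no cap).
#' @param maintenance_atp fixed flux through the tagged maintenance ATPase.
#' @param cyclic_le_noncyclic enforce cyclic <= non-cyclic
#'   photophosphorylation (default on).
#' @param closed transporter ids forced to zero net flux (e.g. to disable a
#'   nitrogen source).
#' @param photon_tx id of the photon uptake transporter; by default the
#'   unique transporter importing the external species `x_Photon`.
#' @return an object of class `leaf_constraints`.
#' @export
leaf_constraints <- function(output, photon_flux,
                             rubisco_cap = Inf, maintenance_atp = 0,
                             cyclic_le_noncyclic = TRUE,
                             closed = character(), photon_tx = NULL) {
  stopifnot(inherits(output, "output_scenario"),
            is.na(photon_flux) || (is.finite(photon_flux) && photon_flux >= 0),
            rubisco_cap > 0, maintenance_atp >= 0,
            is.finite(maintenance_atp))
  structure(list(output = output, photon_flux = photon_flux,
                 rubisco_cap = rubisco_cap,
                 maintenance_atp = maintenance_atp,
                 cyclic_le_noncyclic = isTRUE(cyclic_le_noncyclic),
                 closed = closed, photon_tx = photon_tx),
            class = "leaf_constraints")
}

find_photon_tx <- function(net, photon_tx = NULL) {
  if (!is.null(photon_tx)) {
    if (!photon_tx %in% names(net$reactions))
      stop("photon transporter '", photon_tx, "' not in network")
    return(photon_tx)
  }
  cand <- Filter(function(id) {
    sp <- names(net$reactions[[id]]$stoich)
    any(tolower(species_base(sp)) == "photon" & startsWith(sp, "x_"))
  }, tagged_reactions(net, "transporter"))
  if (length(cand) != 1L)
    stop("expected exactly one photon uptake transporter, found ",
         length(cand), "; pass photon_tx explicitly")
  cand[[1]]
}

## Assemble equality/inequality rows shared by the optimiser and the
## capability scanner. Returns the split system plus constraint matrices.
build_lp_system <- function(net, constraints) {
  split <- split_reversible(net)
  S <- split$S
  nc <- ncol(S)

  A_eq <- S
  b_eq <- numeric(nrow(S))
  add_eq <- function(row, val) {
    A_eq <<- rbind(A_eq, row)
    b_eq <<- c(b_eq, val)
  }

  ## NA photon flux = no light axis (oracle fixtures): leave uptake free
  ptx <- NULL
  if (!is.na(constraints$photon_flux)) {
    ptx <- find_photon_tx(net, constraints$photon_tx)
    add_eq(net_flux_row(split, ptx, nc), constraints$photon_flux)
  }

  out_ids <- tagged_reactions(net, "output_transporter")
  fixed <- constraints$output$fixed_fluxes
  unknown <- setdiff(names(fixed), out_ids)
  if (length(unknown))
    stop("output scenario names untagged transporter: ", unknown[1L])
  for (id in out_ids)
    add_eq(net_flux_row(split, id, nc),
           if (id %in% names(fixed)) fixed[[id]] else 0)

  maint <- tagged_reactions(net, "maintenance_atpase")
  if (constraints$maintenance_atp > 0 && length(maint) == 0L)
    stop("maintenance_atp > 0 but no reaction tagged maintenance_atpase")
  for (id in maint)
    add_eq(net_flux_row(split, id, nc), constraints$maintenance_atp)

  for (id in constraints$closed)
    add_eq(net_flux_row(split, id, nc), 0)

  A_ub <- NULL; b_ub <- numeric()
  if (constraints$cyclic_le_noncyclic) {
    cyc <- tagged_reactions(net, "cyclic_photophos")
    ncyc <- tagged_reactions(net, "noncyclic_photophos")
    if (length(cyc) && length(ncyc)) {
      row <- numeric(nc)
      for (id in cyc) row <- row + net_flux_row(split, id, nc)
      for (id in ncyc) row <- row - net_flux_row(split, id, nc)
      A_ub <- rbind(A_ub, row)
      b_ub <- c(b_ub, 0)
    }
  }
  if (is.finite(constraints$rubisco_cap)) {
    rub <- c(tagged_reactions(net, "rubisco_carboxylase"),
             tagged_reactions(net, "rubisco_oxygenase"))
    if (length(rub)) {
      row <- numeric(nc)
      for (id in rub) row <- row + net_flux_row(split, id, nc)
      A_ub <- rbind(A_ub, row)
      b_ub <- c(b_ub, constraints$rubisco_cap)
    }
  }
  list(split = split, A_eq = A_eq, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub,
       photon_tx = ptx)
}

#' Minimal-total-flux solution of the leaf linear programme
#'
#' Minimises the sum of split (non-negative) fluxes - the 1-norm of the net
#' flux vector, a proxy for economy in enzymatic machinery - subject to
#' steady-state mass balance, irreversibility, and the scan-point constraints
#' of a [leaf_constraints()] object.
#'
#' @param net a `metabolic_network`.
#' @param constraints a `leaf_constraints`.
#' @return A `flux_solution`: list with `net_flux` (named net fluxes),
#'   `objective` (sum of split fluxes), `status` (`"optimal"` or
#'   `"infeasible"`), `photon_flux`, `r` (phloem fraction of the output
#'   scenario) and `residual` (steady-state infinity-norm residual).
#'   Infeasible problems return status only. An unbounded/failed programme
#'   raises an error, since with a fixed photon influx it signals a
#'   mass-creating model defect.
#' @export
minimize_total_flux <- function(net, constraints) {
  sys <- build_lp_system(net, constraints)
  nc <- ncol(sys$split$S)
  res <- lp_min(rep(1, nc), A_eq = sys$A_eq, b_eq = sys$b_eq,
                A_ub = sys$A_ub, b_ub = sys$b_ub)
  r_val <- constraints$output$r %||% NA_real_
  if (res$status == "infeasible")
    return(structure(list(net_flux = NULL, objective = NA_real_,
                          status = "infeasible",
                          photon_flux = constraints$photon_flux, r = r_val),
                     class = "flux_solution"))
  if (res$status != "optimal")
    stop("LP failed (unbounded or solver breakdown): ",
         res$message %||% "no message")
  w <- res$x
  map <- sys$split$map
  v <- w[map$fwd]
  has_b <- !is.na(map$bwd)
  v[has_b] <- v[has_b] - w[map$bwd[has_b]]
  names(v) <- map$reaction
  N <- stoichiometric_matrix(net)
  resid <- max(abs(N %*% v))
  scale <- max(1, max(abs(v)))
  if (resid > 1e-9 * scale)
    stop("steady-state residual ", format(resid), " exceeds tolerance")
  structure(list(net_flux = v, objective = res$objval, status = "optimal",
                 photon_flux = constraints$photon_flux, r = r_val,
                 residual = resid, split_flux = w),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " photon_flux:", format(x$photon_flux), "\n")
  if (x$status == "optimal")
    cat("  objective (total flux):", format(x$objective),
        " active reactions:", active_reaction_count(x), "\n")
  invisible(x)
}

#' Reactions able to carry steady-state flux
#'
#' Classifies each reaction by whether some steady-state flux vector exists
#' with nonzero flux through it, with the named nutrient and output
#' transporters unconstrained, every other exchange closed, and
#' irreversibility respected. Computed by per-reaction maximisation (and for
#' reversible reactions minimisation) of the net flux under a box bound
#' `big_m`, the standard flux-variability formulation.
#'
#' @param net a `metabolic_network`.
#' @param nutrients transporter ids left open as inputs.
#' @param outputs transporter ids left open as sinks.
#' @param tol capability threshold as a fraction of `big_m`: a reaction is
#'   capable when its attainable `|net flux|` exceeds `tol * big_m`.
#' @param big_m box bound making every per-reaction programme bounded.
#' @return character vector of flux-capable reaction ids.
#' @export
flux_capable_reactions <- function(net, nutrients, outputs,
                                   tol = 1e-6, big_m = 1000) {
  ## boundary exchanges: transporters touching an external species.
  ## Intra-cellular transporters move metabolites between compartments and
  ## stay open.
  tx <- Filter(function(id) {
    any(startsWith(names(net$reactions[[id]]$stoich), "x_"))
  }, tagged_reactions(net, "transporter"))
  open <- union(nutrients, outputs)
  missing <- setdiff(open, names(net$reactions))
  if (length(missing)) stop("unknown transporter: ", missing[1L])
  split <- split_reversible(net)
  S <- split$S
  nc <- ncol(S)
  A_eq <- S
  b_eq <- numeric(nrow(S))
  for (id in setdiff(tx, open)) {
    A_eq <- rbind(A_eq, net_flux_row(split, id, nc))
    b_eq <- c(b_eq, 0)
  }
  A_box <- diag(nc)
  b_box <- rep(big_m, nc)
  ## base problem: all right-hand sides are zero here, so w = 0 is feasible;
  ## guard against a future nonzero-rhs variant anyway
  if (any(b_eq != 0)) {
    base <- lp_min(rep(1, nc), A_eq = A_eq, b_eq = b_eq,
                   A_ub = A_box, b_ub = b_box)
    if (base$status != "optimal")
      stop("base capability problem is ", base$status,
           ": network admits no steady state under the closed-exchange setup")
  }
  thresh <- tol * big_m
  capable <- character()
  for (i in seq_len(nrow(split$map))) {
    id <- split$map$reaction[i]
    row <- net_flux_row(split, id, nc)
    up <- lp_min(-row, A_eq = A_eq, b_eq = b_eq, A_ub = A_box, b_ub = b_box)
    ok <- up$status == "optimal" && -up$objval > thresh
    if (!ok && !is.na(split$map$bwd[i])) {
      dn <- lp_min(row, A_eq = A_eq, b_eq = b_eq, A_ub = A_box, b_ub = b_box)
      ok <- dn$status == "optimal" && dn$objval < -thresh
    }
    if (ok) capable <- c(capable, id)
  }
  capable
}

ENERGY_CARRIERS <- c("ATP", "NADPH", "NADH")

#' Diagnose dissipation by substrate cycling in a solution
#'
#' At photon fluxes beyond what the fixed outputs require, the equality
#' photon constraint forces the network to absorb excess ATP and reductant;
#' minimal-flux solutions do so through substrate cycles (paired reactions
#' whose combined operation leaves every non-cofactor species unchanged while
#' consuming ATP/NAD(P)H, e.g. starch synthesis plus degradation). This
#' reports every such pair simultaneously active in a solution.
#'
#' @param sol an optimal `flux_solution`.
#' @param net the network it was solved on.
#' @param tol activity threshold on net flux (defaults to the scale-aware
#'   activity threshold, `1e-7 * max(1, photon_flux)`).
#' @return data frame with one row per active cycle: `forward`, `backward`,
#'   `cycle_flux` and `energy_dissipated` (cofactor units consumed per time).
#'   Zero rows when no dissipation is active.
#' @export
photon_excess_diagnostics <- function(sol, net, tol = NULL) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(tol)) tol <- 1e-7 * max(1, sol$photon_flux)
  v <- sol$net_flux
  ids <- names(v)
  non_carrier <- function(st) {
    st[!(species_base(names(st)) %in% ENERGY_CARRIERS)]
  }
  carrier_net <- function(st) {
    sum(st[species_base(names(st)) %in% ENERGY_CARRIERS])
  }
  out <- data.frame(forward = character(), backward = character(),
                    cycle_flux = numeric(), energy_dissipated = numeric(),
                    stringsAsFactors = FALSE)
  act <- ids[abs(v) > tol]
  if (length(act) < 2L) return(out)
  for (a in seq_along(act)) for (b in seq_along(act)) {
    if (a >= b) next
    ra <- net$reactions[[act[a]]]; rb <- net$reactions[[act[b]]]
    sa <- non_carrier(ra$stoich); sb <- non_carrier(rb$stoich)
    if (length(sa) == 0L || length(sb) != length(sa)) next
    if (!setequal(names(sa), names(sb))) next
    sb <- sb[names(sa)]
    lam <- -sa[1] / sb[1]
    if (!is.finite(lam) || lam <= 0) next
    if (max(abs(sa + lam * sb)) > 1e-9) next
    ## combined unit operation (1, lambda) cancels all non-cofactor species;
    ## it is a dissipating cycle when it consumes energy carriers net
    diss <- -(carrier_net(ra$stoich) + lam * carrier_net(rb$stoich))
    if (diss <= 1e-12) next
    va <- v[[act[a]]]; vb <- v[[act[b]]]
    if (va <= tol || vb <= tol) next   # both must run forward
    cyc <- min(va, vb / lam)
    out <- rbind(out, data.frame(forward = act[a], backward = act[b],
                                 cycle_flux = cyc,
                                 energy_dissipated = cyc * diss,
                                 stringsAsFactors = FALSE))
  }
  out
}
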