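## Boundary exchange transporter for a species: the transporter whose
## stoichiometry includes the external metabolite with that base name.
find_exchange <- function(net, species) {
  cand <- Filter(function(id) {
    sp <- names(net$reactions[[id]]$stoich)
    any(startsWith(sp, "x_") & species_base(sp) == species)
  }, tagged_reactions(net, "transporter"))
  if (length(cand) == 0L)
    stop("no boundary transporter for species '", species, "'")
  cand
}

## Net uptake (positive = into the cell) of a species across the boundary.
boundary_uptake <- function(sol, net, species) {
  ids <- find_exchange(net, species)
  total <- 0
  for (id in ids) {
    st <- net$reactions[[id]]$stoich
    ext <- st[startsWith(names(st), "x_") & species_base(names(st)) == species]
    ## flux in the direction consuming the external species = uptake
    total <- total + sum(-ext * sol$net_flux[[id]])
  }
  total
}

#' Assimilatory Quotient of a solution
#'
#' AQ = net CO2 fixed per net O2 released, both measured at the cell
#' boundary (internal refixation of respiratory or photorespiratory CO2
#' cancels and is degenerate-optimum-dependent; boundary fluxes are
#' unambiguous).
#'
#' @param sol an optimal `flux_solution`.
#' @param net the network solved.
#' @param tol threshold below which the O2 release is treated as zero
#'   (default scale-aware).
#' @return AQ as a single number.
#' @export
assimilatory_quotient <- function(sol, net, tol = NULL) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(tol)) tol <- 1e-7 * max(1, sol$photon_flux)
  co2_in <- boundary_uptake(sol, net, "CO2")
  o2_out <- -boundary_uptake(sol, net, "O2")
  if (abs(o2_out) <= tol)
    stop("AQ undefined: net O2 release is zero")
  co2_in / o2_out
}

#' Number of active reactions in a solution
#'
#' @param sol an optimal `flux_solution`.
#' @param tol activity threshold on `|net flux|`; default is the scale-aware
#'   threshold `1e-7 * max(1, photon_flux)`, identical to the one used for
#'   region detection so counts and regions agree.
#' @return integer count.
#' @export
active_reaction_count <- function(sol, tol = NULL) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(tol)) tol <- 1e-7 * max(1, sol$photon_flux)
  sum(abs(sol$net_flux) > tol)
}

#' Exchange fluxes across a compartment boundary
#'
#' For every species moved by a transport reaction across the boundary of
#' the named compartment, the signed net flux with the convention: positive
#' = import into the compartment, negative = export.
#'
#' @param sol an optimal `flux_solution`.
#' @param net the network solved.
#' @param compartment one of the network's compartments.
#' @return a `compartment_exchange`: named numeric `fluxes` (by species base
#'   name) plus the compartment.
#' @export
compartment_exchange <- function(sol, net, compartment) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (!compartment %in% net$compartments)
    stop("unknown compartment '", compartment, "'")
  comp_of <- stats::setNames(net$metabolites$compartment, net$metabolites$id)
  fluxes <- numeric()
  for (r in net$reactions) {
    sp <- names(r$stoich)
    inside <- comp_of[sp] == compartment
    if (!any(inside) || all(inside)) next   # does not cross this boundary
    v <- sol$net_flux[[r$id]]
    for (s in sp[inside]) {
      base <- species_base(s)
      contrib <- r$stoich[[s]] * v        # production inside = import
      fluxes[base] <- (if (base %in% names(fluxes)) fluxes[[base]] else 0) +
        contrib
    }
  }
  structure(list(compartment = compartment, fluxes = fluxes),
            class = "compartment_exchange")
}

#' Shares of nitrogen uptake by source
#'
#' Fractions of total boundary nitrogen uptake entering as NH3 and as NO3
#' (weighted by nitrogen atoms; both carry one in the standard element
#' table). The fractions sum to one wherever total uptake is positive.
#'
#' @param sol an optimal `flux_solution`.
#' @param net the network solved.
#' @param tol threshold below which total N uptake counts as zero.
#' @return named numeric `c(nh3 = ..., no3 = ...)`.
#' @export
nitrogen_source_shares <- function(sol, net, tol = NULL) {
  stopifnot(inherits(sol, "flux_solution"), sol$status == "optimal")
  if (is.null(tol)) tol <- 1e-7 * max(1, sol$photon_flux)
  n_atoms <- function(species) {
    i <- match(species, species_base(net$metabolites$id))
    a <- net$metabolites$nitrogen[i]
    if (is.na(a)) 1 else a
  }
  nh3 <- boundary_uptake(sol, net, "NH3") * n_atoms("NH3")
  no3 <- boundary_uptake(sol, net, "NO3") * n_atoms("NO3")
  total <- nh3 + no3
  if (total <= tol) stop("no nitrogen uptake in this solution")
  c(nh3 = nh3 / total, no3 = no3 / total)
}

#' @export
print.compartment_exchange <- function(x, ...) {
  cat("<compartment_exchange> ", x$compartment, " (positive = import):\n",
      sep = "")
  print(round(x$fluxes, 6))
  invisible(x)
}
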