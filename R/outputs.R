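#' Composition table for a metabolic output mix
#'
#' Relative molar export rates of the constituent components of an output
#' (leaf biomass or phloem sap), keyed by the export transporter that carries
#' each component to its external sink.
#'
#' @param entries named non-negative numeric: relative molar rate per unit
#'   output for each export transporter id.
#' @param label `"biomass"` or `"phloem"`.
#' @return object of class `composition_table`.
#' @export
composition_table <- function(entries, label = c("biomass", "phloem")) {
  label <- match.arg(label)
  stopifnot(is.numeric(entries), length(entries) > 0L,
            !is.null(names(entries)), all(entries >= 0))
  entries <- entries[entries > 0]
  if (length(entries) == 0L) stop("composition needs at least one positive entry")
  structure(list(entries = entries, label = label),
            class = "composition_table")
}

#' Read a composition table from TSV
#'
#' Expected columns: `transporter_id`, `relative_rate`.
#' @param path file path.
#' @param label `"biomass"` or `"phloem"`.
#' @return a `composition_table`.
#' @export
read_composition <- function(path, label = c("biomass", "phloem")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transporter_id", "relative_rate") %in% names(d)))
    stop("composition table needs columns transporter_id, relative_rate")
  composition_table(stats::setNames(d$relative_rate, d$transporter_id),
                    label = match.arg(label))
}

## Carbon atoms of the species exported by an output transporter: the
## external metabolite on its product side.
exported_carbon <- function(net, tx_id) {
  r <- net$reactions[[tx_id]]
  if (is.null(r)) stop("no transporter '", tx_id, "' in network")
  ext <- names(r$stoich)[startsWith(names(r$stoich), "x_") & r$stoich > 0]
  if (length(ext) != 1L)
    stop("output transporter '", tx_id,
         "' must export exactly one external species")
  carbon <- net$metabolites$carbon[match(ext, net$metabolites$id)]
  if (is.na(carbon))
    stop("no carbon atom count for species '", ext,
         "' exported by '", tx_id, "'; supply it in the element table")
  carbon
}

#' Convert a composition table into fixed export fluxes
#'
#' Multiplies the relative rates by an absolute output rate and computes the
#' carbon export rate from the element side table attached to the network.
#'
#' @param net a `metabolic_network` with carbon data for every exported
#'   species.
#' @param table a `composition_table`.
#' @param rate positive absolute output rate (model flux units).
#' @param r phloem fraction recorded on the scenario (0 = pure biomass,
#'   1 = pure phloem); defaults by table label.
#' @return an `output_scenario`: `fixed_fluxes` (named, non-negative),
#'   `r`, and `carbon_rate` (mol C exported per unit time).
#' @export
composition_to_fluxes <- function(net, table, rate,
                                  r = if (table$label == "phloem") 1 else 0) {
  stopifnot(inherits(table, "composition_table"))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  out_tags <- tagged_reactions(net, "output_transporter")
  bad <- setdiff(names(table$entries), out_tags)
  if (length(bad))
    stop("composition references '", bad[1L],
         "', which is not tagged output_transporter in the network")
  fluxes <- rate * table$entries
  carbons <- vapply(names(fluxes), exported_carbon, numeric(1), net = net)
  output_scenario(fluxes, r = r, carbon_rate = sum(fluxes * carbons))
}

#' Bare constructor for an output scenario
#' @param fixed_fluxes named non-negative numeric, export transporter fluxes.
#' @param r phloem fraction in \[0, 1\].
#' @param carbon_rate carbon export rate backing the equal-carbon design.
#' @export
output_scenario <- function(fixed_fluxes, r, carbon_rate) {
  stopifnot(is.numeric(fixed_fluxes), !is.null(names(fixed_fluxes)),
            all(fixed_fluxes >= 0), r >= 0, r <= 1, carbon_rate >= 0)
  structure(list(fixed_fluxes = fixed_fluxes, r = r,
                 carbon_rate = carbon_rate),
            class = "output_scenario")
}

#' Rescale a phloem scenario to export the same carbon as a biomass scenario
#'
#' The controlled-comparison design: 100% phloem output is set to contain
#' the same amount of fixed carbon as the maximum biomass output, so the
#' amount of carbon fixed does not change along the output-transition axis.
#'
#' @param phloem,biomass `output_scenario` objects with positive carbon rate.
#' @return the phloem scenario with every flux multiplied by
#'   `biomass$carbon_rate / phloem$carbon_rate`.
#' @export
scale_to_equal_carbon <- function(phloem, biomass) {
  stopifnot(inherits(phloem, "output_scenario"),
            inherits(biomass, "output_scenario"))
  if (phloem$carbon_rate <= 0) stop("phloem scenario exports no carbon")
  if (biomass$carbon_rate <= 0) stop("biomass scenario exports no carbon")
  f <- biomass$carbon_rate / phloem$carbon_rate
  output_scenario(phloem$fixed_fluxes * f, r = phloem$r,
                  carbon_rate = phloem$carbon_rate * f)
}

#' Mix biomass and phloem outputs along the transition axis
#'
#' Componentwise convex combination `(1 - r) * biomass + r * phloem`. With
#' the phloem scenario equal-carbon scaled first, the carbon export rate is
#' invariant in `r`.
#'
#' @param biomass,phloem `output_scenario` objects (phloem already scaled).
#' @param r phloem fraction in \[0, 1\].
#' @return an `output_scenario` over the union of transporters.
#' @export
mix_outputs <- function(biomass, phloem, r) {
  stopifnot(inherits(biomass, "output_scenario"),
            inherits(phloem, "output_scenario"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    stop("r must be a single number in [0, 1]")
  ids <- union(names(biomass$fixed_fluxes), names(phloem$fixed_fluxes))
  get <- function(sc) {
    x <- stats::setNames(numeric(length(ids)), ids)
    x[names(sc$fixed_fluxes)] <- sc$fixed_fluxes
    x
  }
  mixed <- (1 - r) * get(biomass) + r * get(phloem)
  output_scenario(mixed, r = r,
                  carbon_rate = (1 - r) * biomass$carbon_rate +
                    r * phloem$carbon_rate)
}
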