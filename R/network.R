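#' @keywords internal
"_PACKAGE"

## Reaction tags understood by the constraint builder and the metrics layer.
KNOWN_TAGS <- c("transporter", "cyclic_photophos", "noncyclic_photophos",
                "rubisco_carboxylase", "rubisco_oxygenase",
                "maintenance_atpase", "output_transporter")

#' Construct a compartmented metabolic network
#'
#' A `metabolic_network` couples an ordered metabolite table with an ordered
#' reaction list. Metabolites whose id carries the `x_` prefix are external
#' (unbalanced): they receive no mass-balance row in the stoichiometry matrix.
#' Internal metabolite compartments are read from the id suffix (`_cyt`,
#' `_chl`, `_mit`); unsuffixed internal species default to the cytosol.
#'
#' @param reactions named list; each element a list with fields `stoich`
#'   (named numeric, negative = consumed), `reversible` (flag) and optional
#'   `tags` (character vector drawn from the known tag set).
#' @param elements optional data frame with columns `species`, `carbon`,
#'   `nitrogen` giving atom counts per metabolite id (or per id with any
#'   compartment suffix / external prefix stripped).
#' @return An object of class `metabolic_network` with components
#'   `metabolites` (data frame: id, compartment, is_external, carbon,
#'   nitrogen), `reactions` and `compartments`.
#' @export
metabolic_network <- function(reactions, elements = NULL) {
  if (length(reactions) == 0L) stop("network needs at least one reaction")
  ids <- names(reactions)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every reaction must be named")
  if (anyDuplicated(ids))
    stop("duplicate reaction id: ", ids[duplicated(ids)][1L])
  reactions <- lapply(seq_along(reactions), function(i) {
    r <- reactions[[i]]
    if (is.null(r$stoich) || length(r$stoich) == 0L)
      stop("reaction '", ids[i], "' has empty stoichiometry")
    if (any(r$stoich == 0))
      stop("reaction '", ids[i], "' has a zero coefficient")
    if (is.null(names(r$stoich)) || any(names(r$stoich) == ""))
      stop("reaction '", ids[i], "' has unnamed species")
    if (anyDuplicated(names(r$stoich)))
      stop("reaction '", ids[i], "' repeats a species")
    r$id <- ids[i]
    r$reversible <- isTRUE(r$reversible)
    r$tags <- as.character(r$tags %||% character())
    bad <- setdiff(r$tags, KNOWN_TAGS)
    if (length(bad)) stop("reaction '", ids[i], "' has unknown tag: ", bad[1L])
    r
  })
  names(reactions) <- ids

  met_ids <- unique(unlist(lapply(reactions, function(r) names(r$stoich)),
                           use.names = FALSE))
  is_ext <- startsWith(met_ids, "x_")
  comp <- ifelse(is_ext, "external", metabolite_compartment(met_ids))
  mets <- data.frame(id = met_ids, compartment = comp, is_external = is_ext,
                     carbon = NA_real_, nitrogen = NA_real_,
                     stringsAsFactors = FALSE)
  net <- structure(list(metabolites = mets, reactions = reactions,
                        compartments = sort(unique(comp[!is_ext]))),
                   class = "metabolic_network")
  if (!is.null(elements)) net <- set_species_elements(net, elements)

  ## a transporter must touch the outside world or cross a compartment wall
  for (r in reactions) {
    if ("transporter" %in% r$tags) {
      sp <- names(r$stoich)
      if (!any(startsWith(sp, "x_")) &&
          length(unique(mets$compartment[match(sp, mets$id)])) < 2L)
        stop("transporter '", r$id, "' references no external metabolite ",
             "and spans a single compartment")
    }
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Compartment from the id suffix; bare ids live in the cytosol.
metabolite_compartment <- function(ids) {
  out <- rep("cyt", length(ids))
  has <- grepl("_(cyt|chl|mit)$", ids)
  out[has] <- sub("^.*_(cyt|chl|mit)$", "\\1", ids[has])
  out
}

## Strip the external prefix and any compartment suffix: the species base name.
species_base <- function(ids) {
  ids <- sub("^x_", "", ids)
  sub("_(cyt|chl|mit)$", "", ids)
}

#' Attach elemental composition (C and N atom counts) to a network
#'
#' Atom counts are supplied in a side table rather than parsed from chemical
#' formulas; entries match metabolite ids after stripping the external prefix
#' and the compartment suffix, so one row covers a species in every
#' compartment.
#'
#' @param net a `metabolic_network`.
#' @param elements data frame with columns `species`, `carbon`, `nitrogen`.
#' @return The network with `carbon`/`nitrogen` filled where known.
#' @export
set_species_elements <- function(net, elements) {
  stopifnot(inherits(net, "metabolic_network"),
            all(c("species", "carbon", "nitrogen") %in% names(elements)))
  if (any(elements$carbon < 0, na.rm = TRUE) ||
      any(elements$nitrogen < 0, na.rm = TRUE))
    stop("atom counts must be non-negative")
  base <- species_base(net$metabolites$id)
  i <- match(base, species_base(elements$species))
  hit <- !is.na(i)
  net$metabolites$carbon[hit] <- as.numeric(elements$carbon[i[hit]])
  net$metabolites$nitrogen[hit] <- as.numeric(elements$nitrogen[i[hit]])
  net
}

#' Read a composition side table (TSV)
#'
#' Expected columns: `metabolite_id`, `carbon_atoms`, `nitrogen_atoms`.
#' @param path file path.
#' @return data frame with columns `species`, `carbon`, `nitrogen`.
#' @export
read_elements <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "carbon_atoms", "nitrogen_atoms")
  if (!all(need %in% names(d)))
    stop("element table needs columns: ", paste(need, collapse = ", "))
  data.frame(species = d$metabolite_id, carbon = d$carbon_atoms,
             nitrogen = d$nitrogen_atoms, stringsAsFactors = FALSE)
}

#' Add or replace tags on a reaction
#' @param net a `metabolic_network`.
#' @param id reaction id.
#' @param tags character vector of tags (from the known tag set).
#' @export
set_reaction_tags <- function(net, id, tags) {
  if (!id %in% names(net$reactions)) stop("no reaction '", id, "'")
  bad <- setdiff(tags, KNOWN_TAGS)
  if (length(bad)) stop("unknown tag: ", bad[1L])
  net$reactions[[id]]$tags <- unique(as.character(tags))
  net
}

#' Reactions carrying a given tag
#' @param net a `metabolic_network`.
#' @param tag one tag.
#' @return character vector of reaction ids.
#' @export
tagged_reactions <- function(net, tag) {
  ids <- names(net$reactions)
  ids[vapply(net$reactions, function(r) tag %in% r$tags, logical(1))]
}

#' Stoichiometry matrix of the internal metabolites
#'
#' One row per internal metabolite, one column per reaction; entry (m, j) is
#' the signed coefficient of metabolite m in reaction j. External metabolites
#' carry no mass-balance row and are excluded.
#'
#' @param net a `metabolic_network`.
#' @return dense numeric matrix with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  internal <- net$metabolites$id[!net$metabolites$is_external]
  N <- matrix(0, nrow = length(internal), ncol = length(net$reactions),
              dimnames = list(internal, names(net$reactions)))
  for (j in seq_along(net$reactions)) {
    st <- net$reactions[[j]]$stoich
    keep <- names(st) %in% internal
    if (any(keep)) N[names(st)[keep], j] <- st[keep]
  }
  N
}

#' @export
print.metabolic_network <- function(x, ...) {
  n_ext <- sum(x$metabolites$is_external)
  cat("<metabolic_network> ", nrow(x$metabolites) - n_ext,
      " internal metabolites (+", n_ext, " external), ",
      length(x$reactions), " reactions, compartments: ",
      paste(x$compartments, collapse = ", "), "\n", sep = "")
  invisible(x)
}
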