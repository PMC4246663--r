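#' Parse a model in the ScrumPy-style reaction dialect
#'
#' Dialect, one reaction per record:
#' \preformatted{
#'   Id: LHS -> RHS     # irreversible
#'   Id: LHS <> RHS     # reversible
#' }
#' Sides are `+`-separated terms `coef species` (coefficient optional,
#' default 1; decimals and rationals like `1/3` accepted). External
#' metabolites carry the prefix `x_`; compartments are encoded as metabolite
#' suffixes `_cyt`, `_chl`, `_mit`. Either side may be empty (pure
#' source/sink, e.g. a maintenance ATPase). Lines starting with `#` are
#' comments, except tag annotations of the form
#' `# @tags reaction_id: tag1,tag2` which attach reaction tags and survive a
#' serialize/parse round trip. A reaction touching an external metabolite is
#' tagged `transporter` automatically.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @param elements optional element side table (see [set_species_elements()]).
#' @param strict reject undeclared constructs (currently: duplicate ids and
#'   malformed records always error; `strict` reserved for future use).
#' @return a `metabolic_network`.
#' @export
parse_scrumpy <- function(text, elements = NULL, strict = TRUE) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  tags <- list()
  reactions <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (raw == "") next
    if (startsWith(raw, "#")) {
      m <- regmatches(raw, regexec("^#\\s*@tags\\s+([^:]+):\\s*(.+)$", raw))[[1]]
      if (length(m) == 3L)
        tags[[trimws(m[2])]] <- trimws(strsplit(m[3], ",")[[1]])
      next
    }
    m <- regmatches(raw, regexec("^([^:]+):(.*)$", raw))[[1]]
    if (length(m) != 3L)
      stop("line ", ln, ": expected 'Id: LHS -> RHS', got: ", raw)
    id <- trimws(m[2])
    body <- m[3]
    rev <- grepl("<>", body, fixed = TRUE)
    arrow <- if (rev) "<>" else "->"
    if (!rev && !grepl("->", body, fixed = TRUE))
      stop("line ", ln, ": reaction '", id, "' has no '->' or '<>' arrow")
    sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
    if (length(sides) > 2L)
      stop("line ", ln, ": more than one arrow in '", id, "'")
    lhs <- parse_side(sides[1], ln)
    rhs <- if (length(sides) == 2L) parse_side(sides[2], ln) else numeric()
    st <- c(-lhs, rhs)
    ## merge species appearing on both sides into net coefficients
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    if (length(st) == 0L)
      stop("line ", ln, ": reaction '", id, "' cancels to nothing")
    if (!is.null(reactions[[id]]))
      stop("line ", ln, ": duplicate reaction id '", id, "'")
    reactions[[id]] <- list(stoich = stats::setNames(as.numeric(st), names(st)),
                            reversible = rev)
  }
  if (length(reactions) == 0L) stop("no reactions found")
  for (id in names(reactions)) {
    tg <- tags[[id]] %||% character()
    if (any(startsWith(names(reactions[[id]]$stoich), "x_")))
      tg <- union(tg, "transporter")
    reactions[[id]]$tags <- tg
  }
  unknown <- setdiff(names(tags), names(reactions))
  if (strict && length(unknown))
    stop("@tags for undeclared reaction: ", unknown[1L])
  metabolic_network(reactions, elements = elements)
}

parse_side <- function(side, ln) {
  side <- trimws(side)
  if (side == "") return(numeric())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  if (any(terms == "")) stop("line ", ln, ": empty term")
  coefs <- numeric(length(terms))
  sp <- character(length(terms))
  for (i in seq_along(terms)) {
    parts <- strsplit(terms[i], "[[:space:]]+")[[1]]
    if (length(parts) == 1L) {
      coefs[i] <- 1
      sp[i] <- parts
    } else if (length(parts) == 2L) {
      coefs[i] <- parse_coef(parts[1], ln)
      sp[i] <- parts[2]
    } else stop("line ", ln, ": cannot parse term '", terms[i], "'")
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", sp[i]))
      stop("line ", ln, ": bad species id '", sp[i], "'")
    if (coefs[i] <= 0) stop("line ", ln, ": non-positive coefficient")
  }
  stats::setNames(coefs, sp)
}

parse_coef <- function(tok, ln) {
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    nd <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    return(nd[1] / nd[2])
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) stop("line ", ln, ": bad coefficient '", tok, "'")
  v
}

#' Serialize a network to the ScrumPy-style dialect
#'
#' Inverse of [parse_scrumpy()]: coefficients are printed with full precision
#' (`format(..., digits = 17)`, integers bare), tags as `# @tags` annotations,
#' so `parse_scrumpy(serialize_scrumpy(net))` reproduces stoichiometry,
#' reversibility and tags exactly.
#'
#' @param net a `metabolic_network`.
#' @return character vector of lines.
#' @export
serialize_scrumpy <- function(net) {
  fmt_side <- function(st) {
    if (length(st) == 0L) return("")
    paste(vapply(seq_along(st), function(i) {
      cf <- st[[i]]
      if (cf == 1) names(st)[i]
      else paste(format(cf, digits = 17, scientific = FALSE), names(st)[i])
    }, character(1)), collapse = " + ")
  }
  out <- character()
  for (r in net$reactions) {
    lhs <- -r$stoich[r$stoich < 0]
    rhs <- r$stoich[r$stoich > 0]
    arrow <- if (r$reversible) "<>" else "->"
    out <- c(out, paste0(r$id, ": ", fmt_side(lhs), " ", arrow, " ",
                         fmt_side(rhs)))
    tg <- r$tags
    if (any(startsWith(names(r$stoich), "x_")))
      tg <- setdiff(tg, "transporter")    # re-derived on parse
    if (length(tg))
      out <- c(out, paste0("# @tags ", r$id, ": ", paste(tg, collapse = ",")))
  }
  out
}

#' Load a stoichiometric model from a file
#'
#' @param path file path (or, for `format = "scrumpy"`, raw text via
#'   `text = TRUE` semantics is available through [parse_scrumpy()]).
#' @param format `"scrumpy"` or `"sbml"`.
#' @param elements optional element side table or path to one (TSV with
#'   columns metabolite_id, carbon_atoms, nitrogen_atoms).
#' @return a `metabolic_network`.
#' @export
load_model <- function(path, format = c("scrumpy", "sbml"), elements = NULL) {
  format <- match.arg(format)
  if (is.character(elements) && length(elements) == 1L)
    elements <- read_elements(elements)
  if (format == "scrumpy")
    parse_scrumpy(readLines(path, warn = FALSE), elements = elements)
  else
    read_sbml(path, elements = elements)
}

#' Read an SBML Level 3 core model
#'
#' Honors species `boundaryCondition` (mapped to the external `x_` role),
#' compartments, `speciesReference` stoichiometry and the reaction
#' `reversible` flag. fbc flux bounds are ignored: bounds come from the
#' analysis pipeline, not the file.
#'
#' @param path SBML file path.
#' @param elements optional element side table.
#' @return a `metabolic_network`.
#' @export
read_sbml <- function(path, elements = NULL) {
  doc <- xml2::read_xml(path)
  ns <- c(s = xml2::xml_ns(doc)[[1]])
  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0L) stop("SBML: no species found")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_bnd <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% c("true", "1")
  ext <- stats::setNames(sp_bnd, sp_id)
  comp <- stats::setNames(sp_comp, sp_id)

  rename <- function(id) {
    # map into the dialect's naming so downstream roles (external prefix,
    # compartment suffix) apply uniformly
    nm <- id
    if (isTRUE(ext[[id]])) {
      if (!startsWith(nm, "x_")) nm <- paste0("x_", nm)
    } else {
      cc <- comp[[id]]
      if (!is.na(cc) && cc %in% c("cyt", "chl", "mit") &&
          !grepl(paste0("_", cc, "$"), nm))
        nm <- paste0(nm, "_", cc)
    }
    nm
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) stop("SBML: no reactions found")
  reactions <- list()
  for (node in rx_nodes) {
    id <- xml2::xml_attr(node, "id")
    rev <- xml2::xml_attr(node, "reversible") %in% c("true", "1", NA)
    get_refs <- function(which, sign) {
      refs <- xml2::xml_find_all(node, paste0("./s:", which, "/s:speciesReference"), ns)
      if (length(refs) == 0L) return(numeric())
      s <- xml2::xml_attr(refs, "stoichiometry")
      s <- ifelse(is.na(s), 1, as.numeric(s))
      stats::setNames(sign * s,
                      vapply(xml2::xml_attr(refs, "species"), rename, character(1)))
    }
    st <- c(get_refs("listOfReactants", -1), get_refs("listOfProducts", +1))
    st <- tapply(st, names(st), sum)
    st <- st[st != 0]
    if (length(st) == 0L) stop("SBML: reaction '", id, "' cancels to nothing")
    if (!is.null(reactions[[id]])) stop("SBML: duplicate reaction id '", id, "'")
    reactions[[id]] <- list(stoich = stats::setNames(as.numeric(st), names(st)),
                            reversible = isTRUE(rev))
  }
  for (id in names(reactions))
    if (any(startsWith(names(reactions[[id]]$stoich), "x_")))
      reactions[[id]]$tags <- "transporter"
  metabolic_network(reactions, elements = elements)
}
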