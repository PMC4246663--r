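#' Minimal feasible photon flux by bisection
#'
#' Feasibility of the leaf programme is monotone in light (any excess can be
#' dissipated), so the minimum photon flux below which no solution exists is
#' located by bisection on LP feasibility.
#'
#' @param net a `metabolic_network`.
#' @param constraints a `leaf_constraints`; its `photon_flux` field is
#'   ignored and replaced by the bisection probe.
#' @param lo,hi bracket: the problem must be infeasible at `lo` and feasible
#'   at `hi`.
#' @param tol absolute tolerance on the returned threshold.
#' @return the threshold photon flux `p*`: feasible at `p*`, infeasible at
#'   `p* - tol`.
#' @export
find_min_photon_flux <- function(net, constraints, lo, hi, tol = 1e-6) {
  stopifnot(lo < hi, tol > 0)
  feasible <- function(p) {
    constraints$photon_flux <- p
    minimize_total_flux(net, constraints)$status == "optimal"
  }
  if (feasible(lo)) stop("lower bracket feasible")
  if (!feasible(hi)) stop("upper bracket infeasible")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' One-dimensional light scan
#'
#' Solves the minimal-total-flux programme at each photon flux; infeasible
#' points (below the minimal light) are recorded, not raised.
#'
#' @param net a `metabolic_network`.
#' @param constraints a `leaf_constraints` (output scenario fixed).
#' @param photon_values strictly increasing photon fluxes.
#' @return a `scan_result` with one r value (the scenario's).
#' @export
scan_light <- function(net, constraints, photon_values) {
  stopifnot(length(photon_values) >= 1L, !is.unsorted(photon_values, strictly = TRUE))
  sols <- lapply(photon_values, function(p) {
    constraints$photon_flux <- p
    minimize_total_flux(net, constraints)
  })
  new_scan_result(photon_values, constraints$output$r %||% NA_real_,
                  matrix(sols, nrow = length(photon_values), ncol = 1L), net)
}

#' Two-dimensional light x output-transition scan
#'
#' For each phloem fraction r the output is the convex mixture
#' `(1 - r) biomass + r phloem` (phloem equal-carbon scaled first), and the
#' light scan is repeated, giving the full i x r grid of minimal-flux
#' solutions.
#'
#' @param net a `metabolic_network`.
#' @param constraints a `leaf_constraints` template (its output field is
#'   replaced by the per-r mixture).
#' @param photon_values strictly increasing photon fluxes.
#' @param r_values increasing phloem fractions in \[0, 1\].
#' @param biomass pure-biomass `output_scenario`.
#' @param phloem pure-phloem `output_scenario`, already equal-carbon scaled.
#' @return a `scan_result`.
#' @export
scan_2d <- function(net, constraints, photon_values, r_values,
                    biomass, phloem) {
  stopifnot(!is.unsorted(photon_values, strictly = TRUE),
            !is.unsorted(r_values, strictly = TRUE),
            all(r_values >= 0), all(r_values <= 1))
  if (abs(phloem$carbon_rate - biomass$carbon_rate) >
      1e-9 * max(biomass$carbon_rate, 1))
    stop("phloem scenario is not equal-carbon scaled; call ",
         "scale_to_equal_carbon() first")
  grid <- matrix(vector("list", length(photon_values) * length(r_values)),
                 nrow = length(photon_values), ncol = length(r_values))
  for (k in seq_along(r_values)) {
    constraints$output <- mix_outputs(biomass, phloem, r_values[k])
    for (i in seq_along(photon_values)) {
      constraints$photon_flux <- photon_values[i]
      grid[[i, k]] <- minimize_total_flux(net, constraints)
    }
  }
  new_scan_result(photon_values, r_values, grid, net)
}

new_scan_result <- function(photon_values, r_values, grid, net) {
  ## feasibility must be monotone in light within each r column
  for (k in seq_len(ncol(grid))) {
    st <- vapply(grid[, k], function(s) s$status == "optimal", logical(1))
    if (any(st) && any(!st[seq(which(st)[1L], length(st))]))
      stop("infeasible point above the feasibility threshold at r = ",
           r_values[k], "; feasibility should be monotone in light")
  }
  structure(list(photon_values = photon_values, r_values = r_values,
                 solutions = grid, reaction_ids = names(net$reactions)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  n_ok <- sum(vapply(x$solutions, function(s) s$status == "optimal", logical(1)))
  cat("<scan_result> ", length(x$photon_values), " light x ",
      length(x$r_values), " r points; ", n_ok, "/", length(x$solutions),
      " feasible\n", sep = "")
  invisible(x)
}

scan_slice <- function(scan, r) {
  k <- match(TRUE, abs(scan$r_values - r) < 1e-12)
  if (is.na(k)) stop("r = ", r, " is not a grid value of this scan")
  scan$solutions[, k]
}

#' Net-flux table of a scan slice
#'
#' @param scan a `scan_result`.
#' @param r which r slice (default: the first).
#' @return numeric matrix, reactions x photon values; infeasible points NA.
#' @export
flux_table <- function(scan, r = scan$r_values[1]) {
  sols <- scan_slice(scan, r)
  out <- matrix(NA_real_, nrow = length(scan$reaction_ids),
                ncol = length(scan$photon_values),
                dimnames = list(scan$reaction_ids,
                                format(scan$photon_values, digits = 12)))
  for (i in seq_along(sols))
    if (sols[[i]]$status == "optimal")
      out[names(sols[[i]]$net_flux), i] <- sols[[i]]$net_flux
  out
}

## Active reaction set of one solution under the scale-aware threshold.
active_set <- function(sol, tol = NULL) {
  if (sol$status != "optimal") return(character())
  if (is.null(tol)) tol <- 1e-7 * max(1, sol$photon_flux)
  names(sol$net_flux)[abs(sol$net_flux) > tol]
}

#' Detect constant-flux-pattern regions along the light axis
#'
#' A region is a contiguous run of light intensities over which the active
#' reaction set of the optimal solution is unchanged; transitions are placed
#' where the symmetric difference between consecutive active sets reaches
#' `min_change`. Breakpoints are reported at the midpoint of the bracketing
#' grid interval and regions are labelled A, B, ... from low light.
#'
#' @param scan a `scan_result`.
#' @param r which r slice to analyse.
#' @param min_change minimum size of the active-set symmetric difference
#'   that counts as a transition (default 1: any change). `Inf` gives a
#'   single region.
#' @param tol activity threshold override (default scale-aware,
#'   `1e-7 * max(1, photon_flux)` per point).
#' @return a `region_partition`: `breakpoints`, `labels`, `point_labels`
#'   (region label per feasible grid point), `change_sizes`.
#' @export
detect_regions <- function(scan, r = scan$r_values[1], min_change = 1,
                           tol = NULL) {
  sols <- scan_slice(scan, r)
  feas <- vapply(sols, function(s) s$status == "optimal", logical(1))
  if (sum(feas) < 3L) stop("need at least 3 feasible points to detect regions")
  idx <- which(feas)
  sets <- lapply(sols[idx], active_set, tol = tol)
  p <- scan$photon_values[idx]
  sizes <- vapply(seq_len(length(sets) - 1L), function(i) {
    length(union(setdiff(sets[[i]], sets[[i + 1L]]),
                 setdiff(sets[[i + 1L]], sets[[i]])))
  }, numeric(1))
  cut <- which(sizes >= min_change)
  breakpoints <- (p[cut] + p[cut + 1L]) / 2
  n_regions <- length(cut) + 1L
  labels <- make_region_labels(n_regions)
  point_region <- findInterval(p, breakpoints) + 1L
  structure(list(breakpoints = breakpoints, labels = labels,
                 point_labels = labels[point_region],
                 photon_values = p, change_sizes = sizes, r = r),
            class = "region_partition")
}

make_region_labels <- function(n) {
  if (n <= 26L) LETTERS[seq_len(n)]
  else paste0(LETTERS[(seq_len(n) - 1L) %/% 26L],
              LETTERS[(seq_len(n) - 1L) %% 26L + 1L])
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> ", length(x$labels), " regions (",
      paste(x$labels, collapse = ", "), ") with breakpoints at ",
      paste(format(x$breakpoints, digits = 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Within-region linearity of fluxes against light
#'
#' Inside a constant-active-set region the optimal basis is fixed, so every
#' flux is an affine function of the photon flux. This fits a line per
#' reaction per region (3+ points) and reports the worst relative residual.
#'
#' @param scan a `scan_result`.
#' @param regions a `region_partition` from [detect_regions()].
#' @param r the slice analysed.
#' @return maximum over reactions and regions of
#'   `max |residual| / max(1, max |flux|)`.
#' @export
region_linearity <- function(scan, regions, r = regions$r) {
  sols <- scan_slice(scan, r)
  feas <- vapply(sols, function(s) s$status == "optimal", logical(1))
  p <- scan$photon_values[feas]
  V <- vapply(sols[feas], function(s) s$net_flux, numeric(length(scan$reaction_ids)))
  worst <- 0
  for (lab in regions$labels) {
    in_reg <- regions$point_labels == lab
    if (sum(in_reg) < 3L) next
    X <- cbind(1, p[in_reg])
    Y <- t(V[, in_reg, drop = FALSE])
    fit <- stats::lm.fit(X, Y)
    res <- abs(fit$residuals)
    rel <- max(res) / max(1, max(abs(Y)))
    worst <- max(worst, rel)
  }
  worst
}

#' Relative-difference surface for one reaction
#'
#' For each grid point the flux is expressed relative to the same flux at
#' the same light for the reference output mixture:
#' `D = J(i, r) / J(i, r_ref) - 1`. Cells whose reference flux is below the
#' activity threshold are undefined (NA), not infinite; infeasible cells are
#' NA as well.
#'
#' @param scan a `scan_result` (2-D).
#' @param reaction reaction id.
#' @param reference_r reference phloem fraction; must be a grid value
#'   (default 0.5).
#' @param tol activity threshold override for the reference flux.
#' @return a `relative_difference_grid`: matrix `D` (photon x r) plus the
#'   axes and reference.
#' @export
relative_difference <- function(scan, reaction, reference_r = 0.5,
                                tol = NULL) {
  if (!reaction %in% scan$reaction_ids)
    stop("no reaction '", reaction, "' in scan")
  kref <- match(TRUE, abs(scan$r_values - reference_r) < 1e-12)
  if (is.na(kref))
    stop("reference_r = ", reference_r, " is not a grid value of this scan")
  D <- matrix(NA_real_, nrow = length(scan$photon_values),
              ncol = length(scan$r_values),
              dimnames = list(format(scan$photon_values, digits = 12),
                              format(scan$r_values, digits = 12)))
  for (i in seq_along(scan$photon_values)) {
    ref <- scan$solutions[[i, kref]]
    if (ref$status != "optimal") next
    tt <- tol %||% (1e-7 * max(1, ref$photon_flux))
    jref <- ref$net_flux[[reaction]]
    if (abs(jref) <= tt) next   # undefined reference: leave the row NA
    for (k in seq_along(scan$r_values)) {
      s <- scan$solutions[[i, k]]
      if (s$status == "optimal")
        D[i, k] <- s$net_flux[[reaction]] / jref - 1
    }
  }
  structure(list(D = D, photon_values = scan$photon_values,
                 r_values = scan$r_values, reference_r = reference_r,
                 reaction = reaction),
            class = "relative_difference_grid")
}

#' Flag where a light scan has become linear at its upper end
#'
#' Operationalises "scan up to the point beyond which all flux responses
#' remain linear": checks that over the last three grid points every flux
#' changes with constant slope.
#'
#' @param scan a `scan_result`.
#' @param r slice to examine.
#' @param tol relative slope-change tolerance.
#' @return TRUE when the inter-point slopes of every flux agree over the
#'   final two intervals.
#' @export
scan_upper_end_linear <- function(scan, r = scan$r_values[1], tol = 1e-6) {
  sols <- scan_slice(scan, r)
  feas <- vapply(sols, function(s) s$status == "optimal", logical(1))
  if (sum(feas) < 3L) return(FALSE)
  idx <- utils::tail(which(feas), 3L)
  p <- scan$photon_values[idx]
  V <- vapply(sols[idx], function(s) s$net_flux,
              numeric(length(scan$reaction_ids)))
  s1 <- (V[, 2] - V[, 1]) / (p[2] - p[1])
  s2 <- (V[, 3] - V[, 2]) / (p[3] - p[2])
  max(abs(s2 - s1)) <= tol * max(1, max(abs(V)))
}

#' Logarithmically spaced light grid
#' @param lo,hi positive range ends.
#' @param n number of points.
#' @export
light_grid <- function(lo, hi, n) {
  stopifnot(lo > 0, hi > lo, n >= 2L)
  exp(seq(log(lo), log(hi), length.out = n))
}
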