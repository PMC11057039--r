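#' Define a particle species
#'
#' A species is a particle kind: a label, a hard-sphere (hydrodynamic) radius
#' and a copy number. Species rows are the unit of all composition tables.
#'
#' @param label Species name.
#' @param radius Hard-sphere radius in nm (R_H for tracers, R_c for crowders).
#' @param count Non-negative integer copy number.
#' @return A one-row data frame with columns `label`, `radius`, `count`.
#' @examples
#' species("ficoll70", 5.1, 100)
#' @export
species <- function(label, radius, count) {
  if (!is.character(label) || length(label) != 1 || is.na(label) || !nzchar(label))
    stop("label must be a non-empty string")
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("radius must be a single positive number (nm)")
  if (!is.numeric(count) || length(count) != 1 || !is.finite(count) ||
      count < 0 || count != round(count))
    stop("count must be a single non-negative integer")
  data.frame(label = label, radius = radius, count = as.integer(count),
             stringsAsFactors = FALSE)
}

#' Construct a particle configuration
#'
#' Positions and radii of all particles in a cubic periodic box at one
#' instant. Construction validates that the box accommodates the particles
#' and (optionally) that no pair overlaps under the minimum-image convention.
#'
#' @param box_edge Cubic box edge in nm; must exceed twice the largest
#'   particle diameter.
#' @param labels Character vector of per-particle species labels.
#' @param radii Numeric vector of per-particle radii (nm).
#' @param positions N x 3 matrix of coordinates (nm); wrapped into the box.
#' @param check_overlaps If `TRUE` (default), fail on any overlapping pair.
#' @return An object of class `configuration`.
#' @export
configuration <- function(box_edge, labels, radii, positions,
                          check_overlaps = TRUE) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (length(labels) != n || length(radii) != n)
    stop("labels, radii and positions disagree on particle count")
  if (any(radii <= 0)) stop("all radii must be positive")
  if (!is.finite(box_edge) || box_edge <= 0) stop("box_edge must be positive")
  if (n > 0 && box_edge <= 4 * max(radii))
    stop("box edge must exceed twice the largest particle diameter")
  positions <- positions %% box_edge
  if (check_overlaps && n > 1 &&
      cpp_min_gap(positions, as.numeric(radii), box_edge) < -1e-9)
    stop("configuration contains overlapping particles")
  structure(list(box_edge = box_edge,
                 labels = as.character(labels),
                 radii = as.numeric(radii),
                 positions = positions),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration> %d particles, box edge %.3f nm\n",
              nrow(x$positions), x$box_edge))
  tab <- table(x$labels)
  for (lbl in names(tab)) {
    r <- unique(x$radii[x$labels == lbl])
    cat(sprintf("  %-16s n = %4d  radius %s nm\n", lbl, tab[[lbl]],
                paste(format(r, digits = 3), collapse = ", ")))
  }
  cat(sprintf("  phi_occ (all species) = %.4f\n", occupied_fraction(x)))
  invisible(x)
}

#' Occupied volume fraction of a configuration
#'
#' Sum of hard-core sphere volumes of the selected species divided by the
#' box volume.
#'
#' @param config A [configuration()].
#' @param species_subset Character vector of labels to include; `NULL`
#'   (default) includes every particle. An empty vector yields 0.
#' @return Occupied volume fraction (decimal).
#' @export
occupied_fraction <- function(config, species_subset = NULL) {
  stopifnot(inherits(config, "configuration"))
  if (is.null(species_subset)) {
    keep <- rep(TRUE, length(config$radii))
  } else {
    if (length(species_subset) == 0) return(0)
    unknown <- setdiff(species_subset, unique(config$labels))
    if (length(unknown) > 0)
      stop("unknown species label(s): ", paste(unknown, collapse = ", "))
    keep <- config$labels %in% species_subset
  }
  sum((4 / 3) * pi * config$radii[keep]^3) / config$box_edge^3
}

#' Smallest interparticle gap in a configuration
#'
#' Minimum over all pairs of (center distance - contact distance), using the
#' minimum-image convention. Negative values signal an overlap.
#'
#' @param config A [configuration()].
#' @return Gap in nm (`Inf` for fewer than two particles).
#' @export
min_pair_gap <- function(config) {
  stopifnot(inherits(config, "configuration"))
  if (nrow(config$positions) < 2) return(Inf)
  cpp_min_gap(config$positions, config$radii, config$box_edge)
}
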