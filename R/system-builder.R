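# Initial-configuration builders. Random sequential addition (RSA), largest
# species first, gives unbiased dilute-to-moderate packings; dense targets
# (where RSA jams) fall back to a compression protocol: insert in an enlarged
# box and shrink stepwise with hard-core overlap relaxation.

.rsa_max_attempts <- 1e5

#' Build a non-overlapping crowder/tracer mixture
#'
#' Places the crowder species at a target occupied volume fraction together
#' with one or more tracer species in a cubic periodic box, by random
#' sequential addition (largest species first). Either `box_edge` is supplied
#' and the crowder count is derived from `target_phi_occ`, or the crowder
#' `count` is supplied and the box edge is derived.
#'
#' @param crowder A [species()] row. Its `count` is used when the box edge
#'   is derived, and recomputed from `target_phi_occ` when `box_edge` is
#'   given; see Details.
#' @param tracers A data frame of [species()] rows (may be empty).
#' @param target_phi_occ Target crowder occupied volume fraction (decimal,
#'   `0 <= phi < 0.55`).
#' @param box_edge Box edge in nm; required when `target_phi_occ = 0` or when
#'   the crowder count should be derived from it.
#' @param seed Integer seed; the same seed and arguments give a bit-identical
#'   configuration.
#'
#' @details With `box_edge = NULL` the edge is chosen as
#'   `(count * v_c / phi)^(1/3)` so the achieved crowder fraction equals the
#'   target exactly. With a given `box_edge` the count is rounded, keeping the
#'   achieved fraction within 0.5% (absolute) of the target or failing.
#'
#' @return A [configuration()] with attributes `phi_occ_crowder` (achieved),
#'   `seed`, and `build_log` (insertion bookkeeping).
#' @export
build_mixture <- function(crowder, tracers = NULL, target_phi_occ,
                          box_edge = NULL, seed = 1) {
  stopifnot(is.data.frame(crowder), nrow(crowder) == 1)
  if (!is.numeric(target_phi_occ) || target_phi_occ < 0 || target_phi_occ >= 0.55)
    stop("target_phi_occ must be in [0, 0.55)")
  v_c <- (4 / 3) * pi * crowder$radius^3
  if (is.null(box_edge)) {
    if (target_phi_occ <= 0)
      stop("box_edge is required when target_phi_occ = 0")
    if (crowder$count < 1)
      stop("crowder count must be >= 1 to derive the box edge")
    n_c <- crowder$count
    box_edge <- (n_c * v_c / target_phi_occ)^(1 / 3)
  } else {
    n_c <- as.integer(round(target_phi_occ * box_edge^3 / v_c))
    achieved <- n_c * v_c / box_edge^3
    if (abs(achieved - target_phi_occ) > 0.005)
      stop("cannot match target_phi_occ within 0.5% with integer counts in ",
           "this box; adjust box_edge")
  }
  tab <- rbind(
    data.frame(label = crowder$label, radius = crowder$radius,
               count = n_c, stringsAsFactors = FALSE),
    if (!is.null(tracers) && nrow(tracers) > 0)
      tracers[, c("label", "radius", "count")]
  )
  cfg <- .build_from_table(tab, box_edge, seed)
  attr(cfg, "phi_occ_crowder") <- n_c * v_c / box_edge^3
  cfg
}

#' Build a polydisperse cytoplasm-like configuration
#'
#' Scales the box so that the macromolecule species of `table` occupy exactly
#' `target_phi_occ` of the volume, then adds the metabolite tracers on top.
#' The packaged default composition (see
#' `system.file("extdata", "cytoplasm_composition_synthetic.csv",
#' package = "crowdiff")`) is a constructed stand-in spanning 1.7-13 nm with
#' a GFP-like and a ribosome-like species; supply your own table for fidelity
#' to a particular proteome.
#'
#' @param table Composition data frame (`label`, `radius`, `count`), counts
#'   >= 1 per listed species.
#' @param metabolite A [species()] row for the tracers (e.g. 50 copies of a
#'   0.8 nm metabolite).
#' @param target_phi_occ Macromolecular occupied volume fraction (decimal).
#' @param seed Integer seed.
#' @param count_scale Multiplier applied to the table counts (rounded, floor
#'   1) to scale system size up or down at fixed composition.
#' @return A [configuration()] with attribute `phi_occ_macromolecules`.
#' @export
build_cytoplasm <- function(table, metabolite, target_phi_occ = 0.426,
                            seed = 1, count_scale = 1) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  if (any(table$count < 1)) stop("each listed species needs count >= 1")
  if (target_phi_occ <= 0 || target_phi_occ >= 0.55)
    stop("target_phi_occ must be in (0, 0.55)")
  tab <- table[, c("label", "radius", "count")]
  if (count_scale != 1)
    tab$count <- pmax(1L, as.integer(round(tab$count * count_scale)))
  vols <- (4 / 3) * pi * tab$radius^3 * tab$count
  box_edge <- (sum(vols) / target_phi_occ)^(1 / 3)
  full <- rbind(tab, metabolite[, c("label", "radius", "count")])
  cfg <- .build_from_table(full, box_edge, seed)
  attr(cfg, "phi_occ_macromolecules") <- sum(vols) / box_edge^3
  cfg
}

#' Default packaged cytoplasm composition (synthetic stand-in)
#'
#' @return Species data frame read from the packaged CSV.
#' @export
default_cytoplasm_composition <- function() {
  read_species_table(system.file("extdata", "cytoplasm_composition_synthetic.csv",
                                 package = "crowdiff", mustWork = TRUE))
}

# Shared insertion engine: RSA largest-first; on failure (or dense targets
# where RSA is known to jam) restart with the compression protocol.
.build_from_table <- function(tab, box_edge, seed) {
  tab <- tab[tab$count > 0, , drop = FALSE]
  labels <- rep(tab$label, tab$count)
  radii <- rep(tab$radius, tab$count)
  ord <- order(radii, decreasing = TRUE)
  labels <- labels[ord]; radii <- radii[ord]
  if (box_edge <= 4 * max(radii))
    stop("box edge must exceed twice the largest particle diameter; ",
         "increase counts or lower target_phi_occ")
  phi_total <- sum((4 / 3) * pi * radii^3) / box_edge^3
  set.seed(seed)
  used_compression <- FALSE
  res <- if (phi_total <= 0.45) cpp_rsa(radii, box_edge, .rsa_max_attempts)
         else list(ok = FALSE, failed_at = 0)
  if (!res$ok) {
    used_compression <- TRUE
    # Insert into a box inflated to phi ~ 0.25, then shrink by 0.5% stages.
    l_start <- max(box_edge, (sum((4 / 3) * pi * radii^3) / 0.25)^(1 / 3))
    res0 <- cpp_rsa(radii, l_start, .rsa_max_attempts)
    if (!res0$ok)
      stop("packing infeasible: random insertion failed for species '",
           labels[res0$failed_at], "' even in the inflated box")
    comp <- cpp_compress(res0$positions, radii, 1 / radii, l_start, box_edge,
                         0.995, 200)
    if (!isTRUE(comp$ok))
      stop("packing infeasible: compression stalled at box edge ",
           format(comp$L, digits = 6), " nm (target ",
           format(box_edge, digits = 6), " nm)")
    res <- list(ok = TRUE, positions = comp$positions)
  }
  cfg <- configuration(box_edge, labels, radii, res$positions,
                       check_overlaps = TRUE)
  attr(cfg, "seed") <- seed
  attr(cfg, "build_log") <- list(seed = seed, n_particles = length(radii),
                                 phi_occ_total = phi_total,
                                 method = if (used_compression) "compression"
                                          else "rsa")
  cfg
}
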