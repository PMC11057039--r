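# Plain-text interchange: species tables as CSV, configurations and
# trajectories as extended XYZ (comment line carries the box edge; per-atom
# columns label, x, y, z, radius, all in nm).

#' Read a species table
#'
#' CSV with header `label,radius_nm,count` or, alternatively,
#' `label,radius_nm,concentration_mM` together with a box edge from which
#' integer counts are derived (the two count specifications are mutually
#' exclusive).
#'
#' @param path CSV file path.
#' @param box_edge Box edge in nm, required when the table carries
#'   `concentration_mM` instead of `count`.
#' @return Data frame with columns `label`, `radius`, `count`.
#' @export
read_species_table <- function(path, box_edge = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("label", "radius_nm") %in% names(df)))
    stop("species table needs columns label, radius_nm")
  has_count <- "count" %in% names(df)
  has_conc <- "concentration_mM" %in% names(df)
  if (has_count == has_conc)
    stop("species table must have exactly one of count / concentration_mM")
  if (has_conc) {
    if (is.null(box_edge))
      stop("box_edge is required to convert concentrations to counts")
    # c [mM] -> number density [1/nm^3] -> integer copies in the box
    rho <- df$concentration_mM * 1e-3 * .NAvogadro / 1e24
    df$count <- as.integer(round(rho * box_edge^3))
  }
  out <- data.frame(label = as.character(df$label), radius = df$radius_nm,
                    count = as.integer(df$count), stringsAsFactors = FALSE)
  if (any(out$radius <= 0)) stop("radii must be positive")
  if (any(out$count < 0)) stop("counts must be non-negative")
  out
}

#' Write a species table
#'
#' @param table Data frame with columns `label`, `radius`, `count`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path) {
  out <- data.frame(label = table$label, radius_nm = table$radius,
                    count = table$count)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a configuration as extended XYZ
#'
#' Line 1: particle count; line 2: `box_edge_nm=<L>` plus free-form
#' `key=value` metadata; then one line per atom: label, x, y, z, radius (nm).
#'
#' @param config A [configuration()].
#' @param path Output path.
#' @param comment Named character/numeric vector of extra `key=value`
#'   metadata for the comment line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(config, path, comment = NULL) {
  stopifnot(inherits(config, "configuration"))
  n <- nrow(config$positions)
  meta <- c(sprintf("box_edge_nm=%.10g", config$box_edge),
            if (!is.null(comment))
              sprintf("%s=%s", names(comment), as.character(comment)))
  lines <- c(as.character(n), paste(meta, collapse = " "),
             sprintf("%s %.10g %.10g %.10g %.10g", config$labels,
                     config$positions[, 1], config$positions[, 2],
                     config$positions[, 3], config$radii))
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended XYZ configuration
#'
#' @param path File written by [write_xyz()] (or any XYZ whose comment line
#'   contains `box_edge_nm=<L>` and whose atom lines carry a trailing radius
#'   column).
#' @param check_overlaps Passed to [configuration()].
#' @return A [configuration()].
#' @export
read_xyz <- function(path, check_overlaps = TRUE) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  m <- regmatches(lines[2], regexec("box_edge_nm=([0-9.eE+-]+)", lines[2]))[[1]]
  if (length(m) < 2) stop("comment line lacks box_edge_nm=<L>")
  box_edge <- as.numeric(m[2])
  if (n == 0)
    return(configuration(box_edge, character(0), numeric(0),
                         matrix(0, 0, 3), check_overlaps = FALSE))
  body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  labels <- vapply(body, `[`, character(1), 1)
  num <- t(vapply(body, function(f) as.numeric(f[2:5]), numeric(4)))
  configuration(box_edge, labels, num[, 4], num[, 1:3],
                check_overlaps = check_overlaps)
}

#' Write a slowdown curve (abscissa, D/D0, sigma) as CSV
#'
#' @param curve Data frame with an abscissa column (`phi_occ` or `r_h_nm`),
#'   `d_ratio` and optionally `sigma`.
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(curve, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a slowdown curve CSV
#'
#' @param path CSV with an abscissa column plus `d_ratio` (and optional
#'   `sigma`); `#` lines are ignored.
#' @return Data frame.
#' @export
read_curve_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
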