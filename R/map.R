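#' Haldane map function
#'
#' Converts a genetic distance into a recombination fraction under the
#' Haldane (no-interference) map function, `c = 0.5 * (1 - exp(-2 d))` with
#' `d` in Morgans.
#'
#' @param distance_cM Non-negative genetic distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_recomb(10)   # ~0.0906
#' @export
haldane_recomb <- function(distance_cM) {
  if (any(!is.finite(distance_cM)) || any(distance_cM < 0)) {
    stop("distance_cM must be finite and non-negative")
  }
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

#' Construct a genetic map of bi-allelic markers
#'
#' @param positions Strictly increasing marker positions in cM.
#' @param marker_ids Optional marker labels (default `M1, M2, ...`).
#' @param qtl_position Optional true QTL position in cM (simulation truth;
#'   it need not coincide with a marker).
#' @return An object of class `genetic_map`: a list with `positions`,
#'   `marker_ids`, `qtl_position` and `n_markers`.
#' @export
genetic_map <- function(positions, marker_ids = NULL, qtl_position = NULL) {
  positions <- as.numeric(positions)
  if (length(positions) < 1L || any(!is.finite(positions))) {
    stop("positions must be finite")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_along(positions))
  if (length(marker_ids) != length(positions)) {
    stop("marker_ids and positions lengths differ")
  }
  if (!is.null(qtl_position)) {
    qtl_position <- as.numeric(qtl_position)
    stopifnot(is.finite(qtl_position))
  }
  structure(
    list(positions = positions,
         marker_ids = as.character(marker_ids),
         qtl_position = qtl_position,
         n_markers = length(positions)),
    class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d markers spanning %.4g-%.4g cM\n",
              x$n_markers, min(x$positions), max(x$positions)))
  if (!is.null(x$qtl_position)) {
    cat(sprintf("  QTL at %.4g cM\n", x$qtl_position))
  }
  invisible(x)
}

#' Evenly spaced map for a simulation scenario
#'
#' Markers at `0, density, 2*density, ...` covering `n_markers` loci.
#'
#' @param n_markers Number of markers.
#' @param density_cM Spacing between adjacent markers in cM.
#' @param qtl_position True QTL position in cM.
#' @return A `genetic_map`.
#' @export
scenario_map <- function(n_markers = 40L, density_cM = 0.25,
                         qtl_position = 3.35) {
  genetic_map(positions = (seq_len(n_markers) - 1) * density_cM,
              qtl_position = qtl_position)
}

# Recombination fractions between adjacent loci of a position vector.
adjacent_recomb <- function(positions) {
  if (length(positions) < 2L) return(numeric(0))
  haldane_recomb(diff(positions))
}

# Midpoints of the marker intervals (the tested positions of both scans).
interval_midpoints <- function(map) {
  p <- map$positions
  (p[-length(p)] + p[-1]) / 2
}

# Index of the marker interval containing position x (1-based; x strictly
# inside the map span).
interval_index <- function(map, x) {
  findInterval(x, map$positions, rightmost.closed = TRUE)
}
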