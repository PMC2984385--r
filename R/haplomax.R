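# Haplotype-dose association scan.
#
# In every marker interval, each observed flanking-marker haplotype is
# tested in turn against all the others with the linear model
# y = sire effect + gamma * dose(h) + e, where dose(h) in {0, 1, 2} counts
# the copies of h among the progeny's two window haplotypes. The interval
# statistic is the maximum over haplotypes of the 1-df F test of gamma, and
# the estimated QTL position is the midpoint of the interval with the
# largest statistic. Because the sire effect is a fixed categorical
# nuisance, all fits reduce to within-family centring followed by a
# single-regressor least-squares step, which is what the code does.

# integer code of the window haplotype of each row of M over columns idx
hap_codes <- function(M, idx) {
  code <- integer(nrow(M))
  for (k in seq_along(idx)) code <- code + M[, idx[k]] * 2L^(k - 1L)
  code
}

# haplotype string in map order (marker 1 first = lowest bit first)
code_to_string <- function(code, width) {
  vapply(code, function(cc) {
    paste(as.integer(intToBits(cc))[seq_len(width)], collapse = "")
  }, character(1))
}

# centre a vector (or the columns of a matrix) on sire-family means
center_by_sire <- function(v, sire, n_sires) {
  cnt <- tabulate(sire, n_sires)
  if (is.matrix(v)) {
    v - (rowsum(v, sire) / cnt)[sire, , drop = FALSE]
  } else {
    v - (rowsum(v, sire) / cnt)[sire]
  }
}

#' Haplotype dose of a progeny
#'
#' Number of copies (0, 1 or 2) of window haplotype `h` among the progeny's
#' paternal and maternal haplotypes over the markers of interval `interval`.
#'
#' @param design A `halfsib_design`.
#' @param h 0/1 allele vector over the window markers.
#' @param interval Marker-interval index (window = its flanking markers,
#'   widened to `n_flanking = 4` if `h` has length 4).
#' @return Integer vector of doses, one per progeny.
#' @export
haplotype_dose <- function(design, h, interval) {
  n_flanking <- length(h)
  x <- interval_midpoints(design$map)[interval]
  idx <- window_markers(design$map, x, as.integer(n_flanking))
  stopifnot(length(idx) == length(h))
  target <- freq_index(h) - 1L
  (hap_codes(design$pat, idx) == target) +
    (hap_codes(design$mat, idx) == target)
}

# Precompute the within-family-centred dose matrix of every (interval,
# observed haplotype) pair; shared by the scan and the permutation null.
haplomax_prepare <- function(design, n_flanking = 2L) {
  map <- design$map
  mids <- interval_midpoints(map)
  n <- design$n_progeny
  cols <- list(); col_interval <- integer(0); col_hap <- character(0)
  for (j in seq_along(mids)) {
    idx <- window_markers(map, mids[j], n_flanking)
    cp <- hap_codes(design$pat, idx)
    cm <- hap_codes(design$mat, idx)
    for (h in sort(unique(c(cp, cm)))) {
      dose <- (cp == h) + (cm == h)
      if (all(dose == dose[1L])) next   # absent or universal: no contrast
      cols[[length(cols) + 1L]] <- dose
      col_interval <- c(col_interval, j)
      col_hap <- c(col_hap, code_to_string(h, length(idx)))
    }
  }
  D <- if (length(cols)) matrix(unlist(cols), nrow = n) else
    matrix(numeric(0), nrow = n)
  Dtil <- center_by_sire(D, design$sire, design$n_sires)
  css <- colSums(Dtil^2)
  keep <- css > 1e-10
  list(Dtil = Dtil[, keep, drop = FALSE], css = css[keep],
       col_interval = col_interval[keep], col_hap = col_hap[keep],
       midpoints = mids, df = n - design$n_sires - 1L,
       sire = design$sire, n_sires = design$n_sires)
}

# F statistics of every kept (interval, haplotype) column for a phenotype
# vector (or a matrix of phenotype columns), given the preparation object.
haplomax_stats <- function(prep, y) {
  ytil <- center_by_sire(y, prep$sire, prep$n_sires)
  if (!is.matrix(ytil)) ytil <- matrix(ytil, ncol = 1L)
  RSS0 <- colSums(ytil^2)
  num <- crossprod(prep$Dtil, ytil)^2 / prep$css   # K x P
  num / (sweep(-num, 2, RSS0, "+") / prep$df)
}

#' HaploMax scan
#'
#' Runs the haplotype-dose association analysis in every marker interval
#' and returns the per-interval maximised F statistics together with the
#' estimated QTL position (the midpoint of the interval with the largest
#' statistic; ties broken towards the smallest interval index).
#'
#' @param design A `halfsib_design` with phenotypes.
#' @param n_flanking Window size: 2 (the interval's flanking markers) or 4
#'   (two markers on each side, truncated at chromosome ends).
#' @return An object of class `scan_result` with elements `midpoints`,
#'   `stat` (per-interval max F), `best_hap`, `s_hat`, `max_stat`,
#'   `interval_hat` and `method = "haplomax"`.
#' @export
haplomax_scan <- function(design, n_flanking = 2L) {
  if (is.null(design$y)) stop("design has no phenotypes")
  if (design$n_sires < 2L) stop("need at least 2 sires")
  prep <- haplomax_prepare(design, n_flanking)
  mids <- prep$midpoints
  stat <- numeric(length(mids))
  best_hap <- rep(NA_character_, length(mids))
  if (ncol(prep$Dtil) > 0L) {
    F <- haplomax_stats(prep, design$y)[, 1L]
    for (j in seq_along(mids)) {
      sel <- which(prep$col_interval == j)
      if (!length(sel)) next
      w <- sel[which.max(F[sel])]
      stat[j] <- F[w]
      best_hap[j] <- prep$col_hap[w]
    }
  }
  interval_hat <- which.max(stat)   # first maximum: smallest interval index
  structure(
    list(method = "haplomax", n_flanking = as.integer(n_flanking),
         midpoints = mids, stat = stat, best_hap = best_hap,
         interval_hat = interval_hat, s_hat = mids[interval_hat],
         max_stat = stat[interval_hat]),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result (%s, %d-marker windows): s_hat = %.4g cM, max stat = %.4g\n",
              x$method, x$n_flanking, x$s_hat, x$max_stat))
  invisible(x)
}
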