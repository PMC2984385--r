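# Sire-to-progeny transmission probabilities.
#
# For a tested position x, the probability that the allele the sire
# transmitted descends from each of his two chromosomes is computed exactly
# under Haldane/no-interference from the grand-parental origins at the
# nearest informative (sire-heterozygous) markers flanking x: conditioning
# on the origins at the left and right flank, the two possible origins at x
# have probabilities proportional to the crossover pattern probabilities
# over the two sub-intervals.

#' Transmission probabilities at a tested position
#'
#' @param sire_h1,sire_h2 The sire's two phased marker haplotypes (0/1).
#' @param progeny_pat The progeny's paternally transmitted haplotype.
#' @param x Tested position in cM.
#' @param map The `genetic_map` of the markers.
#' @return `c(p1, p2)`: probability that the transmitted allele at `x`
#'   descends from sire chromosome 1 / 2; sums to 1 exactly. With no
#'   informative marker the uninformative `(0.5, 0.5)` is returned.
#' @export
transmission_prob <- function(sire_h1, sire_h2, progeny_pat, x, map) {
  stopifnot(length(sire_h1) == map$n_markers,
            length(sire_h2) == map$n_markers,
            length(progeny_pat) == map$n_markers)
  inf <- which(sire_h1 != sire_h2)
  if (length(inf) == 0L) return(c(0.5, 0.5))
  pos <- map$positions[inf]
  origin <- ifelse(progeny_pat[inf] == sire_h1[inf], 1L, 2L)

  hit <- match(x, pos)
  if (!is.na(hit)) {
    return(if (origin[hit] == 1L) c(1, 0) else c(0, 1))
  }
  iL <- findInterval(x, pos)
  w1 <- 1; w2 <- 1
  if (iL >= 1L) {
    cL <- haldane_recomb(x - pos[iL])
    w1 <- w1 * (if (origin[iL] == 1L) 1 - cL else cL)
    w2 <- w2 * (if (origin[iL] == 2L) 1 - cL else cL)
  }
  if (iL < length(pos)) {
    cR <- haldane_recomb(pos[iL + 1L] - x)
    w1 <- w1 * (if (origin[iL + 1L] == 1L) 1 - cR else cR)
    w2 <- w2 * (if (origin[iL + 1L] == 2L) 1 - cR else cR)
  }
  c(w1, w2) / (w1 + w2)
}

# Vectorised transmission probabilities for all progeny of a design at one
# tested position. Returns an n x 2 matrix.
transmission_probs_design <- function(design, x) {
  n <- design$n_progeny
  p1 <- numeric(n)
  map <- design$map
  for (i in seq_len(design$n_sires)) {
    rows <- which(design$sire == i)
    h1 <- design$sire_hap1[i, ]
    h2 <- design$sire_hap2[i, ]
    inf <- which(h1 != h2)
    if (length(inf) == 0L) {
      p1[rows] <- 0.5
      next
    }
    pos <- map$positions[inf]
    orig <- (design$pat[rows, inf, drop = FALSE] !=
               matrix(h1[inf], length(rows), length(inf), byrow = TRUE)) + 1L
    hit <- match(x, pos)
    if (!is.na(hit)) {
      p1[rows] <- as.numeric(orig[, hit] == 1L)
      next
    }
    iL <- findInterval(x, pos)
    w1 <- rep(1, length(rows)); w2 <- w1
    if (iL >= 1L) {
      cL <- haldane_recomb(x - pos[iL])
      oL <- orig[, iL]
      w1 <- w1 * ifelse(oL == 1L, 1 - cL, cL)
      w2 <- w2 * ifelse(oL == 2L, 1 - cL, cL)
    }
    if (iL < length(pos)) {
      cR <- haldane_recomb(pos[iL + 1L] - x)
      oR <- orig[, iL + 1L]
      w1 <- w1 * ifelse(oR == 1L, 1 - cR, cR)
      w2 <- w2 * ifelse(oR == 2L, 1 - cR, cR)
    }
    p1[rows] <- w1 / (w1 + w2)
  }
  cbind(p1 = p1, p2 = 1 - p1)
}
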