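# Multilocus linkage-disequilibrium machinery.
#
# Haplotype frequencies over a small window of loci are decomposed into
# Bennett disequilibria, the unique multilocus LD coefficients that decay
# geometrically under Wright-Fisher random mating: each coefficient over a
# locus set S is multiplied per generation by rho(S), the probability of no
# recombination across S. Throughout, the partitions entering the
# frequency <-> disequilibrium conversions are those made of one
# distinguished block plus singletons; under the in-scope assumption that
# markers are at mutual equilibrium at time 0 these are the only partitions
# with a non-zero contribution, and their constant coefficients equal one.
# General multi-block coefficients (needed only when markers themselves are
# in LD at time 0) are out of scope and rejected explicitly.
#
# Conventions: alleles are coded 0/1; a haplotype frequency table over L
# loci is a numeric vector of length 2^L indexed by
# 1 + sum(allele_l * 2^(l-1)); the order-1 "disequilibrium" of a singleton
# is the allele frequency itself, which makes the recursion well-founded.

freq_index <- function(alleles) 1L + sum(as.integer(alleles) * 2L^(seq_along(alleles) - 1L))

index_alleles <- function(idx, L) as.integer(intToBits(idx - 1L))[seq_len(L)]

#' Probability of no recombination across a set of loci
#'
#' Under no interference, the product over consecutive pairs of
#' `(1 - c)`, with `c` the Haldane recombination fraction.
#'
#' @param positions_cM Map-ordered positions (cM) of the loci in the set.
#' @return A probability in (0, 1]; 1 for a singleton (empty product).
#' @export
rho_no_recomb <- function(positions_cM) {
  if (length(positions_cM) <= 1L) return(1)
  if (is.unsorted(positions_cM)) stop("loci must be map-ordered")
  prod(1 - haldane_recomb(diff(positions_cM)))
}

#' Bennett disequilibria of a haplotype frequency table
#'
#' Computes, bottom-up over locus subsets (pairs, then triples, ...), the
#' Bennett disequilibrium of every subset and allele assignment from the
#' time-0 haplotype frequencies, by the recursion
#' `D(S) = Pi(S) - sum over proper inner blocks T of D(T) * prod of the
#' remaining singleton allele frequencies - prod of all singleton
#' frequencies`.
#'
#' @param freqs Haplotype frequency table over `L` loci: numeric vector of
#'   length `2^L` (see file header for the index convention); must be
#'   non-negative and sum to 1.
#' @param tol Tolerance on `sum(freqs) == 1`.
#' @return An object of class `bennett_state`: list with the number of loci
#'   `L`, the table `tab`, the `2 x L` marginal allele frequencies `marg`,
#'   and `D`, a list indexed by subset bitmask holding the disequilibria of
#'   all allele assignments of that subset.
#' @export
bennett_from_freqs <- function(freqs, tol = 1e-8) {
  L <- as.integer(round(log2(length(freqs))))
  if (2^L != length(freqs)) stop("freqs length must be a power of two")
  if (any(freqs < -tol)) stop("negative haplotype frequency")
  if (abs(sum(freqs) - 1) > tol) stop("haplotype frequencies must sum to 1")

  arr <- array(freqs, rep(2L, L))
  marg <- vapply(seq_len(L),
                 function(l) apply(arr, l, sum),
                 numeric(2))  # rows: allele 0, allele 1

  # marginal haplotype frequency over the loci of `mask`, all assignments
  marg_table <- function(mask) {
    locs <- which(bitwAnd(mask, 2L^(seq_len(L) - 1L)) > 0L)
    if (length(locs) == L) return(as.vector(arr))
    as.vector(apply(arr, locs, sum))
  }

  D <- vector("list", 2L^L - 1L)
  # singletons: D_1 = allele frequency
  for (l in seq_len(L)) D[[2L^(l - 1L)]] <- marg[, l]

  masks <- order(vapply(seq_len(2L^L - 1L), bitcount, integer(1)))
  for (mask in masks) {
    k <- bitcount(mask)
    if (k < 2L) next
    locs <- which(bitwAnd(mask, 2L^(seq_len(L) - 1L)) > 0L)
    Pi <- marg_table(mask)
    nA <- 2L^k
    out <- numeric(nA)
    submasks <- proper_submasks(mask)
    for (ia in seq_len(nA)) {
      a <- index_alleles(ia, k)          # alleles on locs, mask order
      pl <- marg[cbind(a + 1L, locs)]    # singleton freqs of each locus
      acc <- Pi[ia] - prod(pl)
      for (sm in submasks) {
        if (bitcount(sm) < 2L) next
        inlocs <- which(bitwAnd(sm, 2L^(seq_len(L) - 1L)) > 0L)
        rel <- match(inlocs, locs)
        sub_ia <- freq_index(a[rel])
        acc <- acc - D[[sm]][sub_ia] * prod(pl[-rel])
      }
      out[ia] <- acc
    }
    D[[mask]] <- out
  }
  structure(list(L = L, tab = freqs, marg = marg, D = D),
            class = "bennett_state")
}

bitcount <- function(mask) sum(bitwAnd(mask, 2L^(0:30)) > 0L)

proper_submasks <- function(mask) {
  subs <- Filter(function(m) bitwAnd(m, mask) == m, seq_len(mask - 1L))
  subs
}

# Shared kernel of the reconstruction and the decay formula: sum over
# distinguished blocks S (|S| >= 2) of w(S) * D(S) * prod of the remaining
# singleton allele frequencies, plus the all-singleton product term.
block_sum <- function(state, alleles, weight) {
  L <- state$L
  stopifnot(length(alleles) == L)
  pl <- state$marg[cbind(as.integer(alleles) + 1L, seq_len(L))]
  acc <- prod(pl)
  for (mask in seq_len(2L^L - 1L)) {
    if (bitcount(mask) < 2L) next
    locs <- which(bitwAnd(mask, 2L^(seq_len(L) - 1L)) > 0L)
    ia <- freq_index(alleles[locs])
    acc <- acc + weight(mask, locs) * state$D[[mask]][ia] * prod(pl[-locs])
  }
  acc
}

#' Reconstruct a time-0 haplotype frequency from Bennett disequilibria
#'
#' The inverse of [bennett_from_freqs()]: the distinguished-block partition
#' sum with unit coefficients.
#'
#' @param state A `bennett_state`.
#' @param alleles 0/1 allele vector, one per locus.
#' @return The haplotype frequency.
#' @export
freq_from_bennett <- function(state, alleles) {
  block_sum(state, alleles, function(mask, locs) 1)
}

#' Expected haplotype frequency after t generations of drift
#'
#' Each Bennett disequilibrium over a locus block S decays geometrically at
#' rate `rho(S)` (the probability of no recombination across S), while
#' allele frequencies are constant in expectation; the expected haplotype
#' frequency at time t is the partition sum with each block weighted by
#' `rho(S)^t`.
#'
#' @param state A `bennett_state` describing time 0.
#' @param positions_cM Positions (cM) of the loci, aligned with the state.
#' @param t Generations elapsed (>= 0).
#' @param alleles 0/1 allele vector, one per locus.
#' @return Expected frequency, clipped to `[0, 1]`.
#' @export
expected_freq_at_t <- function(state, positions_cM, t, alleles) {
  if (t < 0) stop("t must be >= 0")
  stopifnot(length(positions_cM) == state$L)
  v <- block_sum(state, alleles,
                 function(mask, locs) rho_no_recomb(positions_cM[locs])^t)
  min(1, max(0, v))
}

# ---- time-0 mutation model --------------------------------------------------

#' Parameters of the time-0 linkage-disequilibrium model
#'
#' At time 0 the favourable allele Q sits on founder marker haplotype
#' `hstar`: a fraction `beta` of its copies are new (fully associated with
#' `hstar`) and the rest are distributed independently of the markers,
#' `Pi_{h,Q}(0) = (1 - beta) Pi_h Pi_Q(0) + beta Pi_Q(0) [h == hstar]`.
#' The markers themselves are at mutual linkage equilibrium at time 0, with
#' allele frequencies `marker_freqs`.
#'
#' @param hstar 0/1 allele vector: the founder haplotype over the window
#'   markers.
#' @param piQ0 Frequency of Q at time 0, in (0, 1].
#' @param t Generations elapsed since time 0 (>= 0).
#' @param marker_freqs Frequency of allele 1 at each window marker.
#' @param beta Proportion of Q copies that are new at time 0 (default 1: no
#'   pre-existing copies).
#' @return An object of class `ld_params`.
#' @export
ld_params <- function(hstar, piQ0, t, marker_freqs, beta = 1) {
  hstar <- as.integer(hstar)
  stopifnot(all(hstar %in% c(0L, 1L)),
            length(marker_freqs) == length(hstar),
            all(marker_freqs >= 0 & marker_freqs <= 1),
            beta >= 0, beta <= 1, t >= 0)
  if (!(piQ0 > 0 && piQ0 <= 1)) stop("piQ0 must be in (0, 1]")
  pi_hstar <- prod(ifelse(hstar == 1L, marker_freqs, 1 - marker_freqs))
  if (pi_hstar - piQ0 * ((1 - beta) * pi_hstar + beta) < -1e-12) {
    stop("piQ0 too large: haplotype hstar would get a negative (hstar, q) frequency")
  }
  structure(list(hstar = hstar, piQ0 = piQ0, t = t,
                 marker_freqs = as.numeric(marker_freqs), beta = beta,
                 pi_hstar = pi_hstar),
            class = "ld_params")
}

#' Time-0 extended-haplotype frequency table
#'
#' Builds the joint frequency table of (window marker haplotype, QTL allele)
#' at time 0 under the mutation model of [ld_params()], with the QTL locus
#' inserted at column `qtl_idx` of the extended window.
#'
#' @param params An `ld_params`.
#' @param qtl_idx Position (index) of the QTL locus within the extended
#'   window, `1 .. m + 1` for `m` markers.
#' @return Frequency table over `m + 1` loci in the vector convention of
#'   [bennett_from_freqs()].
#' @export
time0_freqs <- function(params, qtl_idx) {
  m <- length(params$hstar)
  L <- m + 1L
  stopifnot(qtl_idx >= 1L, qtl_idx <= L)
  tab <- numeric(2^L)
  for (idx in seq_len(2^L)) {
    al <- index_alleles(idx, L)
    h <- al[-qtl_idx]
    qa <- al[qtl_idx]
    pi_h <- prod(ifelse(h == 1L, params$marker_freqs, 1 - params$marker_freqs))
    pi_hQ <- (1 - params$beta) * pi_h * params$piQ0 +
      params$beta * params$piQ0 * as.numeric(all(h == params$hstar))
    tab[idx] <- if (qa == 1L) pi_hQ else pi_h - pi_hQ
  }
  if (any(tab < -1e-12)) stop("piQ0 exceeds the frequency of hstar")
  pmax(tab, 0)
}

#' Probability of a QTL allele given a flanking marker haplotype
#'
#' The likelihood approximation
#' `P(allele a at x | h) = min(1, E[Pi_{a,h}(t)] / E[Pi_h(t)])`, with the
#' expected frequencies obtained by geometric Bennett decay from the time-0
#' mutation model. If the expected marker-haplotype frequency is zero (a
#' window haplotype absent from the model) the marginal `Pi_Q(0)` is
#' returned with a warning, keeping downstream likelihoods finite.
#'
#' @param params An `ld_params` (its `t` is used unless `t` is supplied).
#' @param h 0/1 window marker haplotype.
#' @param a QTL allele: 1 (or "Q") for the favourable allele, 0 (or "q").
#' @param marker_positions Positions (cM) of the window markers.
#' @param x Tested QTL position (cM).
#' @param t Generations elapsed; dams transmit at `params$t + 1`.
#' @return A probability in `[0, 1]`.
#' @export
qtl_prob_given_hap <- function(params, h, a, marker_positions, x,
                               t = params$t) {
  a <- if (is.character(a)) as.integer(a == "Q") else as.integer(a)
  h <- as.integer(h)
  m <- length(h)
  stopifnot(length(marker_positions) == m)
  ord <- order(c(marker_positions, x))
  pos_ext <- c(marker_positions, x)[ord]
  qtl_idx <- which(ord == m + 1L)
  state <- bennett_from_freqs(time0_freqs(params, qtl_idx))
  alleles_ext <- append(h, a, after = qtl_idx - 1L)
  num <- expected_freq_at_t(state, pos_ext, t, alleles_ext)
  alleles_alt <- alleles_ext
  alleles_alt[qtl_idx] <- 1L - a
  den <- num + expected_freq_at_t(state, pos_ext, t, alleles_alt)
  if (den <= .Machine$double.eps) {
    warning("window haplotype has zero expected frequency; ",
            "falling back to the marginal QTL allele frequency")
    return(if (a == 1L) params$piQ0 else 1 - params$piQ0)
  }
  min(1, num / den)
}

#' Window markers flanking a tested position
#'
#' The `n_flanking` markers closest to `x`, symmetric (`n_flanking / 2` on
#' each side), truncated to the available markers at chromosome ends.
#'
#' @param map A `genetic_map`.
#' @param x Tested position (cM), inside the map span.
#' @param n_flanking 2 or 4.
#' @return Integer marker indices, map-ordered.
#' @export
window_markers <- function(map, x, n_flanking = 2L) {
  if (!n_flanking %in% c(2L, 4L)) stop("n_flanking must be 2 or 4")
  j <- interval_index(map, x)
  half <- n_flanking %/% 2L
  idx <- (j - half + 1L):(j + half)
  idx[idx >= 1L & idx <= map$n_markers]
}
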