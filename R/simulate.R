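#' Define a simulation scenario
#'
#' A scenario bundles the population-history and design parameters of one
#' simulation study cell: founder effective size, generations of drift,
#' half-sib family structure, marker map density, QTL effect and position,
#' founder linkage-disequilibrium mode, per-generation phenotypic selection
#' and marker mutation.
#'
#' @param Ne Founder effective size (number of diploid individuals).
#' @param Ng Generations of evolution between founding and sampling.
#' @param Ns Number of sires sampled from the final generation.
#' @param Np Progeny per sire (one progeny per dam).
#' @param n_markers Number of evenly spaced bi-allelic markers.
#' @param density_cM Marker spacing in cM.
#' @param qtl_effect Allele-substitution effect of the favourable QTL allele
#'   in phenotype units (per copy).
#' @param qtl_position_cM True QTL position in cM (between markers).
#' @param founder_mode `"complete_LD"` (the favourable allele appears as a
#'   single new mutation on one founder haplotype, markers at linkage
#'   equilibrium) or `"equilibrium"` (QTL treated as one more independent
#'   bi-allelic locus).
#' @param selection_fraction Fraction of individuals retained for breeding
#'   each historical generation by phenotypic truncation; 1 = no selection.
#' @param marker_mutation_rate Per-allele, per-meiosis marker mutation
#'   probability (the QTL never mutates after time 0).
#' @param sigma2 Residual phenotypic variance.
#' @return An object of class `scenario`.
#' @export
scenario <- function(Ne = 100L, Ng = 50L, Ns = 20L, Np = 100L,
                     n_markers = 40L, density_cM = 0.25,
                     qtl_effect = 0.25, qtl_position_cM = 3.35,
                     founder_mode = c("complete_LD", "equilibrium"),
                     selection_fraction = 1,
                     marker_mutation_rate = 0,
                     sigma2 = 1) {
  founder_mode <- match.arg(founder_mode)
  for (v in c(Ne = Ne, Ng = Ng, Ns = Ns, Np = Np, n_markers = n_markers)) {
    if (!is.finite(v) || v < 1 || v != round(v)) {
      stop("Ne, Ng, Ns, Np and n_markers must be positive integers")
    }
  }
  if (!(selection_fraction > 0 && selection_fraction <= 1)) {
    stop("selection_fraction must be in (0, 1]")
  }
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  if (marker_mutation_rate < 0 || marker_mutation_rate > 1) {
    stop("marker_mutation_rate must be in [0, 1]")
  }
  structure(
    list(Ne = as.integer(Ne), Ng = as.integer(Ng), Ns = as.integer(Ns),
         Np = as.integer(Np), n_markers = as.integer(n_markers),
         density_cM = density_cM, qtl_effect = qtl_effect,
         qtl_position_cM = qtl_position_cM, founder_mode = founder_mode,
         selection_fraction = selection_fraction,
         marker_mutation_rate = marker_mutation_rate, sigma2 = sigma2),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "scenario: Ne=%d Ng=%d | %d sires x %d progeny | %d markers @ %g cM\n",
    x$Ne, x$Ng, x$Ns, x$Np, x$n_markers, x$density_cM))
  cat(sprintf("  QTL effect %g at %g cM, founders %s, sel=%g, mut=%g\n",
              x$qtl_effect, x$qtl_position_cM, x$founder_mode,
              x$selection_fraction, x$marker_mutation_rate))
  invisible(x)
}

#' Marker map implied by a scenario
#' @param scn A [scenario()].
#' @return A `genetic_map` with the scenario's QTL position attached.
#' @export
scenario_map_of <- function(scn) {
  scenario_map(n_markers = scn$n_markers, density_cM = scn$density_cM,
               qtl_position = scn$qtl_position_cM)
}

# ---- population state -------------------------------------------------------

# A population is a list:
#   H         : 2*Ne x L 0/1 integer matrix of haplotypes (QTL column
#               inserted at its map position)
#   positions : length-L cM positions of all loci (markers + QTL)
#   qtl_col   : column index of the QTL locus
#   gen       : generation counter t
new_population <- function(H, positions, qtl_col, gen = 0L) {
  structure(list(H = H, positions = positions, qtl_col = qtl_col,
                 gen = as.integer(gen)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d haplotypes, %d loci, generation %d, Q freq %.4f\n",
              nrow(x$H), ncol(x$H), x$gen, mean(x$H[, x$qtl_col])))
  invisible(x)
}

#' Frequency of the favourable QTL allele in a population
#' @param pop A population as returned by [init_founders()] or [evolve()].
#' @return Frequency of allele Q among the 2 Ne haplotypes.
#' @export
qtl_frequency <- function(pop) mean(pop$H[, pop$qtl_col])

#' Initialise the founder population
#'
#' In `complete_LD` mode the markers are drawn at linkage equilibrium
#' (i.i.d. Bernoulli(0.5) alleles) and the favourable QTL allele is placed on
#' exactly one of the 2 Ne founder haplotypes, creating complete marker-QTL
#' disequilibrium by mutation. In `equilibrium` mode the QTL locus is drawn
#' like one more independent marker.
#'
#' @param scn A [scenario()].
#' @param map A `genetic_map`; defaults to the scenario's own map.
#' @return A population at generation 0.
#' @export
init_founders <- function(scn, map = scenario_map_of(scn)) {
  n_hap <- 2L * scn$Ne
  pos <- sort(c(map$positions, scn$qtl_position_cM))
  qtl_col <- match(scn$qtl_position_cM, pos)
  L <- length(pos)
  H <- matrix(as.integer(stats::runif(n_hap * L) < 0.5), n_hap, L)
  if (scn$founder_mode == "complete_LD") {
    H[, qtl_col] <- 0L
    H[sample.int(n_hap, 1L), qtl_col] <- 1L
  }
  new_population(H, pos, qtl_col, gen = 0L)
}

# Row-wise parity cumulative sums via one triangular matrix product; used to
# turn per-interval crossover indicators into per-locus grand-parental origin.
row_cumsum <- function(m) {
  if (ncol(m) == 0L) return(m)
  m %*% upper.tri(diag(ncol(m)), diag = TRUE)
}

# Form one gamete per row from paired parental haplotype matrices.
# H1, H2: k x L matrices (haplotype 1 and 2 of the chosen parent for each
# gamete); rec: length L-1 adjacent recombination fractions.
make_gametes <- function(H1, H2, rec, mutation_rate = 0, qtl_col = NULL) {
  k <- nrow(H1); L <- ncol(H1)
  start <- sample.int(2L, k, replace = TRUE) - 1L
  if (L > 1L) {
    xo <- matrix(stats::runif(k * (L - 1L)), k) <
      matrix(rec, k, L - 1L, byrow = TRUE)
    origin <- (start + cbind(0, row_cumsum(xo))) %% 2
  } else {
    origin <- matrix(start, k, 1L)
  }
  G <- H1
  take2 <- origin == 1
  G[take2] <- H2[take2]
  if (mutation_rate > 0) {
    mut <- matrix(stats::runif(k * L) < mutation_rate, k, L)
    if (!is.null(qtl_col)) mut[, qtl_col] <- FALSE
    G[mut] <- 1L - G[mut]
  }
  storage.mode(G) <- "integer"
  G
}

#' Truncation selection on phenotype
#'
#' Retains the top `fraction` of individuals by phenotypic value as the
#' breeding pool of the next generation.
#'
#' @param phenotypes Phenotypic values, one per individual.
#' @param fraction Fraction retained, in (0, 1].
#' @return Integer indices of the selected individuals.
#' @export
apply_truncation_selection <- function(phenotypes, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  n <- length(phenotypes)
  k <- ceiling(fraction * n)
  if (k < 1L) stop("selection leaves an empty breeding pool")
  order(phenotypes, decreasing = TRUE)[seq_len(k)]
}

#' Evolve a population by Wright-Fisher random mating
#'
#' Each generation, 2 Ne gametes are formed by drawing a parent uniformly
#' with replacement (from the truncation-selected pool when
#' `selection_fraction < 1`, with selection on the dose-model phenotype) and
#' recombining its two haplotypes with Haldane crossover probabilities
#' between adjacent loci. Marker alleles mutate with probability
#' `marker_mutation_rate` per meiosis; the QTL allele never mutates.
#'
#' @param pop A population.
#' @param scn The [scenario()] providing selection, mutation and phenotype
#'   parameters.
#' @param generations Number of generations to advance.
#' @return The evolved population (`gen` advanced by `generations`).
#' @export
evolve <- function(pop, scn, generations = scn$Ng) {
  if (generations < 0) stop("generations must be >= 0")
  if (generations == 0) return(pop)
  rec <- adjacent_recomb(pop$positions)
  n_ind <- nrow(pop$H) %/% 2L
  for (g in seq_len(generations)) {
    pool <- seq_len(n_ind)
    if (scn$selection_fraction < 1) {
      geno <- pop$H[2L * pool - 1L, pop$qtl_col] + pop$H[2L * pool, pop$qtl_col]
      phen <- scn$qtl_effect * geno +
        stats::rnorm(n_ind, 0, sqrt(scn$sigma2))
      pool <- apply_truncation_selection(phen, scn$selection_fraction)
    }
    parents <- pool[sample.int(length(pool), 2L * n_ind, replace = TRUE)]
    H <- make_gametes(pop$H[2L * parents - 1L, , drop = FALSE],
                      pop$H[2L * parents, , drop = FALSE],
                      rec,
                      mutation_rate = scn$marker_mutation_rate,
                      qtl_col = pop$qtl_col)
    pop$H <- H
    pop$gen <- pop$gen + 1L
  }
  pop
}

# ---- half-sib design --------------------------------------------------------

new_halfsib_design <- function(map, sire_hap1, sire_hap2, sire_qtl1, sire_qtl2,
                               pat, mat, pat_qtl, mat_qtl, sire, y = NULL,
                               generations = NULL) {
  structure(
    list(map = map,
         sire_hap1 = sire_hap1, sire_hap2 = sire_hap2,
         sire_qtl1 = sire_qtl1, sire_qtl2 = sire_qtl2,
         pat = pat, mat = mat, pat_qtl = pat_qtl, mat_qtl = mat_qtl,
         sire = sire, y = y,
         n_sires = nrow(sire_hap1), n_progeny = nrow(pat),
         generations = generations),
    class = "halfsib_design")
}

#' @export
print.halfsib_design <- function(x, ...) {
  cat(sprintf("halfsib_design: %d sires, %d progeny, %d markers\n",
              x$n_sires, x$n_progeny, ncol(x$pat)))
  invisible(x)
}

#' Sample a half-sib design from an evolved population
#'
#' Draws `Ns` sires without replacement from the final generation; each of
#' the `Ns * Np` progeny receives a recombined paternal gamete from its sire
#' and a recombined maternal gamete from a dam drawn from the same
#' generation, excluding the progeny's own sire (one progeny per dam).
#' Phenotypes are
#' not attached; see [simulate_phenotypes()]. The true QTL alleles are kept
#' in separate `*_qtl` fields so the mapping methods never see them.
#'
#' @param pop An evolved population.
#' @param scn The [scenario()].
#' @param map The marker `genetic_map` (defaults to the scenario's).
#' @return A `halfsib_design`.
#' @export
sample_design <- function(pop, scn, map = scenario_map_of(scn)) {
  n_ind <- nrow(pop$H) %/% 2L
  if (n_ind < scn$Ns || n_ind < 2L) {
    stop("population too small to draw ", scn$Ns, " sires plus dams")
  }
  qc <- pop$qtl_col
  mcols <- setdiff(seq_len(ncol(pop$H)), qc)
  rec <- adjacent_recomb(pop$positions)

  sires <- sample.int(n_ind, scn$Ns)
  N <- scn$Ns * scn$Np
  sire_of <- rep(seq_len(scn$Ns), each = scn$Np)

  # one dam per progeny, drawn from the final generation excluding the
  # progeny's own sire (a small evolved population cannot supply
  # Ns * Np distinct non-sire dams)
  dams <- sample.int(n_ind, N, replace = TRUE)
  repeat {
    clash <- dams == sires[sire_of]
    if (!any(clash)) break
    dams[clash] <- sample.int(n_ind, sum(clash), replace = TRUE)
  }

  sp <- sires[sire_of]
  pat_full <- make_gametes(pop$H[2L * sp - 1L, , drop = FALSE],
                           pop$H[2L * sp, , drop = FALSE], rec,
                           mutation_rate = scn$marker_mutation_rate,
                           qtl_col = qc)
  mat_full <- make_gametes(pop$H[2L * dams - 1L, , drop = FALSE],
                           pop$H[2L * dams, , drop = FALSE], rec,
                           mutation_rate = scn$marker_mutation_rate,
                           qtl_col = qc)

  new_halfsib_design(
    map = map,
    sire_hap1 = pop$H[2L * sires - 1L, mcols, drop = FALSE],
    sire_hap2 = pop$H[2L * sires, mcols, drop = FALSE],
    sire_qtl1 = pop$H[2L * sires - 1L, qc],
    sire_qtl2 = pop$H[2L * sires, qc],
    pat = pat_full[, mcols, drop = FALSE],
    mat = mat_full[, mcols, drop = FALSE],
    pat_qtl = pat_full[, qc],
    mat_qtl = mat_full[, qc],
    sire = sire_of,
    generations = pop$gen)
}

#' Simulate progeny phenotypes under the dose-response model
#'
#' `y_ij = qtl_effect * (number of Q alleles of progeny ij) + e_ij`,
#' `e_ij ~ Normal(0, sigma2)`.
#'
#' @param design A `halfsib_design` carrying true QTL alleles.
#' @param scn The [scenario()].
#' @return The design with phenotypes filled in.
#' @export
simulate_phenotypes <- function(design, scn) {
  n <- design$n_progeny
  dose <- design$pat_qtl + design$mat_qtl
  design$y <- scn$qtl_effect * dose + stats::rnorm(n, 0, sqrt(scn$sigma2))
  design
}

# At least one sire heterozygous at the QTL (also implies Q segregates).
has_heterozygous_sire <- function(design) {
  any(design$sire_qtl1 != design$sire_qtl2)
}

#' Simulate one accepted replicate of a scenario
#'
#' Founds, evolves and samples a half-sib design with phenotypes; designs
#' with no QTL-heterozygous sire (in particular, replicates where the
#' favourable allele was lost to drift) are discarded and redrawn within the
#' same random stream, so a given seed always yields the same accepted
#' design.
#'
#' @param scn A [scenario()].
#' @param seed Optional integer seed for the replicate.
#' @param max_attempts Safety bound on discard-and-redraw attempts.
#' @return A `halfsib_design` with phenotypes; attribute `attempts` records
#'   how many draws were needed.
#' @export
simulate_replicate <- function(scn, seed = NULL, max_attempts = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  map <- scenario_map_of(scn)
  for (attempt in seq_len(max_attempts)) {
    pop <- init_founders(scn, map)
    pop <- evolve(pop, scn, scn$Ng)
    design <- sample_design(pop, scn, map)
    if (has_heterozygous_sire(design)) {
      design <- simulate_phenotypes(design, scn)
      attr(design, "attempts") <- attempt
      return(design)
    }
  }
  stop("no accepted design in ", max_attempts, " attempts")
}

#' Derive a per-replicate seed from a master seed
#'
#' A small counter-based splitter keeping results reproducible and
#' parallelisable across replicates: `(master * 48271 + r * 1000003) mod
#' (2^31 - 2) + 1`.
#'
#' @param master_seed Integer master seed.
#' @param r Replicate index (1-based).
#' @return An integer seed.
#' @export
split_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(r) * 1000003) %%
               2147483646) + 1L
}
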