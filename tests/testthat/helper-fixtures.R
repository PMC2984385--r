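# Small fixtures built in code.

freq_index <- function(alleles) ldlmap:::freq_index(alleles)

# a compact scenario that simulates in milliseconds
toy_scenario <- function(...) {
  args <- list(Ne = 50L, Ng = 10L, Ns = 4L, Np = 15L, n_markers = 8L,
               density_cM = 1, qtl_effect = 0.5, qtl_position_cM = 3.4)
  args[names(list(...))] <- list(...)
  do.call(scenario, args)
}

# hand-buildable design: explicit haplotypes, sires and phenotypes
manual_design <- function(sire_hap1, sire_hap2, pat, mat, sire, y,
                          positions = seq_len(ncol(pat)) - 1,
                          qtl_position = NULL, generations = 10L,
                          pat_qtl = rep(NA_integer_, nrow(pat)),
                          mat_qtl = rep(NA_integer_, nrow(pat))) {
  map <- genetic_map(positions, qtl_position = qtl_position)
  ldlmap:::new_halfsib_design(
    map, sire_hap1, sire_hap2,
    sire_qtl1 = rep(NA_integer_, nrow(sire_hap1)),
    sire_qtl2 = rep(NA_integer_, nrow(sire_hap1)),
    pat = pat, mat = mat, pat_qtl = pat_qtl, mat_qtl = mat_qtl,
    sire = sire, y = y, generations = generations)
}

# random small frequency table over L bi-allelic loci (sums to 1)
random_freq_table <- function(L, seed) {
  set.seed(seed)
  x <- stats::rgamma(2^L, shape = 1)
  x / sum(x)
}

# oracle: decay every Bennett coefficient by rho(S)^t and reconstruct the
# haplotype frequency (independent per-generation application of the
# geometric decay rule)
decay_then_reconstruct <- function(state, positions, t, alleles) {
  st <- state
  for (mask in seq_along(st$D)) {
    if (is.null(st$D[[mask]])) next
    k <- ldlmap:::bitcount(mask)
    if (k < 2L) next
    locs <- which(bitwAnd(mask, 2L^(seq_len(st$L) - 1L)) > 0L)
    rho <- rho_no_recomb(positions[locs])
    for (g in seq_len(t)) st$D[[mask]] <- st$D[[mask]] * rho
  }
  freq_from_bennett(st, alleles)
}
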