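test_that("no-recombination probability multiplies over adjacent gaps", {
  expect_identical(rho_no_recomb(3.2), 1)
  c10 <- haldane_recomb(10)
  expect_equal(rho_no_recomb(c(0, 10)), 1 - c10)
  expect_equal(rho_no_recomb(c(0, 10, 20)), (1 - c10)^2)
  # Haldane composition: the 0-20 cM fraction equals the two-step chain
  c20 <- haldane_recomb(20)
  expect_equal(c20, c10 * (1 - c10) + c10 * (1 - c10) + c10^2 * 0 +
                 (1 - c10)^2 * 0)   # odd-crossover configurations of 2 gaps
  expect_error(rho_no_recomb(c(10, 0)), "map-ordered")
})

test_that("pairwise Bennett disequilibrium matches the textbook value", {
  # Pi(1,1) = Pi(0,0) = 0.5: alleles perfectly associated at freq 0.5
  tab <- c(0.5, 0, 0, 0.5)   # order: 00, 10, 01, 11
  st <- bennett_from_freqs(tab)
  expect_equal(st$marg[2, ], c(0.5, 0.5))
  expect_equal(st$D[[3L]][freq_index(c(1, 1))], 0.25)
  expect_equal(st$D[[3L]][freq_index(c(1, 0))], -0.25)
})

test_that("independent loci have zero disequilibria of every order", {
  p <- c(0.3, 0.6, 0.85)
  tab <- numeric(8)
  for (idx in 1:8) {
    a <- ldlmap:::index_alleles(idx, 3L)
    tab[idx] <- prod(ifelse(a == 1, p, 1 - p))
  }
  st <- bennett_from_freqs(tab)
  for (mask in c(3L, 5L, 6L, 7L)) {
    expect_lt(max(abs(st$D[[mask]])), 1e-14)
  }
})

test_that("frequency <-> disequilibrium conversion is an exact round trip", {
  for (L in 3:5) {
    tab <- random_freq_table(L, seed = 100 + L)
    st <- bennett_from_freqs(tab)
    for (idx in seq_along(tab)) {
      a <- ldlmap:::index_alleles(idx, L)
      expect_lt(abs(freq_from_bennett(st, a) - tab[idx]), 1e-12)
    }
  }
})

test_that("inconsistent frequency tables are rejected", {
  expect_error(bennett_from_freqs(c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(bennett_from_freqs(c(-0.2, 0.6, 0.3, 0.3)), "negative")
})

test_that("expected frequency at t matches per-generation geometric decay", {
  pos3 <- c(0, 2, 5)
  for (L in c(3L, 4L)) {
    pos <- if (L == 3L) pos3 else c(0, 2, 5, 6)
    tab <- random_freq_table(L, seed = 200 + L)
    st <- bennett_from_freqs(tab)
    for (t in c(0L, 1L, 5L, 20L)) {
      for (idx in c(1L, 2L, 2L^L)) {
        a <- ldlmap:::index_alleles(idx, L)
        expect_lt(abs(expected_freq_at_t(st, pos, t, a) -
                        decay_then_reconstruct(st, pos, t, a)), 1e-12)
      }
    }
  }
  # t = 0 reproduces the table; complete linkage freezes it
  tab <- random_freq_table(3L, 201)
  st <- bennett_from_freqs(tab)
  expect_equal(expected_freq_at_t(st, pos3, 0L, c(1, 1, 0)),
               tab[freq_index(c(1, 1, 0))])
  expect_equal(expected_freq_at_t(st, c(1, 1, 1), 50L, c(1, 1, 0)),
               tab[freq_index(c(1, 1, 0))])
  expect_error(expected_freq_at_t(st, pos3, -1, c(1, 1, 0)), ">= 0")
})

test_that("two-locus decay equals iterating D(t+1) = (1 - c) D(t)", {
  p <- c(0.4)  # one marker
  lp <- ld_params(hstar = 1L, piQ0 = 0.2, t = 5L, marker_freqs = p)
  tab <- time0_freqs(lp, qtl_idx = 2L)
  st <- bennett_from_freqs(tab)
  c1 <- haldane_recomb(10)
  D0 <- tab[freq_index(c(1, 1))] - p * 0.2
  Dt <- D0
  for (g in 1:5) Dt <- (1 - c1) * Dt
  expect_lt(abs(expected_freq_at_t(st, c(0, 10), 5L, c(1, 1)) -
                  (p * 0.2 + Dt)), 1e-12)
})

test_that("the time-0 mutation model concentrates Q on the founder haplotype", {
  f <- c(0.5, 0.4)
  lp1 <- ld_params(c(1L, 0L), piQ0 = 0.1, t = 0L, marker_freqs = f)
  tab <- time0_freqs(lp1, qtl_idx = 3L)
  # beta = 1: Q only on hstar
  for (idx in seq_len(8)) {
    a <- ldlmap:::index_alleles(idx, 3L)
    if (a[3] == 1 && !identical(a[1:2], c(1L, 0L))) {
      expect_equal(tab[idx], 0)
    }
  }
  expect_equal(tab[freq_index(c(1, 0, 1))], 0.1)
  # beta = 0: independence, no LD created
  lp0 <- ld_params(c(1L, 0L), piQ0 = 0.1, t = 0L, marker_freqs = f, beta = 0)
  tab0 <- time0_freqs(lp0, qtl_idx = 3L)
  expect_equal(tab0[freq_index(c(1, 0, 1))], 0.5 * 0.6 * 0.1)
  # piQ0 above the founder haplotype frequency is impossible
  expect_error(ld_params(c(1L, 0L), piQ0 = 0.5, t = 0L, marker_freqs = f),
               "piQ0 too large")
})

test_that("conditional QTL probabilities are coherent and decay to the margin", {
  f <- c(0.5, 0.5)
  wpos <- c(3.25, 3.5)
  x <- 3.375
  lp <- ld_params(c(1L, 1L), piQ0 = 0.2, t = 10L, marker_freqs = f)
  # additivity P(Q|h) + P(q|h) = 1 (no clipping at these settings)
  for (idx in 1:4) {
    h <- ldlmap:::index_alleles(idx, 2L)
    pQ <- qtl_prob_given_hap(lp, h, 1L, wpos, x)
    pq <- qtl_prob_given_hap(lp, h, 0L, wpos, x)
    expect_lt(abs(pQ + pq - 1), 1e-12)
    expect_gte(pQ, 0); expect_lte(pQ, 1)
  }
  # t = 0, piQ0 = Pi_hstar: carrying hstar implies carrying Q
  lp0 <- ld_params(c(1L, 1L), piQ0 = 0.25, t = 0L, marker_freqs = f)
  expect_equal(qtl_prob_given_hap(lp0, c(1L, 1L), 1L, wpos, x, t = 0), 1)
  # monotone non-increasing in t on the founder haplotype, limit = margin
  ps <- vapply(c(0, 2, 5, 20, 100, 20000), function(tt) {
    qtl_prob_given_hap(lp, c(1L, 1L), 1L, wpos, x, t = tt)
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_lt(abs(ps[length(ps)] - 0.2), 1e-6)
  # off-founder haplotypes rise towards the margin from below
  p_off <- qtl_prob_given_hap(lp, c(0L, 0L), 1L, wpos, x, t = 20000)
  expect_lt(abs(p_off - 0.2), 1e-6)
})

test_that("degenerate window haplotypes fall back to the marginal with a warning", {
  f <- c(0, 0.5)    # marker 1 monomorphic for allele 0
  lp <- ld_params(c(0L, 1L), piQ0 = 0.1, t = 5L, marker_freqs = f)
  expect_warning(
    p <- qtl_prob_given_hap(lp, c(1L, 1L), 1L, c(0, 1), 0.5),
    "zero expected frequency")
  expect_equal(p, 0.1)
})
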