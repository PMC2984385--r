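test_that("founders carry a single new mutation in complete-LD mode", {
  scn <- scenario(Ne = 100L)
  set.seed(1)
  for (r in 1:5) {
    pop <- init_founders(scn)
    expect_equal(sum(pop$H[, pop$qtl_col]), 1L)
    expect_equal(nrow(pop$H), 200L)
    expect_true(all(pop$H %in% 0:1))
  }
})

test_that("equilibrium founders draw the QTL like an independent marker", {
  scn <- scenario(Ne = 200L, founder_mode = "equilibrium")
  set.seed(2)
  freqs <- replicate(200, qtl_frequency(init_founders(scn)))
  # mean 0.5 within 3 MC standard errors
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.5), 3 * se)
})

test_that("founder marker LD is zero on average (linkage equilibrium)", {
  scn <- toy_scenario(Ne = 100L)
  set.seed(3)
  Ds <- replicate(1000, {
    pop <- init_founders(scn)
    m <- pop$H[, -pop$qtl_col]
    mean(m[, 1] * m[, 2]) - mean(m[, 1]) * mean(m[, 2])
  })
  expect_lt(abs(mean(Ds)), 3 * sd(Ds) / sqrt(length(Ds)))
})

test_that("zero generations of evolution is the identity", {
  scn <- toy_scenario()
  set.seed(4)
  pop <- init_founders(scn)
  expect_identical(evolve(pop, scn, 0L), pop)
})

test_that("drift is frequency-neutral and erodes heterozygosity at 1/(2Ne)", {
  scn <- scenario(Ne = 20L, Ng = 8L, n_markers = 1L, density_cM = 1,
                  qtl_position_cM = 0.5, founder_mode = "equilibrium")
  set.seed(5)
  R <- 2000
  f0 <- f1 <- h1 <- numeric(R)
  for (r in seq_len(R)) {
    pop <- init_founders(scn)
    f0[r] <- qtl_frequency(pop)
    pop <- evolve(pop, scn, scn$Ng)
    f1[r] <- qtl_frequency(pop)
    h1[r] <- 2 * f1[r] * (1 - f1[r])
  }
  d <- f1 - f0
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(R))           # martingale
  H0 <- mean(2 * f0 * (1 - f0))
  expected_H <- H0 * (1 - 1 / (2 * scn$Ne))^scn$Ng
  se_H <- sd(h1) / sqrt(R)
  expect_lt(abs(mean(h1) - expected_H), 3 * se_H)
})

test_that("truncation selection keeps the top fraction and drives Q up", {
  expect_equal(sort(apply_truncation_selection(1:10, 1)), 1:10)
  sel <- apply_truncation_selection(c(3, 9, 1, 7, 5, 8), 0.5)
  expect_equal(sort(sel), c(2, 4, 6))   # phenotypes 9, 7, 8
  expect_error(apply_truncation_selection(1:4, 0), "in \\(0, 1]")

  scn <- scenario(Ne = 40L, Ng = 10L, n_markers = 4L, density_cM = 1,
                  qtl_position_cM = 1.5, founder_mode = "equilibrium",
                  qtl_effect = 1, selection_fraction = 0.5)
  set.seed(6)
  R <- 400
  gain <- replicate(R, {
    pop <- init_founders(scn)
    f0 <- qtl_frequency(pop)
    qtl_frequency(evolve(pop, scn, scn$Ng)) - f0
  })
  expect_gt(mean(gain), 3 * sd(gain) / sqrt(R))   # directional selection
})

test_that("sampled designs have the right shape and consistent gametes", {
  scn <- toy_scenario(marker_mutation_rate = 0)
  set.seed(7)
  d <- simulate_replicate(scn, seed = 11)
  expect_s3_class(d, "halfsib_design")
  expect_equal(d$n_sires, scn$Ns)
  expect_equal(d$n_progeny, scn$Ns * scn$Np)
  expect_true(has_het <- any(d$sire_qtl1 != d$sire_qtl2))
  # gamete consistency: each paternal allele is one of the sire's alleles
  for (j in seq_len(d$n_progeny)) {
    i <- d$sire[j]
    expect_true(all(d$pat[j, ] == d$sire_hap1[i, ] |
                      d$pat[j, ] == d$sire_hap2[i, ]))
  }
})

test_that("design sampling rejects populations smaller than the sire count", {
  scn <- toy_scenario(Ns = 60L)   # Ne = 50 < Ns
  pop <- init_founders(scn)
  expect_error(sample_design(pop, scn), "too small")
})

test_that("phenotypes follow the dose-response model", {
  scn <- toy_scenario(qtl_effect = 0.25, sigma2 = 1)
  n <- 10000L
  d <- manual_design(
    sire_hap1 = matrix(0L, 2, 4), sire_hap2 = matrix(1L, 2, 4),
    pat = matrix(0L, n, 4), mat = matrix(0L, n, 4),
    sire = rep(1:2, each = n / 2), y = rep(0, n),
    pat_qtl = rep(c(0L, 1L), each = n / 2),
    mat_qtl = rep(c(0L, 1L), each = n / 2))
  set.seed(8)
  d <- simulate_phenotypes(d, scn)
  qq <- d$pat_qtl + d$mat_qtl == 2L
  diff_hat <- mean(d$y[qq]) - mean(d$y[!qq])
  se <- sqrt(2 / (n / 2))
  expect_lt(abs(diff_hat - 0.5), 3 * se)       # 2 copies x effect 0.25
  resid <- d$y - scn$qtl_effect * (d$pat_qtl + d$mat_qtl)
  expect_lt(abs(var(resid) - 1), 3 * sqrt(2 / n))
  # zero effect: i.i.d. Normal(0, sigma2)
  scn0 <- toy_scenario(qtl_effect = 0)
  d0 <- simulate_phenotypes(d, scn0)
  expect_lt(abs(mean(d0$y)), 3 / sqrt(n))
})

test_that("identical seed and scenario give bit-identical designs", {
  scn <- toy_scenario()
  d1 <- simulate_replicate(scn, seed = 99)
  d2 <- simulate_replicate(scn, seed = 99)
  expect_identical(d1, d2)
  expect_identical(split_seed(5L, 10L), split_seed(5L, 10L))
  expect_true(split_seed(2L, 3L) != split_seed(3L, 2L))
  expect_true(all(vapply(1:50, function(r) split_seed(123L, r),
                         integer(1)) > 0))
})

test_that("two-locus LD decays as (1 - c)^t in a near-infinite population", {
  # joint check of the simulator against the geometric decay rule
  scn <- scenario(Ne = 10000L, Ng = 4L, n_markers = 1L, density_cM = 10,
                  qtl_position_cM = 5, founder_mode = "equilibrium")
  c01 <- haldane_recomb(5)
  set.seed(9)
  R <- 60
  ratio <- replicate(R, {
    pop <- init_founders(scn)
    H <- pop$H
    D0 <- mean(H[, 1] * H[, 2]) - mean(H[, 1]) * mean(H[, 2])
    pop <- evolve(pop, scn, scn$Ng)
    Dt <- mean(pop$H[, 1] * pop$H[, 2]) -
      mean(pop$H[, 1]) * mean(pop$H[, 2])
    Dt - (1 - c01)^scn$Ng * D0
  })
  expect_lt(abs(mean(ratio)), 3 * sd(ratio) / sqrt(R))
})
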