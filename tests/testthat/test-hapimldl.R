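# full enumeration oracle over (diplotype z, dam allele a, origin k)
lambda_oracle <- function(y, mu, sigma2, alpha4, zp, pdQ, trans) {
  chrom_allele <- list(QQ = c("Q", "Q"), qq = c("q", "q"),
                       Qq = c("Q", "q"), qQ = c("q", "Q"))
  tot <- 0
  for (z in names(chrom_allele)) {
    for (a in c("Q", "q")) {
      pa <- if (a == "Q") pdQ else 1 - pdQ
      for (k in 1:2) {
        S <- chrom_allele[[z]][k]
        eff <- alpha4[[paste0(S, a)]]
        tot <- tot + zp[[z]] * pa * trans[k] *
          stats::dnorm(y, mu + eff, sqrt(sigma2))
      }
    }
  }
  tot
}

test_that("sire diplotype probabilities factorise under Hardy-Weinberg", {
  expect_equal(sire_diplotype_probs(0.5, 0.5),
               c(QQ = 0.25, qq = 0.25, Qq = 0.25, qQ = 0.25))
  expect_equal(sire_diplotype_probs(1, 0),
               c(QQ = 0, qq = 0, Qq = 1, qQ = 0))
  set.seed(50)
  for (r in 1:20) {
    p <- sire_diplotype_probs(runif(1), runif(1))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("individual likelihood collapses to a single Gaussian when alpha = 0", {
  zp <- sire_diplotype_probs(0.3, 0.8)
  lam <- individual_likelihood(1.3, mu = 0.4, sigma2 = 2, alpha = 0,
                               zprobs = zp, p_dam_Q = 0.6,
                               trans = c(0.7, 0.3))
  expect_equal(lam, dnorm(1.3, 0.4, sqrt(2)), tolerance = 1e-14)
})

test_that("individual likelihood equals the triple-sum enumeration oracle", {
  set.seed(51)
  for (r in 1:25) {
    alpha4 <- c(QQ = rnorm(1), Qq = rnorm(1), qQ = rnorm(1), qq = rnorm(1))
    zp <- sire_diplotype_probs(runif(1), runif(1))
    pdQ <- runif(1)
    p1 <- runif(1)
    y <- rnorm(1); mu <- rnorm(1); s2 <- runif(1, 0.2, 3)
    got <- individual_likelihood(y, mu, s2, alpha4, zp, pdQ, c(p1, 1 - p1))
    want <- lambda_oracle(y, mu, s2, as.list(alpha4), as.list(zp), pdQ,
                          c(p1, 1 - p1))
    expect_lt(abs(got - want), 1e-12 * max(1, abs(want)))
  }
})

test_that("a certainly-Qq sire with known transmission reduces by hand", {
  # sire Qq, transmission (1, 0): the sire surely passed Q; mixture is over
  # the dam allele only
  zp <- c(QQ = 0, qq = 0, Qq = 1, qQ = 0)
  p <- 0.35
  alpha <- 0.7
  y <- 0.2; mu <- -0.1; s2 <- 1.4
  got <- individual_likelihood(y, mu, s2, alpha, zp, p, c(1, 0))
  want <- p * dnorm(y, mu + alpha, sqrt(s2)) + (1 - p) * dnorm(y, mu, sqrt(s2))
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("the design log-likelihood is additive over progeny", {
  scn <- toy_scenario()
  d <- simulate_replicate(scn, seed = 52)
  params <- list(mu = tapply(d$y, d$sire, mean), sigma2 = 1.1, alpha = 0.4,
                 hstar = c(1L, 0L), piQ0 = 0.05, t = 10L)
  x <- 3.5
  ll <- ldl_loglik(d, x, params)
  d2 <- d
  d2$pat <- rbind(d$pat, d$pat); d2$mat <- rbind(d$mat, d$mat)
  d2$pat_qtl <- c(d$pat_qtl, d$pat_qtl); d2$mat_qtl <- c(d$mat_qtl, d$mat_qtl)
  d2$sire <- c(d$sire, d$sire); d2$y <- c(d$y, d$y)
  d2$n_progeny <- 2L * d$n_progeny
  expect_equal(ldl_loglik(d2, x, params), 2 * ll, tolerance = 1e-10)
})

test_that("with alpha = 0 the profile likelihood is flat and equals the null", {
  scn <- toy_scenario()
  d <- simulate_replicate(scn, seed = 53)
  mu0 <- as.numeric(tapply(d$y, d$sire, mean))
  s20 <- mean((d$y - mu0[d$sire])^2)
  ll0 <- sum(dnorm(d$y, mu0[d$sire], sqrt(s20), log = TRUE))
  for (x in c(1.5, 3.5, 6.5)) {
    widx <- window_markers(d$map, x, 2L)
    f1 <- ldlmap:::estimate_marker_freqs(d)[widx]
    hstar <- as.integer(f1 >= 0.5)   # the most common window haplotype
    params <- list(mu = mu0, sigma2 = s20, alpha = 0, hstar = hstar,
                   piQ0 = prod(ifelse(hstar == 1, f1, 1 - f1)) / 2,
                   t = 10L)
    expect_equal(ldl_loglik(d, x, params), ll0, tolerance = 1e-8)
  }
})

test_that("the EM scan maximum matches the reference likelihood evaluation", {
  scn <- toy_scenario(Ns = 5L, Np = 30L)
  d <- simulate_replicate(scn, seed = 54)
  res <- ldl_scan(d, 2L, t = scn$Ng)
  x <- res$s_hat
  params <- list(mu = res$mu_hat, sigma2 = res$sigma2_hat,
                 alpha = res$alpha_hat,
                 hstar = as.integer(strsplit(res$hstar_hat, "")[[1]]),
                 piQ0 = res$piQ0_hat, t = scn$Ng)
  ll_ref <- ldl_loglik(d, x, params)
  lrt_ref <- 2 * (ll_ref - res$loglik_null)
  expect_equal(res$max_stat, lrt_ref, tolerance = 1e-6)
})

test_that("the LRT profile is non-negative everywhere", {
  scn <- toy_scenario()
  for (s in c(55, 56)) {
    d <- simulate_replicate(scn, seed = s)
    res <- ldl_scan(d, 2L)
    expect_true(all(res$stat >= 0, na.rm = TRUE))
    expect_true(res$s_hat >= min(d$map$positions) &&
                  res$s_hat <= max(d$map$positions))
  }
})

test_that("null data give a conservatively small LRT", {
  scn <- toy_scenario(qtl_effect = 0, Ns = 5L, Np = 20L)
  lrts <- vapply(1:40, function(r) {
    d <- simulate_replicate(scn, seed = split_seed(600L, r))
    res <- ldl_scan(d, 2L)
    res$stat[4L]   # a fixed interior position
  }, numeric(1))
  # two added continuous parameters (alpha, piQ0) maximised over at most 4
  # candidate founder haplotypes: the median should stay below the median
  # of the max of four independent chi^2_2 draws (a conservative envelope)
  expect_lt(median(lrts), qchisq(0.5^(1 / 4), df = 2))
})

test_that("the additive effect is recovered without gross bias", {
  scn <- scenario(Ne = 100L, Ng = 50L, Ns = 10L, Np = 50L, n_markers = 20L,
                  density_cM = 0.5, qtl_effect = 0.5, qtl_position_cM = 3.35)
  alphas <- vapply(1:20, function(r) {
    d <- simulate_replicate(scn, seed = split_seed(700L, r))
    ldl_scan(d, 2L)$alpha_hat
  }, numeric(1))
  expect_gt(mean(alphas), 0)                      # correct sign
  expect_lt(abs(mean(alphas) - 0.5), 0.5 * 0.5)   # |bias| < 50%
})
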