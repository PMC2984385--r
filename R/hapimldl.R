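# Linkage + linkage-disequilibrium likelihood (LDL) scan.
#
# At a tested position x, each progeny's phenotype is modelled as a Gaussian
# mixture over (i) the sire's QTL diplotype (four ordered states QQ, qq, Qq,
# qQ, probabilities from the LD model under Hardy-Weinberg), (ii) the origin
# of the sire-transmitted allele (exact flanking-marker transmission
# probabilities) and (iii) the dam-transmitted allele (LD model at t + 1).
# Sire means, the additive substitution effect, the residual variance, the
# founder haplotype h* and the time-0 frequency of Q are maximised per
# position; the scan statistic is the likelihood-ratio against the
# no-QTL-effect null and the estimated position is the interval midpoint
# with the largest statistic.

#' Sire QTL diplotype probabilities under Hardy-Weinberg
#'
#' @param pQ1,pQ2 Probability that chromosome 1 / 2 carries Q given its
#'   marker haplotype.
#' @return Named probability vector over the four ordered diplotypes
#'   `c(QQ, qq, Qq, qQ)`, renormalised to sum to 1.
#' @export
sire_diplotype_probs <- function(pQ1, pQ2) {
  p <- c(QQ = pQ1 * pQ2,
         qq = (1 - pQ1) * (1 - pQ2),
         Qq = pQ1 * (1 - pQ2),
         qQ = (1 - pQ1) * pQ2)
  p / sum(p)
}

# expand a scalar additive effect into the four (sire allele, dam allele)
# diplotype effects alpha_{Sa}; the additive constraint zeroes the mixed
# states and makes alpha_qq = -alpha_QQ
expand_alpha <- function(alpha) {
  if (length(alpha) == 1L) {
    c(QQ = unname(alpha), Qq = 0, qQ = 0, qq = -unname(alpha))
  } else {
    stopifnot(all(c("QQ", "Qq", "qQ", "qq") %in% names(alpha)))
    alpha[c("QQ", "Qq", "qQ", "qq")]
  }
}

#' Individual LDL likelihood of one progeny
#'
#' The full mixture sum over sire diplotypes z, dam-transmitted allele a and
#' origin of the sire-transmitted allele, with Gaussian densities
#' `phi(y; mu + alpha_{Sa}, sigma2)` where S is the sire-transmitted allele.
#'
#' @param y Phenotype (finite).
#' @param mu Sire-family mean.
#' @param sigma2 Residual variance.
#' @param alpha Either a single additive substitution effect, or a named
#'   vector of the four diplotype effects `c(QQ, Qq, qQ, qq)` (sire allele
#'   first, dam allele second).
#' @param zprobs Sire diplotype probabilities, as from
#'   [sire_diplotype_probs()].
#' @param p_dam_Q Probability that the dam transmitted Q.
#' @param trans Transmission probabilities `c(p1, p2)` from
#'   [transmission_prob()].
#' @return The likelihood contribution (positive scalar).
#' @export
individual_likelihood <- function(y, mu, sigma2, alpha, zprobs, p_dam_Q,
                                  trans) {
  if (!is.finite(y)) stop("phenotype must be finite")
  al <- expand_alpha(alpha)
  I1 <- c(QQ = 1, qq = 0, Qq = 1, qQ = 0)   # chromosome 1 carries Q given z
  I2 <- c(QQ = 1, qq = 0, Qq = 0, qQ = 1)
  pa <- c(Q = p_dam_Q, q = 1 - p_dam_Q)
  lam <- 0
  for (z in c("QQ", "qq", "Qq", "qQ")) {
    wQ <- trans[1] * I1[[z]] + trans[2] * I2[[z]]
    wq <- trans[1] * (1 - I1[[z]]) + trans[2] * (1 - I2[[z]])
    for (a in c("Q", "q")) {
      lam <- lam + zprobs[[z]] * pa[[a]] *
        (stats::dnorm(y, mu + al[[paste0("Q", a)]], sqrt(sigma2)) * wQ +
         stats::dnorm(y, mu + al[[paste0("q", a)]], sqrt(sigma2)) * wq)
    }
  }
  lam
}

# pooled marker allele-1 frequencies estimated from the transmitted
# haplotypes of the sample (drift is frequency-neutral in expectation, so
# the time-t sample estimates stand in for the time-0 frequencies)
estimate_marker_freqs <- function(design) {
  colMeans(rbind(design$pat, design$mat))
}

#' Total LDL log-likelihood of a design at a position
#'
#' Reference (per-progeny) evaluation of the scan objective: the sum over
#' progeny of the log individual likelihoods, at explicit parameter values.
#' [ldl_scan()] maximises the same objective through a fast mixture-EM
#' path.
#'
#' @param design A `halfsib_design` with phenotypes.
#' @param x Tested position (cM).
#' @param params List with `mu` (per-sire means), `sigma2`, `alpha`
#'   (additive effect or four diplotype effects), `hstar` (0/1 founder
#'   haplotype over the window markers), `piQ0`, `t` (generations; dams use
#'   `t + 1`), optional `beta` (default 1) and `n_flanking` (default 2).
#' @return The log-likelihood; zero likelihoods are floored at 1e-300 with
#'   a warning.
#' @export
ldl_loglik <- function(design, x, params) {
  n_flanking <- if (is.null(params$n_flanking)) 2L else params$n_flanking
  beta <- if (is.null(params$beta)) 1 else params$beta
  map <- design$map
  widx <- window_markers(map, x, n_flanking)
  wpos <- map$positions[widx]
  f1 <- estimate_marker_freqs(design)[widx]
  lp <- ld_params(params$hstar, params$piQ0, params$t, f1, beta)

  pQ_memo <- new.env(parent = emptyenv())
  pQ_of <- function(h, t_use) {
    key <- paste0(paste(h, collapse = ""), "@", t_use)
    if (is.null(pQ_memo[[key]])) {
      pQ_memo[[key]] <- suppressWarnings(
        qtl_prob_given_hap(lp, h, 1L, wpos, x, t = t_use))
    }
    pQ_memo[[key]]
  }

  trans <- transmission_probs_design(design, x)
  ll <- 0
  warned <- FALSE
  for (j in seq_len(design$n_progeny)) {
    i <- design$sire[j]
    zp <- sire_diplotype_probs(pQ_of(design$sire_hap1[i, widx], params$t),
                               pQ_of(design$sire_hap2[i, widx], params$t))
    pdQ <- pQ_of(design$mat[j, widx], params$t + 1)
    lam <- individual_likelihood(design$y[j], params$mu[i], params$sigma2,
                                 params$alpha, zp, pdQ, trans[j, ])
    if (lam <= 0) {
      lam <- 1e-300
      if (!warned) {
        warning("zero individual likelihood floored at 1e-300")
        warned <- TRUE
      }
    }
    ll <- ll + log(lam)
  }
  unname(ll)
}

# ---- fast scan path ---------------------------------------------------------

# raw (unclipped) expected frequency used to extract affine coefficients
raw_expected_freq <- function(state, positions, t, alleles) {
  block_sum(state, alleles,
            function(mask, locs) rho_no_recomb(positions[locs])^t)
}

# For a candidate founder haplotype, the expected extended-haplotype
# frequencies E[Pi_{Q,h}(t)] and E[Pi_{q,h}(t)] are affine in piQ0 (the
# time-0 table is affine in piQ0 for fixed beta and the Bennett decay is
# linear), so two evaluations determine them for every window haplotype h.
# Returns coefficient vectors indexed by haplotype code + 1.
ld_affine_coeffs <- function(hstar, marker_freqs, wpos, x, t, beta = 1,
                             pi_hstar) {
  m <- length(hstar)
  ord <- order(c(wpos, x))
  pos_ext <- c(wpos, x)[ord]
  qtl_idx <- which(ord == m + 1L)
  piA <- pi_hstar / 3
  piB <- 2 * pi_hstar / 3
  states <- lapply(c(piA, piB), function(p0) {
    bennett_from_freqs(time0_freqs(
      ld_params(hstar, p0, t, marker_freqs, beta), qtl_idx))
  })
  nh <- 2L^m
  aQ <- bQ <- aq <- bq <- numeric(nh)
  for (code in seq_len(nh) - 1L) {
    h <- index_alleles(code + 1L, m)
    eQ <- ext_q <- numeric(2)
    for (s in 1:2) {
      alleles <- append(h, 1L, after = qtl_idx - 1L)
      eQ[s] <- raw_expected_freq(states[[s]], pos_ext, t, alleles)
      alleles[qtl_idx] <- 0L
      ext_q[s] <- raw_expected_freq(states[[s]], pos_ext, t, alleles)
    }
    bQ[code + 1L] <- (eQ[2] - eQ[1]) / (piB - piA)
    aQ[code + 1L] <- eQ[1] - bQ[code + 1L] * piA
    bq[code + 1L] <- (ext_q[2] - ext_q[1]) / (piB - piA)
    aq[code + 1L] <- ext_q[1] - bq[code + 1L] * piA
  }
  list(aQ = aQ, bQ = bQ, aq = aq, bq = bq)
}

# P(Q | hap code, piQ0) for every window haplotype, replicating the clip
# chain of qtl_prob_given_hap
ld_prob_from_coeffs <- function(cf, piQ0) {
  numQ <- pmin(1, pmax(0, cf$aQ + cf$bQ * piQ0))
  numq <- pmin(1, pmax(0, cf$aq + cf$bq * piQ0))
  den <- numQ + numq
  out <- ifelse(den <= .Machine$double.eps, piQ0, pmin(1, numQ / den))
  out
}

#' LDL likelihood-ratio scan
#'
#' Maximises the LDL likelihood at every marker-interval midpoint over the
#' per-sire means, the additive QTL effect, the residual variance, the
#' time-0 frequency of Q (a bounded continuous nuisance) and the founder
#' haplotype h* (profiled over the window haplotypes observed in the
#' sample), and reports the likelihood-ratio statistic against the null
#' model with no QTL effect (sire means and variance only, fitted once).
#'
#' @param design A `halfsib_design` with phenotypes.
#' @param n_flanking Window size, 2 or 4.
#' @param t Generations since the founder mutation (known in simulations;
#'   dam-transmitted haplotypes use `t + 1`).
#' @param em_tol Convergence tolerance on the log-likelihood of the EM
#'   inner loop.
#' @param em_maxit Maximum EM iterations of a refinement fit (prescreening
#'   fits over the coarse piQ0 grid are capped at `em_maxit / 4`).
#' @param piQ0_grid Coarse profiling grid of the time-0 Q frequency,
#'   expressed as fractions of its admissible upper bound (the estimated
#'   founder-haplotype frequency); the best grid point of the best founder
#'   haplotype is then refined by a bounded line search.
#' @param piQ0_rel_tol Relative tolerance of the refining line search.
#' @param n_starts Number of deterministic starting values of the effect
#'   (0 and symmetric perturbations of +/- half a phenotypic SD) used for
#'   the first fit of each founder haplotype; later fits warm-start from
#'   the previous effect estimate.
#' @return A `scan_result` with per-midpoint `stat` (LRT), the estimated
#'   position `s_hat`, and the fitted `alpha_hat`, `mu_hat`, `sigma2_hat`,
#'   `piQ0_hat` and `hstar_hat` at the best position.
#' @export
ldl_scan <- function(design, n_flanking = 2L, t = design$generations,
                     em_tol = 1e-6, em_maxit = 200L,
                     piQ0_grid = c(0.08, 0.25, 0.5, 0.85),
                     piQ0_rel_tol = 0.05, n_starts = 3L) {
  if (is.null(design$y)) stop("design has no phenotypes")
  if (is.null(t)) stop("t (generations since mutation) must be supplied")
  map <- design$map
  y <- design$y
  sire <- design$sire
  Ns <- design$n_sires
  n <- design$n_progeny
  cnt <- tabulate(sire, Ns)
  mu0 <- as.numeric(rowsum(y, sire) / cnt)
  sig2_0 <- mean((y - mu0[sire])^2)
  ll0 <- sum(stats::dnorm(y, mu0[sire], sqrt(sig2_0), log = TRUE))
  sdy <- stats::sd(y)
  starts0 <- c(0, 0.5 * sdy, -0.5 * sdy)[seq_len(max(1L, n_starts))]

  freqs_all <- estimate_marker_freqs(design)
  mids <- interval_midpoints(map)
  stat <- numeric(length(mids))
  fits <- vector("list", length(mids))

  for (jm in seq_along(mids)) {
    x <- mids[jm]
    widx <- window_markers(map, x, n_flanking)
    wpos <- map$positions[widx]
    f1 <- freqs_all[widx]
    s1 <- hap_codes(design$sire_hap1, widx)
    s2 <- hap_codes(design$sire_hap2, widx)
    dm <- hap_codes(design$mat, widx)
    trans <- transmission_probs_design(design, x)
    s1p <- s1[sire]; s2p <- s2[sire]

    cand <- sort(unique(c(s1, s2, dm)))
    best <- list(loglik = -Inf)
    best_obj <- NULL
    for (hs in cand) {
      hvec <- index_alleles(hs + 1L, length(widx))
      pi_hstar <- prod(ifelse(hvec == 1L, f1, 1 - f1))
      if (pi_hstar < 1e-4) next
      cfS <- ld_affine_coeffs(hvec, f1, wpos, x, t, pi_hstar = pi_hstar)
      cfD <- ld_affine_coeffs(hvec, f1, wpos, x, t + 1, pi_hstar = pi_hstar)
      warm <- new.env(parent = emptyenv())
      obj <- local({
        cfS <- cfS; cfD <- cfD; hvec <- hvec; warm <- warm
        function(piQ0, maxit = em_maxit) {
          pQ_s <- ld_prob_from_coeffs(cfS, piQ0)
          pQ_d <- ld_prob_from_coeffs(cfD, piQ0)
          pS <- trans[, 1] * pQ_s[s1p + 1L] + trans[, 2] * pQ_s[s2p + 1L]
          pd <- pQ_d[dm + 1L]
          st <- if (is.null(warm$alpha)) starts0 else warm$alpha
          fit <- ldl_em_fit(y, sire, Ns, pS, pd, st, mu0, sig2_0,
                            em_tol, maxit)
          warm$alpha <- fit$alpha
          fit$piQ0 <- piQ0
          fit$hstar <- hvec
          fit
        }
      })
      upper <- min(pi_hstar, 1 - 1e-6)
      # coarse profile of piQ0 for this founder haplotype
      for (g in piQ0_grid) {
        fit <- obj(g * upper, maxit = max(25L, em_maxit %/% 4L))
        if (fit$loglik > best$loglik) {
          best <- fit
          best$upper <- upper
          best_obj <- obj
        }
      }
    }
    if (is.finite(best$loglik)) {
      # refine piQ0 around the winning grid point
      upper <- best$upper
      lower <- min(1e-4, upper / 2)
      lo <- max(lower, best$piQ0 / 3)
      hi <- min(upper, best$piQ0 * 3)
      op <- stats::optimize(function(p) best_obj(p)$loglik, c(lo, hi),
                            maximum = TRUE,
                            tol = max(1e-5, piQ0_rel_tol * upper))
      fo <- best_obj(op$maximum)
      if (fo$loglik > best$loglik) best <- fo
    }
    if (!is.finite(best$loglik)) {
      warning("no admissible founder haplotype at ", x, " cM; position skipped")
      stat[jm] <- NA_real_
      next
    }
    stat[jm] <- max(0, 2 * (best$loglik - ll0))
    fits[[jm]] <- best
  }
  if (all(is.na(stat))) stop("all positions skipped")
  interval_hat <- which.max(ifelse(is.na(stat), -Inf, stat))
  bf <- fits[[interval_hat]]
  structure(
    list(method = "hapimldl", n_flanking = as.integer(n_flanking),
         midpoints = mids, stat = stat,
         interval_hat = interval_hat, s_hat = mids[interval_hat],
         max_stat = stat[interval_hat],
         alpha_hat = bf$alpha, mu_hat = bf$mu, sigma2_hat = bf$sigma2,
         piQ0_hat = bf$piQ0,
         hstar_hat = paste(bf$hstar, collapse = ""),
         t = t, loglik_null = ll0),
    class = "scan_result")
}
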