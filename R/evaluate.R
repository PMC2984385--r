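# Replicate orchestration and evaluation metrics: root mean squared error
# of the estimated QTL position over simulation replicates, permutation 5%
# thresholds of the scan maxima, empirical power, and the paired t-test
# comparison of two methods' squared position errors.

#' Root mean squared error of estimated QTL positions
#'
#' `sqrt(sum((s_hat_r - s)^2) / R)` over replicates.
#'
#' @param estimates Estimated positions (cM), one per replicate.
#' @param true_position True QTL position (cM).
#' @return Root-MSE in cM.
#' @export
root_mse <- function(estimates, true_position) {
  if (length(estimates) < 1L) stop("no estimates")
  sqrt(mean((estimates - true_position)^2))
}

#' Monte-Carlo standard error of a root-MSE estimate
#'
#' Delta-method standard error: `se(MSE) / (2 * rootMSE)` with `se(MSE)`
#' the standard error of the mean squared error over replicates.
#'
#' @inheritParams root_mse
#' @return Standard error in cM.
#' @export
root_mse_se <- function(estimates, true_position) {
  r <- length(estimates)
  if (r < 2L) return(NA_real_)
  sq <- (estimates - true_position)^2
  rmse <- sqrt(mean(sq))
  if (rmse <= 0) return(0)
  stats::sd(sq) / sqrt(r) / (2 * rmse)
}

# maximum scan statistic of a design for one method
scan_max_stat <- function(design, method = c("haplomax", "ldl"),
                          n_flanking = 2L, t = design$generations, ...) {
  method <- match.arg(method)
  if (method == "haplomax") {
    haplomax_scan(design, n_flanking)$max_stat
  } else {
    ldl_scan(design, n_flanking, t = t, ...)$max_stat
  }
}

# within-sire-family permutation of a phenotype vector
permute_within_families <- function(y, sire) {
  out <- y
  for (i in unique(sire)) {
    rows <- which(sire == i)
    out[rows] <- y[rows[sample.int(length(rows))]]
  }
  out
}

#' Permutation threshold of the maximum scan statistic
#'
#' Phenotypes are permuted within sire families (preserving the family
#' structure under the no-QTL null); the threshold is the empirical
#' `1 - level` quantile (the `ceiling((1 - level) * n_perm)`-th order
#' statistic) of the maximum statistic over permutations.
#'
#' @param design A `halfsib_design` with phenotypes.
#' @param method `"haplomax"` or `"ldl"`.
#' @param level Significance level (default 0.05).
#' @param n_perm Number of permutations; must be at least `1 / level`.
#' @param n_flanking Window size, 2 or 4.
#' @param t Generations (LDL method only).
#' @return The threshold (scalar).
#' @export
permutation_threshold <- function(design, method = c("haplomax", "ldl"),
                                  level = 0.05, n_perm = 1000L,
                                  n_flanking = 2L,
                                  t = design$generations) {
  method <- match.arg(method)
  if (n_perm < 1 / level) stop("n_perm must be at least 1/level")
  stats_perm <- perm_max_stats(design, method, n_perm, n_flanking, t)
  sort(stats_perm)[ceiling((1 - level) * n_perm)]
}

# vector of n_perm max statistics under within-family permutation; the
# HaploMax path evaluates all permutations with one matrix product
perm_max_stats <- function(design, method, n_perm, n_flanking, t) {
  if (method == "haplomax") {
    prep <- haplomax_prepare(design, n_flanking)
    if (ncol(prep$Dtil) == 0L) return(rep(0, n_perm))
    Y <- vapply(seq_len(n_perm),
                function(p) permute_within_families(design$y, design$sire),
                numeric(design$n_progeny))
    F <- haplomax_stats(prep, Y)
    apply(F, 2L, max)
  } else {
    vapply(seq_len(n_perm), function(p) {
      d <- design
      d$y <- permute_within_families(design$y, design$sire)
      ldl_scan(d, n_flanking, t = t)$max_stat
    }, numeric(1))
  }
}

#' Empirical power of a scan at the permutation threshold
#'
#' Simulates accepted replicates of a scenario, computes each replicate's
#' maximum scan statistic and its own within-family permutation threshold,
#' and returns the fraction of replicates declared significant.
#'
#' @param scn A [scenario()].
#' @param method `"haplomax"` or `"ldl"`.
#' @param n_replicates Number of accepted replicates.
#' @param n_perm Permutations per replicate.
#' @param level Significance level.
#' @param seed Master seed; replicate seeds derive via [split_seed()].
#' @param n_flanking Window size.
#' @return List with `power`, per-replicate `max_stat`, `threshold` and
#'   `significant`.
#' @export
power_estimate <- function(scn, method = c("haplomax", "ldl"),
                           n_replicates = 100L, n_perm = 200L,
                           level = 0.05, seed = 1L, n_flanking = 2L) {
  method <- match.arg(method)
  ms <- thr <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    design <- simulate_replicate(scn, seed = split_seed(seed, r))
    ms[r] <- scan_max_stat(design, method, n_flanking)
    thr[r] <- permutation_threshold(design, method, level, n_perm,
                                    n_flanking)
  }
  sig <- ms > thr
  list(power = mean(sig), max_stat = ms, threshold = thr, significant = sig)
}

#' Paired t-test comparison of two methods' squared position errors
#'
#' @param squared_errors_A,squared_errors_B Per-replicate squared position
#'   errors of the two methods (paired by replicate).
#' @return The two-sided p-value; identical inputs give 1.
#' @export
compare_methods_ttest <- function(squared_errors_A, squared_errors_B) {
  stopifnot(length(squared_errors_A) == length(squared_errors_B))
  if (length(squared_errors_A) < 2L) stop("need at least 2 replicates")
  d <- squared_errors_A - squared_errors_B
  if (all(abs(d - mean(d)) < 1e-12)) {
    return(if (abs(mean(d)) < 1e-12) 1 else 0)
  }
  stats::t.test(squared_errors_A, squared_errors_B, paired = TRUE)$p.value
}

#' Run replicated scans of one scenario
#'
#' Simulates `n_replicates` accepted designs (discard-and-redraw happens
#' inside each replicate's own random stream) and runs the requested scans
#' on each.
#'
#' @param scn A [scenario()].
#' @param methods Character vector among `"haplomax"`, `"ldl"`.
#' @param n_replicates Number of accepted replicates.
#' @param seed Master seed.
#' @param n_flanking Window size(s); recycled along `methods`.
#' @return A data.frame with one row per replicate x method: `replicate`,
#'   `method`, `n_flanking`, `s_hat`, `max_stat`, `sq_error`.
#' @export
run_replicates <- function(scn, methods = "haplomax", n_replicates = 100L,
                           seed = 1L, n_flanking = 2L) {
  n_flanking <- rep_len(n_flanking, length(methods))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    design <- simulate_replicate(scn, seed = split_seed(seed, r))
    for (k in seq_along(methods)) {
      res <- if (methods[k] == "haplomax") {
        haplomax_scan(design, n_flanking[k])
      } else {
        ldl_scan(design, n_flanking[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = methods[k], n_flanking = n_flanking[k],
        s_hat = res$s_hat, max_stat = res$max_stat,
        sq_error = (res$s_hat - scn$qtl_position_cM)^2)
    }
  }
  do.call(rbind, rows)
}

#' Root-MSE table over a scenario grid
#'
#' @param scenarios Named list of [scenario()] objects.
#' @param methods Methods to run (see [run_replicates()]).
#' @param n_replicates Accepted replicates per scenario.
#' @param seed Master seed (replicate r of every scenario uses the same
#'   derived seed, pairing scenarios and methods by replicate).
#' @param n_flanking Window size(s), recycled along `methods`.
#' @return Data.frame with one row per scenario x method: `scenario`,
#'   `method`, `n_flanking`, `root_mse`, `mc_se`, `n_replicates`.
#' @export
run_table <- function(scenarios, methods = "haplomax", n_replicates = 100L,
                      seed = 1L, n_flanking = 2L) {
  stopifnot(length(names(scenarios)) == length(scenarios))
  out <- list()
  for (nm in names(scenarios)) {
    scn <- scenarios[[nm]]
    reps <- run_replicates(scn, methods, n_replicates, seed, n_flanking)
    for (k in seq_along(methods)) {
      sel <- reps$method == methods[k] &
        reps$n_flanking == rep_len(n_flanking, length(methods))[k]
      est <- reps$s_hat[sel]
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, method = methods[k],
        n_flanking = rep_len(n_flanking, length(methods))[k],
        root_mse = root_mse(est, scn$qtl_position_cM),
        mc_se = root_mse_se(est, scn$qtl_position_cM),
        n_replicates = n_replicates)
    }
  }
  do.call(rbind, out)
}
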