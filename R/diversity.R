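#' Haplotype (gene) diversity with standard deviation
#'
#' Nei's unbiased gene diversity
#' \deqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with its sampling variance (Nei 1987, eq. 8.12):
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}}
#'
#' @param counts Integer vector of haplotype counts for one population.
#' @return List with \code{h} and \code{sd}, or both \code{NA} when
#'   \code{sum(counts) < 2}.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) return(list(h = NA_real_, sd = NA_real_))
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  h <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(h = h, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity with standard deviation
#'
#' Mean proportion of differing sites over all sequence pairs, with
#' pairwise deletion of ambiguous positions; the sampling standard
#' deviation uses Nei's total variance (Nei 1987, eq. 10.7), which
#' includes the stochastic (coalescent) component:
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}
#'
#' @param aln A \code{coi_alignment} (one population).
#' @param percent Report \code{pi} (and its SD) multiplied by 100.
#' @return List with \code{pi}, \code{sd} and \code{mean_pairwise_diff}
#'   (the unscaled mean number of differing sites per pair).
#' @export
nucleotide_diversity <- function(aln, percent = FALSE) {
  n <- nrow(aln)
  if (n < 2L) return(list(pi = NA_real_, sd = NA_real_, mean_pairwise_diff = NA_real_))
  chars <- unclass(aln)
  valid <- chars != "N" & chars != "-"
  tot_prop <- 0; tot_diff <- 0; npair <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    nok <- sum(ok)
    d <- sum(chars[i, ok] != chars[j, ok])
    if (nok > 0L) tot_prop <- tot_prop + d / nok
    tot_diff <- tot_diff + d
    npair <- npair + 1L
  }
  pi <- tot_prop / npair
  L <- ncol(aln)
  v <- (n + 1) / (3 * (n - 1) * L) * pi + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  scale <- if (percent) 100 else 1
  list(pi = pi * scale, sd = sqrt(max(v, 0)) * scale,
       mean_pairwise_diff = tot_diff / npair)
}

# segregating sites: columns with >1 distinct unambiguous base
segregating_sites <- function(aln) {
  chars <- unclass(aln)
  sum(apply(chars, 2L, function(col) {
    b <- unique(col[col != "N" & col != "-"])
    length(b) > 1L
  }))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D neutrality test
#'
#' Contrasts the mean number of pairwise differences with the Watterson
#' estimate \eqn{S/a_1} of theta; strongly negative values indicate an
#' excess of rare variants, as expected after a population expansion or a
#' selective sweep. The p-value is obtained by neutral coalescent
#' simulation conditioned on the sample size and on theta estimated from
#' the mean pairwise differences, as population-genetics packages
#' conventionally do; it is the lower-tail proportion of simulated D
#' values at or below the observed one (values above 0.5 thus indicate a
#' positive D).
#'
#' @param aln A \code{coi_alignment} for a single population.
#' @param nsim Number of coalescent replicates for the p-value; 0 skips it.
#' @param seed Seed for the simulation.
#' @return List with \code{D}, \code{p_value}, \code{S},
#'   \code{mean_pairwise_diff}; \code{D} is \code{NA} when \code{n < 4} or
#'   no site segregates.
#' @export
tajimas_d <- function(aln, nsim = 10000L, seed = NULL) {
  n <- nrow(aln)
  S <- segregating_sites(aln)
  k <- nucleotide_diversity(aln)$mean_pairwise_diff
  if (n < 4L || S < 1L)
    return(list(D = NA_real_, p_value = NA_real_, S = S, mean_pairwise_diff = k))
  D <- tajimas_d_stat(n, S, k)
  p <- NA_real_
  if (nsim > 0L) {
    sims <- simulate_neutral_stats(n = n, theta = k, L = ncol(aln),
                                   nsim = nsim, seed = seed)
    ok <- !is.na(sims$D)
    p <- if (any(ok)) mean(sims$D[ok] <= D) else NA_real_
  }
  list(D = D, p_value = p, S = S, mean_pairwise_diff = k)
}

tajimas_d_stat <- function(n, S, k) {
  cst <- tajima_constants(n)
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (k - S / cst$a1) / denom
}

#' Fu's Fs neutrality test
#'
#' Based on the probability, under the Ewens sampling formula with theta
#' set to the mean number of pairwise differences, of observing at least
#' as many distinct haplotypes as sampled:
#' \deqn{F_s = \ln\frac{S'}{1-S'},\qquad S' = \Pr(K \ge k_{obs})}
#' Large negative values indicate an excess of alleles, the signature of
#' a recent population expansion. The p-value is the proportion of
#' neutral coalescent replicates with \eqn{F_s} at or below the observed
#' value; note the conventional significance threshold for Fs is 0.02
#' rather than 0.05 (reported, never applied silently).
#'
#' @inheritParams tajimas_d
#' @return List with \code{Fs}, \code{p_value}, \code{k_obs},
#'   \code{theta_pi}, and \code{note} (set when Fs is infinite or
#'   undefined).
#' @export
fus_fs <- function(aln, nsim = 10000L, seed = NULL) {
  n <- nrow(aln)
  theta <- nucleotide_diversity(aln)$mean_pairwise_diff
  k_obs <- n_haplotypes(collapse_haplotypes(aln))
  if (n < 2L || is.na(theta) || theta == 0)
    return(list(Fs = NA_real_, p_value = NA_real_, k_obs = k_obs,
                theta_pi = theta, note = "monomorphic sample"))
  Fs <- fus_fs_stat(n, theta, k_obs)
  if (!is.finite(Fs))
    return(list(Fs = NA_real_, p_value = NA_real_, k_obs = k_obs,
                theta_pi = theta, note = "S' degenerate (0 or 1)"))
  p <- NA_real_
  if (nsim > 0L) {
    sims <- simulate_neutral_stats(n = n, theta = theta, L = ncol(aln),
                                   nsim = nsim, seed = seed)
    ok <- is.finite(sims$Fs)
    p <- if (any(ok)) mean(sims$Fs[ok] <= Fs) else NA_real_
  }
  list(Fs = Fs, p_value = p, k_obs = k_obs, theta_pi = theta, note = "")
}

fus_fs_stat <- function(n, theta, k_obs) {
  lp <- ewens_log_probs(n, theta)        # log Pr(K = 1..n)
  log_Sp <- log_sum_exp(lp[k_obs:n])     # Pr(K >= k_obs)
  Sp <- exp(log_Sp)
  if (Sp >= 1 || Sp <= 0) return(if (Sp >= 1) -Inf else Inf)
  # ln(S'/(1-S')) with 1-S' computed stably from the lower tail
  log_1mSp <- if (k_obs > 1L) log_sum_exp(lp[1:(k_obs - 1L)]) else -Inf
  if (!is.finite(log_1mSp)) return(Inf)
  log_Sp - log_1mSp
}

#' Ewens allele-count distribution
#'
#' Probabilities \eqn{\Pr(K=k\mid\theta,n)} of observing k distinct
#' alleles in a sample of n under the neutral infinite-alleles model:
#' \deqn{\Pr(K=k) = \frac{|s(n,k)|\,\theta^k}{\theta_{(n)}}}
#' with unsigned Stirling numbers of the first kind \eqn{|s(n,k)|} and
#' rising factorial \eqn{\theta_{(n)}}, computed in log space by the
#' Stirling recursion so that it remains exact for large n.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of length n of log-probabilities for k = 1..n.
#' @export
ewens_log_probs <- function(n, theta) {
  stopifnot(n >= 1L, theta > 0)
  ls <- log_stirling_first(n)            # log |s(n, k)| for k = 1..n
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1L)))
  lp - log_sum_exp(lp)                   # guard rounding; sums to 1 exactly
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n),
# via |s(m+1,k)| = |s(m,k-1)| + m * |s(m,k)| in log space
log_stirling_first <- function(n) {
  row <- 0                               # row m = 1: |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in 1:(n - 1L)) {
    new <- numeric(m + 1L)
    new[1L] <- log(m) + row[1L]                       # k = 1
    if (m > 1L)
      new[2:m] <- vapply(2:m, function(k)
        log_sum_exp(c(row[k - 1L], log(m) + row[k])), numeric(1))
    new[m + 1L] <- row[m]                             # k = m + 1
    row <- new
  }
  row
}

log_sum_exp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# neutral-coalescent null distribution of D and Fs, conditioning on n and
# theta (constant population size); reuses the package's own simulator
simulate_neutral_stats <- function(n, theta, L, nsim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L_sim <- max(L, 2000L)  # generous site count so infinite sites never saturates
  D <- Fs <- numeric(nsim)
  for (b in seq_len(nsim)) {
    aln <- simulate_expansion(expansion_config(n = n, tau = 0, theta0 = theta,
                                               theta1 = theta, L = L_sim,
                                               seed = NULL))
    S <- segregating_sites(aln)
    if (S == 0L) { D[b] <- NA; Fs[b] <- NA; next }
    k <- nucleotide_diversity(aln)$mean_pairwise_diff
    D[b] <- tajimas_d_stat(n, S, k)
    Fs[b] <- if (k > 0) fus_fs_stat(n, k, n_haplotypes(collapse_haplotypes(aln))) else NA
  }
  list(D = D, Fs = Fs)
}
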