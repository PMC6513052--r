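#' Observed mismatch distribution
#'
#' Relative frequency of pairwise difference counts over all sequence
#' pairs of one population sample. Under a sudden demographic expansion
#' the distribution is smooth and unimodal with mode near tau; at
#' demographic equilibrium it is typically ragged or multimodal.
#'
#' @param aln A \code{coi_alignment} for one population (n >= 2).
#' @return Numeric vector of frequencies for 0, 1, ... ,max difference
#'   classes; sums to 1. Names give the difference count.
#' @export
mismatch_distribution <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("mismatch distribution needs at least 2 sequences")
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  d <- diff_count_matrix(seqs)
  diffs <- d[upper.tri(d)]
  tab <- tabulate(diffs + 1L, nbins = max(diffs) + 1L)
  stats::setNames(tab / sum(tab), 0:max(diffs))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The classic closed form for the distribution of pairwise differences
#' after an instantaneous change of the scaled population size from
#' \code{theta0} to \code{theta1} at mutational time \code{tau} before the
#' present. With the equilibrium distribution
#' \eqn{\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}}:
#' \deqn{F_i(\tau,\theta_0,\theta_1) = \hat F_i(\theta_1) +
#'   e^{-\tau(\theta_1+1)/\theta_1}\sum_{j=0}^{i}\frac{\tau^j}{j!}
#'   \left[\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)\right]}
#'
#' @param tau Mutational time since the expansion (\eqn{\tau = 2ut}).
#' @param theta0,theta1 Scaled population sizes before/after expansion.
#' @param max_diff Largest difference class to evaluate.
#' @param renormalize Rescale so the truncated vector sums to 1 (used when
#'   comparing with an observed distribution of finite support).
#' @return Numeric vector of expected frequencies for classes
#'   0..\code{max_diff}.
#' @export
expected_mismatch <- function(tau, theta0, theta1, max_diff,
                              renormalize = TRUE) {
  i <- 0:max_diff
  Feq <- function(th) if (th == 0) c(1, rep(0, max_diff)) else
    th^i / (th + 1)^(i + 1)
  f1 <- Feq(theta1); f0 <- Feq(theta0)
  if (tau == 0) {
    out <- f0  # no time has passed: pairs behave as in the ancestral pool
  } else {
    decay <- exp(-tau * (theta1 + 1) / max(theta1, 1e-12))
    pois <- exp(i * log(tau) - lgamma(i + 1))  # tau^j / j!
    conv <- vapply(i, function(k) {
      j <- 0:k
      sum(pois[j + 1L] * (f0[k - j + 1L] - f1[k - j + 1L]))
    }, numeric(1))
    out <- f1 + decay * conv
  }
  out <- pmax(out, 0)
  if (renormalize && sum(out) > 0) out <- out / sum(out)
  stats::setNames(out, i)
}

#' Harpending's raggedness index
#'
#' \deqn{r = \sum_{i=1}^{d}(x_i - x_{i-1})^2} over the observed
#' difference classes \eqn{x_0..x_d} (no zero padding beyond the observed
#' support — conventions differ between programs, so the one used here is
#' stated explicitly). Smooth unimodal distributions give small r.
#'
#' @param freq Mismatch frequency vector (classes 0..d).
#' @return Non-negative scalar.
#' @export
raggedness_index <- function(freq) {
  if (length(freq) < 2L) return(0)
  sum(diff(freq)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Finds \code{(tau, theta0, theta1)} minimizing the sum of squared
#' deviations (SSD) between the observed and expected mismatch
#' distribution, by multi-start Nelder–Mead on log-transformed parameters
#' (theta1 parameterized as theta0 + exp(c), so the constraint
#' theta1 >= theta0 >= 0 holds by construction; theta1 capped at 1e5).
#' Goodness-of-fit p-values come from a parametric bootstrap: \code{B}
#' coalescent datasets are simulated under the fitted expansion, each is
#' refitted, and p is the proportion of bootstrap SSD (resp. raggedness)
#' at or above the observed value — a LARGE p means the expansion model
#' cannot be rejected.
#'
#' @param observed Observed mismatch frequency vector (from
#'   [mismatch_distribution()]).
#' @param n Sample size underlying \code{observed} (needed for the
#'   bootstrap).
#' @param L Sequence length for the bootstrap simulations.
#' @param B Number of parametric-bootstrap replicates; 0 skips p-values.
#' @param seed Seed for multi-start jitter and the bootstrap.
#' @param starts Number of Nelder–Mead starts.
#' @return Object of class \code{mismatch_fit}: list with \code{tau},
#'   \code{theta0}, \code{theta1}, \code{ssd}, \code{raggedness},
#'   \code{p_ssd}, \code{p_raggedness}, \code{observed}, \code{expected},
#'   \code{convergence}.
#' @export
fit_sudden_expansion <- function(observed, n, L = 600L, B = 1000L,
                                 seed = NULL, starts = 3L) {
  if (length(observed) < 2L) stop("need at least 2 mismatch classes to fit")
  if (!is.null(seed)) set.seed(seed)
  maxd <- length(observed) - 1L
  classes <- 0:maxd
  mean_d <- sum(classes * observed)

  obj <- function(par) {
    tau <- exp(par[1]); th0 <- exp(par[2]); th1 <- min(th0 + exp(par[3]), 1e5)
    e <- expected_mismatch(tau, th0, th1, maxd)
    sum((observed - e)^2)
  }
  start_list <- list(
    c(log(max(mean_d, 0.5)), log(0.1), log(100)),
    c(log(max(mean_d / 2, 0.25)), log(max(mean_d / 4, 0.05)), log(max(10 * mean_d, 10))),
    c(log(max(2 * mean_d, 1)), log(0.01), log(1000)))
  if (starts > 3L) for (s in 4:starts)
    start_list[[s]] <- start_list[[1L]] + stats::rnorm(3, 0, 0.5)
  start_list <- start_list[seq_len(min(starts, length(start_list)))]

  best <- NULL
  for (st in start_list) {
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tau <- exp(best$par[1]); theta0 <- exp(best$par[2])
  theta1 <- min(theta0 + exp(best$par[3]), 1e5)
  expected <- expected_mismatch(tau, theta0, theta1, maxd)
  ssd <- sum((observed - expected)^2)
  hri <- raggedness_index(observed)

  p_ssd <- p_hri <- NA_real_
  if (B > 0L) {
    boot_ssd <- boot_hri <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      sim <- simulate_expansion(expansion_config(n = n, tau = tau,
                                                 theta0 = theta0,
                                                 theta1 = min(theta1, 1e3),
                                                 L = L, seed = NULL))
      om <- mismatch_distribution(sim)
      if (length(om) < 2L) { boot_ssd[b] <- 0; boot_hri[b] <- raggedness_index(om); next }
      refit <- fit_sudden_expansion(om, n = n, B = 0L, starts = 2L)
      boot_ssd[b] <- refit$ssd
      boot_hri[b] <- refit$raggedness
    }
    p_ssd <- mean(boot_ssd >= ssd, na.rm = TRUE)
    p_hri <- mean(boot_hri >= hri, na.rm = TRUE)
  }

  structure(list(tau = tau, theta0 = theta0, theta1 = theta1, ssd = ssd,
                 raggedness = hri, p_ssd = p_ssd, p_raggedness = p_hri,
                 observed = observed, expected = expected, n = n,
                 convergence = best$convergence), class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat("Sudden-expansion mismatch fit\n")
  cat(sprintf("  tau = %.3f   theta0 = %.4f   theta1 = %.3g\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f (p = %s)   raggedness = %.5f (p = %s)\n",
              x$ssd, fmt_p(x$p_ssd), x$raggedness, fmt_p(x$p_raggedness)))
  cat("  (large p: sudden-expansion model not rejected)\n")
  invisible(x)
}

#' @export
coef.mismatch_fit <- function(object, ...) {
  c(tau = object$tau, theta0 = object$theta0, theta1 = object$theta1)
}

#' @export
plot.mismatch_fit <- function(x, ...) {
  classes <- as.integer(names(x$observed))
  graphics::plot(classes, x$observed, type = "h", lwd = 3,
                 xlab = "pairwise differences", ylab = "frequency", ...)
  graphics::lines(classes, x$expected, col = 2, lwd = 2)
  graphics::legend("topright", legend = c("observed", "expected (expansion)"),
                   col = c(1, 2), lwd = c(3, 2), bty = "n")
  invisible(x)
}

fmt_p <- function(p) if (is.na(p)) "NA" else sprintf("%.3f", p)
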