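#' Mantel test of matrix correlation (isolation by distance)
#'
#' Correlates two symmetric distance matrices over the same ordered site
#' set, e.g. pairwise PhiST against marine-pathway geographic distances.
#' Reports the classic Mantel Z statistic (sum of element-wise products
#' over the upper triangle), the Pearson correlation r of the
#' off-diagonal entries, and a one-tailed permutation p-value obtained by
#' jointly permuting rows and columns of one matrix (proportion of
#' permutations with r at least the observed value).
#'
#' When \code{exact = TRUE} (or n! <= nperm) all n! relabelings are
#' enumerated and the p-value is exact: the proportion of the full
#' permutation distribution (identity included) with r >= observed.
#'
#' @param genetic,geographic Symmetric numeric matrices with identical
#'   dimnames order.
#' @param nperm Number of random permutations.
#' @param seed Seed for the random permutations.
#' @param exact Force exhaustive enumeration of all n! permutations.
#' @return Object of class \code{mantel_test}: list with \code{Z},
#'   \code{r}, \code{p_value}, \code{nperm} (actual count used),
#'   \code{exact}, \code{seed}. \code{r} is \code{NA} (flagged in
#'   \code{note}) when either matrix is constant off-diagonal.
#' @export
mantel_test <- function(genetic, geographic, nperm = 10000L, seed = NULL,
                        exact = FALSE) {
  g <- as.matrix(genetic); d <- as.matrix(geographic)
  if (!all(dim(g) == dim(d))) stop("matrices differ in dimension")
  n <- nrow(g)
  if (!is.null(rownames(g)) && !is.null(rownames(d)) &&
      !identical(rownames(g), rownames(d)))
    stop("matrices must share the same ordered site set")
  ut <- upper.tri(g)
  Z <- sum(g[ut] * d[ut])
  if (stats::sd(g[ut]) == 0 || stats::sd(d[ut]) == 0) {
    return(structure(list(Z = Z, r = NA_real_, p_value = NA_real_,
                          nperm = 0L, exact = FALSE, seed = seed,
                          note = "constant matrix; correlation undefined"),
                     class = "mantel_test"))
  }
  r_obs <- stats::cor(g[ut], d[ut])

  nfact <- factorial(n)
  if (exact || nfact <= nperm) {
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) {
      dp <- d[p, p]
      stats::cor(g[ut], dp[ut])
    }, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    return(structure(list(Z = Z, r = r_obs, p_value = p, nperm = length(perms),
                          exact = TRUE, seed = seed, note = ""),
                     class = "mantel_test"))
  }

  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(nperm)) {
    p <- sample.int(n)
    dp <- d[p, p]
    if (stats::cor(g[ut], dp[ut]) >= r_obs - 1e-12) hits <- hits + 1L
  }
  structure(list(Z = Z, r = r_obs, p_value = (hits + 1) / (nperm + 1),
                 nperm = nperm, exact = FALSE, seed = seed, note = ""),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat("Mantel test\n")
  if (!is.na(x$r)) {
    cat(sprintf("  Z = %.4g   r = %.4f   p (one-tailed, %s%d perms) = %.4g\n",
                x$Z, x$r, if (x$exact) "exact, " else "", x$nperm, x$p_value))
  } else {
    cat("  ", x$note, "\n")
  }
  invisible(x)
}

# all permutations of 1..n as a list (n <= 9 or so)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}
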