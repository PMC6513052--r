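#' Analysis of molecular variance (AMOVA)
#'
#' Decomposes the total sum of squared molecular distances (pairwise
#' difference counts by default) into variance components and
#' Phi-statistics, following the classic weighted sums-of-squares
#' formulation for unequal sample sizes. One-level AMOVA (populations
#' only) yields PhiST; with a grouping of populations the hierarchical
#' decomposition additionally yields PhiCT (among groups) and PhiSC
#' (among populations within groups).
#'
#' Significance is assessed by permutation, one-tailed (proportion of
#' permuted statistics >= observed, with the +1 correction so p is never
#' exactly 0):
#' \itemize{
#'   \item PhiST — individuals permuted among populations;
#'   \item PhiSC — individuals permuted among populations within their
#'     group;
#'   \item PhiCT — whole populations permuted among groups.
#' }
#'
#' @param aln A \code{coi_alignment} whose \code{site} attribute assigns
#'   every sequence to a population, or \code{NULL} if \code{d} is given.
#' @param grouping Optional named list of character vectors of site codes
#'   (a grouping scheme); when supplied a hierarchical AMOVA is run.
#' @param nperm Number of permutations (0 skips p-values).
#' @param seed Seed for the permutations.
#' @param d Optional precomputed squared-distance matrix (difference
#'   counts) with rownames matching sequence ids; computed from
#'   \code{aln} when missing.
#' @param pop Optional population factor overriding the alignment's site
#'   attribute.
#' @return Object of class \code{amova_fit}: list with \code{components}
#'   (data frame: source, df, SS, variance, percent), \code{phi}
#'   (named vector), \code{p_value} (named vector), \code{nperm},
#'   \code{seed}.
#' @examples
#' aln <- as_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTAA", b2 = "TTAA"),
#'                     site_code = c("A", "A", "B", "B"))
#' amova(aln, nperm = 99, seed = 1)  # fixed difference: PhiST = 1
#' @export
amova <- function(aln, grouping = NULL, nperm = 10000L, seed = NULL,
                  d = NULL, pop = NULL) {
  if (is.null(d)) {
    seqs <- apply(unclass(aln), 1L, paste, collapse = "")
    names(seqs) <- rownames(aln)
    d <- diff_count_matrix(seqs)
  }
  if (is.null(pop)) pop <- site_of(aln)
  pop <- as.character(pop)
  if (anyNA(pop)) stop("every sequence needs a population (site) label")
  sizes <- table(pop)
  if (any(sizes < 1L)) stop("empty population")
  if (length(sizes) < 2L) stop("AMOVA needs at least 2 populations")

  group <- NULL
  if (!is.null(grouping)) {
    if (length(grouping) < 2L) stop("hierarchical AMOVA needs at least 2 groups")
    group_of <- unlist(lapply(names(grouping), function(g)
      stats::setNames(rep(g, length(grouping[[g]])), grouping[[g]])))
    miss <- setdiff(unique(pop), names(group_of))
    if (length(miss)) stop("population(s) not covered by grouping: ",
                           paste(miss, collapse = ", "))
    group <- unname(group_of[pop])
  }

  obs <- amova_components(d, pop, group)
  if (all(obs$sigma == 0)) {
    warning("no molecular variance in the data; Phi undefined")
  }

  pv <- stats::setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  if (nperm > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(pop)
    hits <- stats::setNames(numeric(length(obs$phi)), names(obs$phi))
    if (is.null(group)) {
      for (b in seq_len(nperm)) {
        perm <- amova_components(d, sample(pop), NULL)
        hits["PhiST"] <- hits["PhiST"] + (perm$phi["PhiST"] >= obs$phi["PhiST"])
      }
    } else {
      pops <- names(sizes)
      pop_group <- group[match(pops, pop)]   # group of each population
      for (b in seq_len(nperm)) {
        # PhiST: individuals among all populations (groups follow the pops)
        p1 <- sample(pop)
        g1 <- unname(stats::setNames(pop_group, pops)[p1])
        hits["PhiST"] <- hits["PhiST"] +
          (amova_components(d, p1, g1)$phi["PhiST"] >= obs$phi["PhiST"])
        # PhiSC: individuals among populations within their group
        p2 <- pop
        for (g in unique(group)) {
          idx <- which(group == g)
          p2[idx] <- sample(pop[idx])
        }
        hits["PhiSC"] <- hits["PhiSC"] +
          (amova_components(d, p2, group)$phi["PhiSC"] >= obs$phi["PhiSC"])
        # PhiCT: whole populations among groups
        gperm <- sample(pop_group)
        g3 <- unname(stats::setNames(gperm, pops)[pop])
        hits["PhiCT"] <- hits["PhiCT"] +
          (amova_components(d, pop, g3)$phi["PhiCT"] >= obs$phi["PhiCT"])
      }
    }
    pv <- (hits + 1) / (nperm + 1)
    pv[is.na(obs$phi)] <- NA_real_
  }

  structure(list(components = obs$components, phi = obs$phi, p_value = pv,
                 nperm = nperm, seed = seed), class = "amova_fit")
}

# variance decomposition from a squared-distance matrix and labels;
# group = NULL gives the one-level design
amova_components <- function(d, pop, group = NULL) {
  n <- nrow(d)
  pops <- unique(pop)
  P <- length(pops)
  np <- vapply(pops, function(p) sum(pop == p), numeric(1))

  ss_pair <- function(idx) if (length(idx) < 2L) 0 else
    sum(d[idx, idx][upper.tri(d[idx, idx])])
  ss_total <- ss_pair(seq_len(n)) / n
  ss_wp <- sum(vapply(pops, function(p) {
    idx <- which(pop == p)
    ss_pair(idx) / length(idx)
  }, numeric(1)))

  if (is.null(group)) {
    df_ap <- P - 1L; df_wp <- n - P
    ss_ap <- ss_total - ss_wp
    ms_wp <- ss_wp / df_wp
    ms_ap <- ss_ap / df_ap
    nbar <- (n - sum(np^2) / n) / df_ap
    sigma_w <- ms_wp
    sigma_a <- (ms_ap - sigma_w) / nbar
    tot <- sigma_a + sigma_w
    phi <- c(PhiST = if (tot > 0) sigma_a / tot else NA_real_)
    comp <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(df_ap, df_wp, n - 1L),
      SS = c(ss_ap, ss_wp, ss_total),
      variance = c(sigma_a, sigma_w, tot),
      percent = if (tot > 0) 100 * c(sigma_a, sigma_w, tot) / tot else NA_real_,
      stringsAsFactors = FALSE)
    return(list(components = comp, phi = phi,
                sigma = c(a = sigma_a, w = sigma_w)))
  }

  groups <- unique(group)
  G <- length(groups)
  pop_group <- group[match(pops, pop)]
  ng <- vapply(groups, function(g) sum(group == g), numeric(1))
  ss_g <- sum(vapply(groups, function(g) {
    idx <- which(group == g)
    ss_pair(idx) / length(idx)
  }, numeric(1)))

  df_ag <- G - 1L
  df_ap <- P - G
  df_wp <- n - P
  ss_ag <- ss_total - ss_g
  ss_ap <- ss_g - ss_wp

  # expected-mean-square coefficients for unequal sizes
  n1 <- (n - sum(vapply(groups, function(g) {
    pg <- pops[pop_group == g]
    sum(np[pg]^2) / sum(np[pg])
  }, numeric(1)))) / df_ap
  n2 <- (sum(vapply(groups, function(g) {
    pg <- pops[pop_group == g]
    sum(np[pg]^2) / sum(np[pg])
  }, numeric(1))) - sum(np^2) / n) / df_ag
  n3 <- (n - sum(ng^2) / n) / df_ag

  ms_wp <- ss_wp / df_wp
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else 0
  ms_ag <- ss_ag / df_ag
  sigma_c <- ms_wp
  sigma_b <- if (df_ap > 0) (ms_ap - sigma_c) / n1 else 0
  sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  tot <- sigma_a + sigma_b + sigma_c

  phi <- c(
    PhiST = if (tot > 0) (sigma_a + sigma_b) / tot else NA_real_,
    PhiSC = if ((sigma_b + sigma_c) > 0) sigma_b / (sigma_b + sigma_c) else NA_real_,
    PhiCT = if (tot > 0) sigma_a / tot else NA_real_)
  comp <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(df_ag, df_ap, df_wp, n - 1L),
    SS = c(ss_ag, ss_ap, ss_wp, ss_total),
    variance = c(sigma_a, sigma_b, sigma_c, tot),
    percent = if (tot > 0) 100 * c(sigma_a, sigma_b, sigma_c, tot) / tot else NA_real_,
    stringsAsFactors = FALSE)
  list(components = comp, phi = phi,
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c))
}

#' @export
print.amova_fit <- function(x, ...) {
  cat("AMOVA\n")
  comp <- x$components
  comp$SS <- round(comp$SS, 3); comp$variance <- round(comp$variance, 5)
  comp$percent <- round(comp$percent, 2)
  print(comp, row.names = FALSE)
  cat("\nPhi-statistics (negative values clamped to 0 for display):\n")
  for (nm in names(x$phi)) {
    cat(sprintf("  %s = %.5f", nm, max(x$phi[nm], 0)))
    if (!is.na(x$p_value[nm]))
      cat(sprintf("  (p = %.4g, %d permutations)", x$p_value[nm], x$nperm))
    cat("\n")
  }
  invisible(x)
}

#' Pairwise PhiST between all population pairs
#'
#' Runs a two-population AMOVA for every pair of sites and assembles the
#' PhiST matrix with raw permutation p-values and Holm-adjusted
#' significance calls.
#'
#' @inheritParams amova
#' @param clamp_negative Replace negative PhiST by 0 in the reported
#'   matrix (the raw values are kept in \code{phi_raw}).
#' @param alpha Significance level applied to Holm-adjusted p-values.
#' @return Object of class \code{pairwise_phist}: list with \code{phi}
#'   (matrix, clamped), \code{phi_raw}, \code{p_raw}, \code{p_holm},
#'   \code{significant} (logical matrix), \code{nperm}.
#' @export
pairwise_phist <- function(aln, nperm = 10000L, seed = NULL,
                           clamp_negative = TRUE, alpha = 0.05) {
  pop <- as.character(site_of(aln))
  sites <- unique(pop)
  k <- length(sites)
  if (k < 2L) stop("need at least 2 populations")
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  names(seqs) <- rownames(aln)
  d <- diff_count_matrix(seqs)
  if (!is.null(seed)) set.seed(seed)

  phi <- p <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  diag(phi) <- 0
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    idx <- which(pop %in% sites[c(i, j)])
    res <- amova(aln = NULL, nperm = nperm, seed = NULL,
                 d = d[idx, idx, drop = FALSE], pop = pop[idx])
    phi[i, j] <- phi[j, i] <- unname(res$phi["PhiST"])
    p[i, j] <- p[j, i] <- unname(res$p_value["PhiST"])
  }
  raw <- phi
  if (clamp_negative) phi[phi < 0] <- 0
  p_upper <- p[upper.tri(p)]
  holm <- holm_adjust(p_upper)
  p_holm <- p
  p_holm[upper.tri(p_holm)] <- holm
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  structure(list(phi = phi, phi_raw = raw, p_raw = p, p_holm = p_holm,
                 significant = p_holm <= alpha, nperm = nperm),
            class = "pairwise_phist")
}

#' @export
print.pairwise_phist <- function(x, digits = 3, ...) {
  cat("Pairwise PhiST (lower triangle; * Holm-significant)\n")
  k <- nrow(x$phi)
  m <- format(round(x$phi, digits))
  m[upper.tri(m, diag = FALSE)] <- ""
  star <- ifelse(!is.na(x$significant) & x$significant, "*", " ")
  for (i in seq_len(k))
    cat(sprintf("%-6s %s\n", rownames(x$phi)[i],
                paste(paste0(m[i, 1:i], star[i, 1:i]), collapse = " ")))
  invisible(x)
}

#' Holm's sequential Bonferroni adjustment
#'
#' Thin, explicitly named wrapper around
#' \code{stats::p.adjust(method = "holm")}: p-values are sorted
#' ascending, the i-th smallest multiplied by (m - i + 1), the sequence
#' made monotone non-decreasing, capped at 1, and returned in input
#' order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "holm")
}
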