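# Independent brute-force oracles. These re-derive quantities from first
# principles (definitional loops, exhaustive enumeration) and never call the
# package's own implementation paths.

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")

mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# definitional pairwise difference count
naive_diff <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- ca != "N" & cb != "N" & ca != "-" & cb != "-"
  sum(ca[ok] != cb[ok])
}

# one-level AMOVA from the definitional sums of squares (Excoffier-style),
# written as plain double loops
naive_amova1 <- function(seqs, pop) {
  n <- length(seqs)
  d <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) naive_diff(seqs[i], seqs[j])))
  ss <- function(idx) {
    tot <- 0
    if (length(idx) >= 2)
      for (i in seq_along(idx)) for (j in seq_along(idx))
        if (i < j) tot <- tot + d[idx[i], idx[j]]
    tot
  }
  pops <- unique(pop)
  P <- length(pops)
  np <- sapply(pops, function(p) sum(pop == p))
  ss_tot <- ss(1:n) / n
  ss_wp <- sum(sapply(pops, function(p) ss(which(pop == p)) / sum(pop == p)))
  ss_ap <- ss_tot - ss_wp
  ms_wp <- ss_wp / (n - P); ms_ap <- ss_ap / (P - 1)
  nbar <- (n - sum(np^2) / n) / (P - 1)
  sw <- ms_wp
  sa <- (ms_ap - sw) / nbar
  list(sigma_a = sa, sigma_w = sw, ss_ap = ss_ap, ss_wp = ss_wp,
       ss_tot = ss_tot, phi_st = sa / (sa + sw))
}

# PhiST directly from a precomputed distance matrix (definitional, compact)
phist_from_d <- function(d, pop) {
  n <- nrow(d)
  pops <- unique(pop)
  P <- length(pops)
  np <- sapply(pops, function(p) sum(pop == p))
  ss <- function(idx) sum(d[idx, idx][upper.tri(d[idx, idx])])
  ss_tot <- ss(1:n) / n
  ss_wp <- sum(sapply(pops, function(p) ss(which(pop == p)) / sum(pop == p)))
  ms_wp <- ss_wp / (n - P); ms_ap <- (ss_tot - ss_wp) / (P - 1)
  nbar <- (n - sum(np^2) / n) / (P - 1)
  sa <- (ms_ap - ms_wp) / nbar
  sa / (sa + ms_wp)
}

# exhaustive PhiST permutation distribution over all distinct assignments of
# individuals to populations of the observed sizes
exhaustive_phist_p <- function(seqs, pop) {
  n <- length(seqs)
  d <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) naive_diff(seqs[i], seqs[j])))
  obs <- phist_from_d(d, pop)
  # enumerate multiset permutations of the label vector
  enum <- function(remaining, labels) {
    if (sum(remaining) == 0) return(list(labels))
    out <- list()
    for (p in names(remaining)[remaining > 0]) {
      r2 <- remaining; r2[p] <- r2[p] - 1
      out <- c(out, enum(r2, c(labels, p)))
    }
    out
  }
  sizes <- table(pop)
  rem <- as.vector(sizes); names(rem) <- names(sizes)
  all_lab <- enum(rem, character(0))
  vals <- vapply(all_lab, function(lab) phist_from_d(d, lab), numeric(1))
  mean(vals >= obs - 1e-12)
}

# exhaustive minimum spanning tree weight over all spanning trees (k <= 7)
brute_mst_weight <- function(d) {
  k <- nrow(d)
  if (k == 1) return(0)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  best <- Inf
  for (sel in utils::combn(ne, k - 1, simplify = FALSE)) {
    parent <- 1:k
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      ri <- find(pairs[e, 1]); rj <- find(pairs[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
  }
  best
}

# unsigned Stirling numbers of the first kind, exact integer recursion
brute_stirling_row <- function(n) {
  row <- 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    new <- numeric(m + 1)
    new[1] <- m * row[1]
    if (m > 1) new[2:m] <- row[1:(m - 1)] + m * row[2:m]
    new[m + 1] <- row[m]
    row <- new
  }
  row
}

brute_ewens_probs <- function(n, theta) {
  s <- brute_stirling_row(n)
  p <- s * theta^(1:n) / prod(theta + 0:(n - 1))
  p
}

make_aln <- function(seqs, site = NULL) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  as_alignment(seqs, site_code = site)
}
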