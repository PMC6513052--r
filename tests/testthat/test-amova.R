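test_that("molecular distance counts differing sites with pairwise deletion", {
  expect_equal(molecular_distance("ACGT", "ACGT"), 0L)
  expect_equal(molecular_distance("AAT", "AAA"), 1L)
  expect_equal(molecular_distance("ACGT", "TGCA"), 4L)
  expect_equal(molecular_distance("ANGT", "ACGA"), 1L)
  expect_error(molecular_distance("ACG", "ACGT"), "length")
})

test_that("PhiST hits its analytic limits", {
  # two populations fixed for haplotypes 3 steps apart: PhiST = 1
  fixed <- make_aln(c(a1 = "AAAAA", a2 = "AAAAA", b1 = "TTTAA", b2 = "TTTAA"),
                    site = c("A", "A", "B", "B"))
  expect_equal(unname(amova(fixed, nperm = 0)$phi["PhiST"]), 1)

  # identical haplotype compositions: PhiST <= 0, reported as such raw
  same <- make_aln(c(a1 = "AAAA", a2 = "TTAA", b1 = "AAAA", b2 = "TTAA"),
                   site = c("A", "A", "B", "B"))
  expect_lte(unname(amova(same, nperm = 0)$phi["PhiST"]), 0)
})

test_that("variance components match the definitional brute-force oracle", {
  # spec-style toy: 3 populations, 2 haplotypes 1 step apart,
  # counts (4,0), (2,2), (0,4)
  seqs <- c(rep("AA", 4), rep("AA", 2), rep("AT", 2), rep("AT", 4))
  names(seqs) <- paste0("s", 1:12)
  pop <- rep(c("P1", "P2", "P3"), each = 4)
  aln <- make_aln(seqs, site = pop)
  mine <- amova(aln, nperm = 0)
  oracle <- naive_amova1(seqs, pop)
  expect_equal(mine$components$variance[1], oracle$sigma_a, tolerance = 1e-12)
  expect_equal(mine$components$variance[2], oracle$sigma_w, tolerance = 1e-12)
  expect_equal(unname(mine$phi["PhiST"]), oracle$phi_st, tolerance = 1e-12)
  # bookkeeping identity: level sums of squares add to the total
  expect_equal(sum(mine$components$SS[1:2]), mine$components$SS[3],
               tolerance = 1e-12)
})

test_that("components agree with the oracle on random unbalanced data", {
  set.seed(13)
  for (rep in 1:3) {
    sizes <- sample(3:6, 3)
    pop <- rep(paste0("P", 1:3), sizes)
    seqs <- vapply(seq_along(pop), function(i)
      mutate_seq(rand_seq(30), sample(0:3, 1)), character(1))
    names(seqs) <- paste0("s", seq_along(pop))
    mine <- amova(make_aln(seqs, site = pop), nperm = 0)
    oracle <- naive_amova1(seqs, pop)
    expect_equal(unname(mine$phi["PhiST"]), oracle$phi_st, tolerance = 1e-10)
    expect_equal(mine$components$SS[1], oracle$ss_ap, tolerance = 1e-10)
  }
})

test_that("permutation p matches exhaustive enumeration on a small sample", {
  seqs <- c(rep("AAAA", 3), "AATA", rep("TTTT", 2), "TTTA", "ATTT")
  names(seqs) <- paste0("s", 1:8)
  pop <- rep(c("P1", "P2"), each = 4)
  p_exact <- exhaustive_phist_p(seqs, pop)    # all 8!/(4!4!) label vectors
  res <- amova(make_aln(seqs, site = pop), nperm = 20000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p_value["PhiST"] - p_exact), 3 * se + 1e-4)
})

test_that("hierarchical AMOVA agrees with an independent implementation", {
  skip_if_not_installed("ade4")
  set.seed(17)
  n <- c(5, 6, 4, 7)
  pop <- rep(paste0("P", 1:4), n)
  anc <- c(rand_seq(30), rand_seq(30))
  seqs <- c(vapply(1:11, function(i) mutate_seq(anc[1], sample(1:3, 1)), character(1)),
            vapply(1:11, function(i) mutate_seq(anc[2], sample(1:3, 1)), character(1)))
  names(seqs) <- paste0("s", 1:22)
  aln <- make_aln(seqs, site = pop)
  mine <- amova(aln, grouping = list(G1 = c("P1", "P2"), G2 = c("P3", "P4")),
                nperm = 0)
  ht <- collapse_haplotypes(aln)
  d <- stats::as.dist(sqrt(outer(seq_along(ht$haplotype), seq_along(ht$haplotype),
                                 Vectorize(function(i, j)
                                   naive_diff(ht$haplotype[i], ht$haplotype[j])))))
  samples <- as.data.frame(ht$counts)
  structures <- data.frame(grp = factor(c("G1", "G1", "G2", "G2")))
  rownames(structures) <- colnames(samples)
  ref <- ade4::amova(samples = samples, distances = d, structures = structures)
  expect_equal(unname(mine$phi),
               unname(ref$statphi[, 1]), tolerance = 1e-8)
  expect_equal(mine$components$variance[1:3],
               ref$componentsofcovariance[1:3, 1], tolerance = 1e-8)
  # PhiCT of a real two-group split should be detected by permutation
  res <- amova(aln, grouping = list(G1 = c("P1", "P2"), G2 = c("P3", "P4")),
               nperm = 200, seed = 3)
  expect_true(all(c("PhiST", "PhiSC", "PhiCT") %in% names(res$p_value)))
})

test_that("pairwise PhiST equals a two-population AMOVA per pair", {
  set.seed(19)
  pop <- rep(c("A", "B", "C"), each = 4)
  seqs <- vapply(seq_along(pop), function(i)
    mutate_seq(rand_seq(25), sample(0:2, 1)), character(1))
  names(seqs) <- paste0("s", seq_along(pop))
  aln <- make_aln(seqs, site = pop)
  pw <- pairwise_phist(aln, nperm = 0)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    sub <- aln_subset(aln, rows = which(pop %in% pair))
    expect_equal(pw$phi_raw[pair[1], pair[2]],
                 unname(amova(sub, nperm = 0)$phi["PhiST"]), tolerance = 1e-12)
  }
  # reported matrix is clamped at zero per convention
  expect_true(all(pw$phi >= 0, na.rm = TRUE))
})

test_that("random split of one site gives PhiST near zero", {
  set.seed(23)
  seqs <- vapply(1:16, function(i) mutate_seq(rand_seq(40), sample(0:2, 1)),
                 character(1))
  names(seqs) <- paste0("s", 1:16)
  pop <- sample(rep(c("X1", "X2"), each = 8))
  res <- amova(make_aln(seqs, site = pop), nperm = 200, seed = 1)
  expect_lt(abs(res$phi["PhiST"]), 0.15)
  expect_gt(res$p_value["PhiST"], 0.05)
})

test_that("Holm adjustment follows the sequential procedure and its bounds", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  set.seed(29)
  p <- runif(12)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(1, length(p) * p)))
  # order preserved relative to input positions
  expect_equal(order(h), order(holm_adjust(p)))
})

test_that("Mantel r, Z and exact p match a full 5! enumeration", {
  set.seed(37)
  sym <- function(n) { m <- matrix(runif(n * n), n, n); m <- m + t(m); diag(m) <- 0; m }
  g <- sym(5); d <- sym(5)
  res <- mantel_test(g, d, exact = TRUE)
  expect_equal(res$nperm, 120)
  ut <- upper.tri(g)
  expect_equal(res$Z, sum(g[ut] * d[ut]))
  expect_equal(res$r, cor(g[ut], d[ut]))
  # manual enumeration over all 120 relabelings
  perms <- coipop:::all_permutations(5)
  rs <- vapply(perms, function(p) { dp <- d[p, p]; cor(g[ut], dp[ut]) }, numeric(1))
  expect_equal(res$p_value, mean(rs >= res$r - 1e-12))
  # independent cross-check of r against vegan
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(as.dist(g), as.dist(d), permutations = 99)
  expect_equal(res$r, unname(vg$statistic), tolerance = 1e-10)
})

test_that("Mantel handles perfect linearity and constant matrices", {
  g <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  expect_equal(mantel_test(g, 2 * g, exact = TRUE)$r, 1)
  const <- matrix(1, 3, 3); diag(const) <- 0
  res <- mantel_test(g, const, exact = TRUE)
  expect_true(is.na(res$r))
  expect_match(res$note, "constant")
})

test_that("permutation p-values are stable across seeds", {
  set.seed(43)
  seqs <- vapply(1:18, function(i) mutate_seq(rand_seq(40), sample(0:3, 1)),
                 character(1))
  names(seqs) <- paste0("s", 1:18)
  pop <- rep(c("A", "B", "C"), each = 6)
  aln <- make_aln(seqs, site = pop)
  p1 <- amova(aln, nperm = 4000, seed = 1)$p_value["PhiST"]
  p2 <- amova(aln, nperm = 4000, seed = 999)$p_value["PhiST"]
  se <- sqrt(p1 * (1 - p1) / 4000)
  expect_lt(abs(p1 - p2), 3 * se + 1e-3)
})
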