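test_that("p-distance and raw counts follow their definitions", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("A", 99), "T"), collapse = "")
  aln <- make_aln(c(x = a, y = b, z = a))
  dp <- pairwise_distances(aln, "p")
  expect_equal(dp["x", "y"], 0.01)
  expect_equal(dp["x", "z"], 0)
  dr <- pairwise_distances(aln, "raw")
  expect_equal(dr["x", "y"], 1)
  # identical sequences are at distance 0 under every model
  for (m in c("p", "K2P", "raw"))
    expect_equal(pairwise_distances(aln, m)["x", "z"], 0)
})

test_that("K2P matches an independent evaluation of Kimura's formula", {
  # 2 transitions (A<->G) + 1 transversion (A<->C) over 100 sites
  a <- rep("A", 100)
  b <- a; b[1] <- "G"; b[2] <- "G"; b[3] <- "C"
  aln <- make_aln(c(x = paste(a, collapse = ""), y = paste(b, collapse = "")))
  P <- 2 / 100; Q <- 1 / 100
  expected <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  expect_equal(pairwise_distances(aln, "K2P")["x", "y"], expected,
               tolerance = 1e-10)
})

test_that("ambiguous sites are excluded pairwise", {
  aln <- make_aln(c(x = "ANAAAAAAAA", y = "ATAAAAAAAT"))
  # site 2 dropped for this pair: 1 diff over 9 sites
  expect_equal(pairwise_distances(aln, "p")["x", "y"], 1 / 9)
  expect_equal(molecular_distance("ANAAAAAAAA", "ATAAAAAAAT"), 1L)
})

test_that("3-taxon NJ branch lengths obey the three-point formulas", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  # leaf edge lengths: x_a = (d_ab + d_ac - d_bc)/2 = 1, x_b = 2, x_c = 4
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(1, 2, 4))
})

test_that("NJ recovers the generating topology of additive matrices (n <= 6)", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (ntax in 4:6) {
    for (rep in 1:3) {
      tr0 <- ape::rtree(ntax, rooted = FALSE,
                        br = function(n) runif(n, 0.3, 1.5))
      d <- cophenetic(tr0)
      tr <- neighbor_joining(d)
      expect_equal(ape::dist.topo(ape::unroot(tr0), tr), 0,
                   ignore_attr = TRUE)
      # exhaustive check: the recovered topology attains the best
      # least-squares fit over ALL unrooted topologies
      all_t <- phangorn::allTrees(ntax, rooted = FALSE,
                                  tip.label = rownames(d))
      ls_fit <- vapply(all_t, function(t) {
        t2 <- phangorn::nnls.tree(d, t)
        sum((cophenetic(t2)[rownames(d), colnames(d)] - d)^2)
      }, numeric(1))
      best <- all_t[[which.min(ls_fit)]]
      expect_equal(ape::dist.topo(best, tr), 0, ignore_attr = TRUE)
    }
  }
})

test_that("NJ rejects incomplete matrices and tiny inputs", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighbor_joining(d), "3 taxa")
  d3 <- matrix(0, 3, 3); d3[1, 2] <- d3[2, 1] <- NA
  expect_error(neighbor_joining(d3), "missing")
})

test_that("bootstrap support is high for well-separated clusters", {
  set.seed(31)
  # two 3-leaf clusters, 10 diagnostic sites between them plus noise
  core <- rand_seq(80)
  grpA <- substr(core, 1, 80)
  grpB <- mutate_seq(core, 10)
  seqs <- c(a1 = grpA, a2 = mutate_seq(grpA, 1), a3 = mutate_seq(grpA, 1),
            b1 = grpB, b2 = mutate_seq(grpB, 1), b3 = mutate_seq(grpB, 1))
  tr <- bootstrap_nj(make_aln(seqs), replicates = 200, seed = 7)
  sup <- as.numeric(tr$node.label)
  # the deepest split must be strongly supported
  expect_true(max(sup, na.rm = TRUE) >= 95)
  expect_false(isTRUE(attr(tr, "degenerate")))
})

test_that("single-replicate supports are 0 or 100; invariant data flagged", {
  set.seed(32)
  seqs <- c(a = rand_seq(50), b = rand_seq(50), c = rand_seq(50), d = rand_seq(50))
  tr <- bootstrap_nj(make_aln(seqs), replicates = 1, seed = 1)
  expect_true(all(as.numeric(tr$node.label) %in% c(0, 100)))
  inv <- make_aln(setNames(rep(paste(rep("A", 30), collapse = ""), 4),
                           c("a", "b", "c", "d")))
  tri <- bootstrap_nj(inv, replicates = 5, seed = 1)
  expect_true(attr(tri, "degenerate"))
})

test_that("species assignment: exact hit, threshold rule, order invariance", {
  refs <- make_aln(c(r1 = "AAAAAAAAAA", r2 = "TTTTTTTTTT", r3 = "GGGGGGGGGG"))
  attr(refs, "species") <- setNames(c("sp1", "sp2", "sp2"), rownames(refs))
  q <- make_aln(c(q1 = "AAAAAAAAAA", q2 = "AAAAATTTTT"))
  asg <- assign_species(q, refs)
  expect_equal(asg$species[1], "sp1")
  expect_equal(asg$distance[1], 0)
  expect_false(asg$ambiguous[1])
  # q2 is exactly equidistant between sp1 and sp2: margin 0 -> ambiguous
  expect_equal(asg$margin[2], 0)
  expect_true(asg$ambiguous[2])

  # invariance to reference order
  refs2 <- aln_subset(refs, rows = c(3, 1, 2))
  asg2 <- assign_species(q, refs2)
  expect_equal(asg2$species, asg$species)
  expect_equal(asg2$distance, asg$distance)
})

test_that("simulated 5-species panel is assigned perfectly at 10%/1%", {
  pan <- simulate_species_panel(k = 5, divergence = 0.10,
                                within_variation = 0.01, L = 563, seed = 99)
  asg <- assign_species(pan$queries, pan$references)
  expect_equal(asg$species, unname(pan$truth[asg$id]))
  expect_false(any(asg$ambiguous))
})

test_that("species separated by less than the margin threshold get flagged", {
  # ancestors ~2*divergence apart: below the 0.02 margin some calls must be
  # flagged ambiguous even though a nearest reference still exists
  pan <- simulate_species_panel(k = 4, divergence = 0.008,
                                within_variation = 0.0079, L = 300,
                                n_query = 10, seed = 5)
  asg <- assign_species(pan$queries, pan$references)
  expect_true(any(asg$ambiguous))
})

test_that("single-species panel assigns everything to that species", {
  pan <- simulate_species_panel(k = 1, divergence = 0.05,
                                within_variation = 0.01, L = 200, seed = 3)
  asg <- assign_species(pan$queries, pan$references)
  expect_true(all(asg$species == "sp1"))
})
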