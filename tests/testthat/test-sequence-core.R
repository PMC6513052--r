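test_that("FASTA parsing handles headers, case, RNA and malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1|Be|Octopus cyanea", "acgtacgtna",
               ">s2|Ka", "ACGUACGUAA"), f)
  rec <- read_coi_fasta(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(nchar(rec$seq), c(10L, 10L))
  expect_equal(rec$seq[1], "ACGTACGTNA")     # uppercased
  expect_equal(rec$seq[2], "ACGTACGTAA")     # U -> T
  expect_equal(rec$site_code, c("Be", "Ka"))
  expect_equal(rec$species_label, c("Octopus cyanea", NA))

  writeLines(c(">s1", "ACGT", ">s1", "ACGA"), f)
  expect_error(read_coi_fasta(f), "s1")
  writeLines(c(">bad", "ACGX"), f)
  expect_error(read_coi_fasta(f), "bad")
  writeLines(character(0), f)
  expect_error(read_coi_fasta(f), "empty")
})

test_that("metadata overrides header tokens", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1|Xx", "ACGTACGT", ">s2", "ACGTACGA"), f)
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsite_code\tspecies_label",
               "s1\tBe\tO. cyanea", "s2\tKa\tO. cyanea"), m)
  rec <- read_coi_fasta(f, metadata = read_metadata(m))
  expect_equal(rec$site_code, c("Be", "Ka"))
  expect_equal(rec$species_label, rep("O. cyanea", 2))
})

test_that("FASTA round-trips through write and read", {
  set.seed(11)
  seqs <- replicate(5, rand_seq(60))
  rec <- data.frame(id = paste0("s", 1:5), seq = seqs,
                    site_code = rep(c("A", "B"), c(2, 3)),
                    species_label = NA_character_)
  class(rec) <- c("coi_records", "data.frame")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_coi_fasta(rec, f)
  back <- read_coi_fasta(f)
  expect_equal(back$seq, rec$seq)
  expect_equal(back$site_code, rec$site_code)
})

test_that("trimming truncates to the minimum length and is idempotent", {
  set.seed(3)
  base <- rand_seq(600)
  seqs <- c(a = substr(base, 1, 563), b = substr(base, 1, 570), c = base)
  aln <- trim_to_common(seqs)
  expect_equal(ncol(aln), 563L)
  # idempotent: trimming the trimmed alignment changes nothing
  again <- trim_to_common(as_records(aln))
  expect_identical(unclass(again)[, ], unclass(aln)[, ])
  # equal lengths pass through unchanged
  eq <- trim_to_common(c(x = "ACGTACGTACGT", y = "ACGTACGTACGA"),
                       min_length = 5)
  expect_equal(ncol(eq), 12L)
  expect_error(trim_to_common(c(x = "ACGT", y = "")), "empty")
  expect_warning(trim_to_common(c(x = "ACGTAC", y = "ACGTACGT"),
                                min_length = 100), "only")
})

test_that("anchoring recovers a leading-offset shift before trimming", {
  set.seed(4)
  ref <- rand_seq(300)
  shifted <- paste0(rand_seq(7), ref)   # 7 junk bases before the amplicon
  aln <- trim_to_common(c(a = ref, b = shifted), anchor_to = ref)
  expect_equal(ncol(aln), 300L)
  expect_equal(molecular_distance(paste(unclass(aln)[1, ], collapse = ""),
                                  paste(unclass(aln)[2, ], collapse = "")), 0L)
})

test_that("gap columns are removed before statistics", {
  aln <- make_aln(c(a = "AC-GT", b = "ACTGT", c = "ACTGA"))
  expect_equal(ncol(aln), 5L)
  clean <- drop_gap_columns(aln)
  expect_equal(ncol(clean), 4L)
})

test_that("translation QC flags internal stops and picks the best frame", {
  # Met-Phe-Ile under the invertebrate mitochondrial code: clean in frame 0
  aln <- make_aln(c(ok = "ATGTTTATT"))
  qc <- translate_qc(aln)
  expect_equal(qc$frame, 0L)
  expect_equal(qc$stop_codons, 0L)
  expect_true(qc$pass)

  # internal stop (TAG) in every frame: must fail whatever frame is chosen
  bad <- make_aln(c(x = "ATAGCTAGGTAGGAG"))
  expect_false(translate_qc(bad)$pass)

  # frame 0 hits a TAA stop, frame 1 reads cleanly:
  # "T" + "AATGGTTTGGG" -> frame 0: TAA TGG TTT GGG; frame 1: AAT GGT TTG
  tricky <- make_aln(c(y = "TAATGGTTTGGG"))
  qt <- translate_qc(tricky)
  expect_equal(qt$frame, 1L)
  expect_true(qt$pass)
})

test_that("haplotype collapsing counts, names and round-trips correctly", {
  aln <- make_aln(c(a = "AAA", b = "AAA", c = "AAT", d = "AAA", e = "AAT",
                    f = "ATT"),
                  site = c("X", "X", "X", "Y", "Y", "Y"))
  ht <- collapse_haplotypes(aln)
  expect_equal(n_haplotypes(ht), 3L)
  # H1 = most frequent (AAA, n=3); tie between AAT(2)... ordering by count
  expect_equal(unname(ht$haplotype["H1"]), "AAA")
  expect_equal(unname(rowSums(ht$counts)[c("H1", "H2", "H3")]), c(3, 2, 1))
  expect_equal(colSums(ht$counts), c(X = 3L, Y = 3L))
  # expanding by assignment recovers the exact multiset of inputs
  back <- expand_haplotypes(ht)
  expect_equal(back[rownames(aln)],
               setNames(apply(unclass(aln), 1, paste, collapse = ""),
                        rownames(aln)))
  # identical sequences across two sites collapse to one haplotype
  one <- collapse_haplotypes(make_aln(rep("ACGT", 4), site = c("A", "A", "B", "B")))
  expect_equal(n_haplotypes(one), 1L)
  expect_equal(unname(one$counts[1, ]), c(2L, 2L))
})

test_that("haplotype count is invariant under record reordering", {
  set.seed(9)
  seqs <- replicate(12, mutate_seq(rand_seq(40), sample(0:2, 1)))
  names(seqs) <- paste0("s", 1:12)
  aln1 <- make_aln(seqs)
  aln2 <- make_aln(seqs[sample(12)])
  expect_equal(n_haplotypes(collapse_haplotypes(aln1)),
               n_haplotypes(collapse_haplotypes(aln2)))
})

test_that("ambiguity policy: N-distinct by default, wildcard on request", {
  aln <- make_aln(c(a = "ACGT", b = "ACGN"))
  expect_equal(n_haplotypes(collapse_haplotypes(aln)), 2L)
  expect_equal(n_haplotypes(collapse_haplotypes(aln, n_as_wildcard = TRUE)), 1L)
})
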