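test_that("FASTA reading validates records and normalizes case", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "acga"), tmp)
  a <- read_fasta(tmp, locus = "toy")
  expect_equal(n_columns(a), 4)
  expect_equal(strain_ids(a), c("s1", "s2"))
  expect_equal(paste(a$mat["s2", ], collapse = ""), "ACGA")

  writeLines(c(">s1", "ACGT", ">s2", "ACGTA"), tmp)
  expect_error(read_fasta(tmp), class = "alignment_error")
  writeLines(c(">s1", "ACGT", ">s1", "ACGA"), tmp)
  expect_error(read_fasta(tmp), class = "duplicate_id_error")

  # wrapped records and U -> T normalization round-trip
  a2 <- locus_alignment(c(x = "ACGU", y = "ACGT"))
  expect_equal(paste(a2$mat["x", ], collapse = ""), "ACGT")
  expect_error(locus_alignment(c(x = "ACXT", y = "ACGT")),
               class = "alphabet_error")
  tmp2 <- withr::local_tempfile(fileext = ".fasta")
  big <- locus_alignment(
    c(s1 = paste(rep("ACGT", 50), collapse = ""),
      s2 = paste(rep("ACGA", 50), collapse = "")), locus = "wide")
  write_fasta(big, tmp2, width = 60)
  back <- read_fasta(tmp2, locus = "wide")
  expect_identical(back$mat, big$mat)
})

test_that("harmonize restricts loci to the shared strain set", {
  l1 <- aln_from(a = "ACGT", b = "ACGA", c = "ACGC", locus = "l1")
  l2 <- aln_from(b = "TTT", c = "TTA", d = "TTC", locus = "l2")
  h <- harmonize(list(l1, l2))
  expect_equal(strain_ids(h[[1]]), c("b", "c"))
  expect_equal(strain_ids(h[[2]]), c("b", "c"))
  expect_equal(n_columns(h[[1]]), 4)  # columns untouched

  same <- harmonize(list(l1))
  expect_identical(same[[1]]$mat, l1$mat)

  l3 <- aln_from(x = "GG", y = "GC", locus = "l3")
  expect_error(harmonize(list(l1, l3)), class = "empty_overlap_error")
})

test_that("concatenation records contiguous boundaries and total width", {
  l1 <- aln_from(a = "ACG", b = "ACG", locus = "l1")
  l2 <- aln_from(a = "TTTTT", b = "TTTTA", locus = "l2")
  cc <- concatenate(list(l1, l2))
  expect_equal(cc$n_columns, 8)
  expect_equal(paste(cc$mat["a", ], collapse = ""), "ACGTTTTT")
  expect_equal(cc$boundaries$start, c(1, 4))
  expect_equal(cc$boundaries$end, c(3, 8))
  # boundaries tile [1, n_columns] with no gaps
  expect_equal(cc$boundaries$start[-1], head(cc$boundaries$end, -1) + 1)
  expect_identical(extract_locus(cc, "l2")$mat, l2$mat)

  single <- concatenate(list(l1))
  expect_identical(single$mat, l1$mat)
  l_bad <- aln_from(a = "AA", x = "AC", locus = "bad")
  expect_error(concatenate(list(l1, l_bad)), class = "harmonization_error")
})

test_that("site classification matches the hand-enumerated pattern example", {
  # columns {AAAA}, {AAAC}, {AACC}: 1 conserved, 1 singleton, 1 PI
  a <- aln_from(s1 = "AAA", s2 = "AAA", s3 = "AAC", s4 = "ACC")
  sc <- classify_sites(a)
  expect_equal(sc$n_conserved, 1)
  expect_equal(sc$n_variable, 2)
  expect_equal(sc$n_singleton, 1)
  expect_equal(sc$n_parsimony_informative, 1)

  mono <- aln_from(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT")
  sc2 <- classify_sites(mono)
  expect_equal(sc2$n_conserved, sc2$n_sites)
  expect_equal(sc2$n_variable, 0)

  # a column of one base plus gaps counts conserved (gap exclusion)
  g <- aln_from(s1 = "A", s2 = "-", s3 = "-", s4 = "-")
  expect_equal(classify_sites(g)$n_conserved, 1)
  expect_error(classify_sites(aln_from(s1 = "ACGT")),
               class = "insufficient_data_error")
})

test_that("site classification agrees with per-column brute force on random alignments", {
  for (seed in 1:5) {
    set.seed(seed)
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 6 * 20, TRUE,
                         prob = c(.3, .25, .2, .15, .05, .05)), 6, 20,
                  dimnames = list(paste0("s", 1:6), NULL))
    a <- locus_alignment(mat)
    sc <- classify_sites(a)
    oracle <- brute_classify(mat)
    expect_equal(sc$n_conserved, unname(oracle["conserved"]))
    expect_equal(sc$n_variable, unname(oracle["variable"]))
    expect_equal(sc$n_parsimony_informative, unname(oracle["pi"]))
    expect_equal(sc$n_singleton, unname(oracle["singleton"]))
    expect_equal(sc$n_parsimony_informative + sc$n_singleton, sc$n_variable)
  }
})

test_that("p-distance follows the pairwise-deletion contract", {
  expect_equal(p_distance(aln_from(x = "ACGT", y = "ACGA"))["x", "y"], 0.25)
  expect_equal(p_distance(aln_from(x = "ACGT", y = "ACGT"))["x", "y"], 0)
  # 3 comparable columns (gap excluded), 1 difference
  expect_equal(p_distance(aln_from(x = "AC-T", y = "ACGA"))["x", "y"], 1 / 3)
  expect_error(p_distance(aln_from(x = "--AA", y = "GG--")),
               class = "undefined_distance_error")
  # complete deletion drops any column with a gap anywhere: 3 columns
  # remain for x/y, of which 1 differs
  a <- aln_from(x = "AC-T", y = "ACGA", z = "ACGT")
  expect_equal(p_distance(a, deletion = "complete")["x", "y"], 1 / 3)
  expect_equal(p_distance(a, deletion = "complete")["y", "z"], 1 / 3)
})

test_that("p-distance is a bounded semimetric", {
  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length * 0.1
  a <- simulate_alignment(tr, "JC69", 300, seed = 11)
  d <- p_distance(a)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("corrected distances match closed forms and the ape oracle", {
  # all-transversion pair: p = Q, JC69 closed form
  x <- paste(c(rep("A", 1000 - 76), rep("C", 76)), collapse = "")
  y <- paste(rep("A", 1000), collapse = "")
  a <- aln_from(x = x, y = y)
  p <- 0.076
  expect_equal(corrected_distance(a, "JC69")["x", "y"],
               -3 / 4 * log(1 - 4 / 3 * p))
  expect_equal(corrected_distance(a, "K2P")["x", "y"],
               -1 / 2 * log(1 - 2 * 0 - p) - 1 / 4 * log(1 - 2 * p))

  tr <- ape::rtree(8)
  tr$edge.length <- tr$edge.length * 0.05
  al <- simulate_alignment(tr, "JC69", 500, seed = 4)
  for (mod in c("JC69", "K2P", "T92")) {
    mine <- corrected_distance(al, mod)
    oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(al$mat)),
                                      model = sub("K2P", "K80", mod),
                                      pairwise.deletion = TRUE))
    expect_equal(mine, oracle[rownames(mine), colnames(mine)],
                 tolerance = 1e-4, ignore_attr = TRUE)
    # correction can only stretch distances
    expect_true(all(mine - p_distance(al) >= -1e-12))
  }
  ident <- aln_from(x = "ACGTACGT", y = "ACGTACGT")
  for (mod in c("JC69", "K2P", "T92"))
    expect_equal(corrected_distance(ident, mod)["x", "y"], 0)
  sat <- aln_from(x = paste(rep("A", 10), collapse = ""),
                  y = paste(rep("C", 10), collapse = ""))
  expect_error(corrected_distance(sat, "JC69"), class = "saturation_error")
})

test_that("K2P reduces to JC69 at the JC transition:transversion ratio", {
  # 1 transition : 2 transversions is the JC expectation
  x <- paste(c(rep("A", 940), rep("G", 20), rep("C", 20), rep("T", 20)),
             collapse = "")
  y <- paste(rep("A", 1000), collapse = "")
  a <- aln_from(x = x, y = y)
  expect_equal(corrected_distance(a, "K2P")["x", "y"],
               corrected_distance(a, "JC69")["x", "y"], tolerance = 1e-10)
})

test_that("MLSA ANI summarizes pairwise percent identity", {
  ident <- aln_from(x = "ACGTACGT", y = "ACGTACGT", z = "ACGTACGT")
  expect_equal(ani(ident, c("x", "y", "z"))$mean, 100)
  # 24 differences over 1000 comparable sites -> 97.6%
  x <- paste(c(rep("A", 976), rep("C", 24)), collapse = "")
  y <- paste(rep("A", 1000), collapse = "")
  two <- aln_from(x = x, y = y)
  res <- ani(two, c("x", "y"))
  expect_equal(res$mean, 97.6)
  expect_true(res$same_species)  # above the 95% species cutoff
  expect_error(ani(two, "x"), class = "insufficient_pairs_error")
  cross <- ani(two, "x", "y")
  expect_equal(cross$n_pairs, 1)
})

test_that("site classification is additive over concatenated loci", {
  set.seed(21)
  mk <- function(n) locus_alignment(
    matrix(sample(c("A", "C", "G", "T"), 5 * n, TRUE), 5, n,
           dimnames = list(paste0("s", 1:5), NULL)))
  l1 <- mk(30); l2 <- mk(40)
  cc <- concatenate(list(l1, l2))
  s1 <- classify_sites(l1); s2 <- classify_sites(l2)
  sc <- classify_sites(cc)
  for (f in c("n_sites", "n_conserved", "n_variable",
              "n_parsimony_informative", "n_singleton"))
    expect_equal(sc[[f]], s1[[f]] + s2[[f]])
})
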