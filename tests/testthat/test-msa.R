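# Alignment construction, trimming, row filtering, back-translation,
# orthogroup integration.

test_that("trimming keeps exactly the columns meeting the gap threshold", {
  aln <- OrthoAlignment(c(r1 = "A-A-", r2 = "AA--", r3 = "A---"))
  ## col non-gap fractions: 1, 1/3, 1/3, 0
  out <- trimAlignment(aln, gt = 0.4)
  expect_equal(ncol(out@mat), 1L)
  expect_identical(unname(alignmentStrings(out)), c("A", "A", "A"))
  ## all-gap column dropped even at gt = 0
  out0 <- trimAlignment(aln, gt = 0)
  expect_equal(ncol(out0@mat), 3L)
  ## gap-free alignment unchanged at any gt
  clean <- OrthoAlignment(c(a = "ACGT", b = "ACGA"))
  expect_identical(trimAlignment(clean, 1)@mat, clean@mat)
})

test_that("trimming is idempotent and every kept column verifies gt", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:8, 1); w <- sample(10:60, 1)
    gt <- runif(1)
    m <- matrix(sample(c("A", "C", "-", "-"), n * w, replace = TRUE), n, w)
    rownames(m) <- sprintf("r%d", seq_len(n))
    aln <- new("OrthoAlignment", mat = m, taxa = character(0))
    t1 <- trimAlignment(aln, gt)
    if (ncol(t1@mat) == 0) next
    expect_true(all(colMeans(t1@mat != "-") >= gt))
    expect_true(all(colMeans(t1@mat != "-") > 0))
    t2 <- trimAlignment(t1, gt)
    expect_identical(t2@mat, t1@mat)
    ## kept columns are a subsequence of input columns
    expect_true(ncol(t1@mat) <= ncol(aln@mat))
  }
})

test_that("backtranslate maps residues to codons and gaps to triple gaps", {
  aln <- OrthoAlignment(c(r1 = "M-K", r2 = "MLK"))
  cds <- c(r1 = "ATGAAA", r2 = "ATGCTGAAG")
  out <- backtranslate(aln, cds)
  expect_identical(unname(alignmentStrings(out)[["r1"]]), "ATG---AAA")
  expect_identical(unname(alignmentStrings(out)[["r2"]]), "ATGCTGAAG")
  expect_equal(ncol(out@mat), 3L * ncol(aln@mat))
  ## trailing stop dropped silently
  out2 <- backtranslate(aln, c(r1 = "ATGAAATAA", r2 = "ATGCTGAAG"))
  expect_identical(unname(alignmentStrings(out2)[["r1"]]), "ATG---AAA")
  ## translation mismatch is fatal and names the row
  expect_error(backtranslate(aln, c(r1 = "ATGCCC", r2 = "ATGCTGAAG")), "r1")
})

test_that("ungapping a back-translated row recovers the CDS exactly", {
  set.seed(9)
  for (i in 1:20) {
    n_cod <- sample(5:30, 1)
    cds <- random_cds(n_cod)
    cds_nostop <- substr(cds, 1, nchar(cds) - 3)
    prot <- paste(vapply(seq_len(n_cod),
                         function(j) .oracle_gc[[substr(cds_nostop, 3 * j - 2, 3 * j)]],
                         character(1)), collapse = "")
    ## inject random gaps
    chars <- strsplit(prot, "")[[1]]
    gapped <- character(0)
    for (ch in chars) {
      if (runif(1) < 0.3) gapped <- c(gapped, "-")
      gapped <- c(gapped, ch)
    }
    aln <- OrthoAlignment(setNames(paste(gapped, collapse = ""), "r"))
    out <- backtranslate(aln, c(r = cds))
    expect_identical(gsub("-", "", alignmentStrings(out)[["r"]]), cds_nostop)
  }
})

test_that("integration places scaffold members before new sequences", {
  s <- Scaffold(data.frame(gene_id = c("g1", "g2", "g3"),
                           taxon = c("A", "B", "A"),
                           og_id = c("og1", "og1", "og2")),
                sequences = list(og1 = c(g1 = "AAA", g2 = "CCC"),
                                 og2 = c(g3 = "GGG")))
  ct <- new("ClassificationTable",
            assignments = data.frame(
              gene_id = c("q1", "q2"), og_id = c("og1", "og1"),
              classifier = "similarity", score = 100, conflict = FALSE,
              similarity_og = NA_character_),
            unclassified = character(0), scaffold = s@name, metadata = list())
  ints <- integrateOrthogroups(ct, c(q1 = "TTT", q2 = "TTA"), s)
  expect_identical(names(ints$og1), c("g1", "g2", "q1", "q2"))
  expect_identical(names(ints$og2), "g3")
  ## skip flag removes unchanged orthogroups
  ints2 <- integrateOrthogroups(ct, c(q1 = "TTT", q2 = "TTA"), s,
                                skip_unchanged = TRUE)
  expect_false("og2" %in% names(ints2))
  ## missing sequence is fatal and names the gene
  expect_error(integrateOrthogroups(ct, c(q1 = "TTT"), s), "q2")
  ## id clash between scaffold and query is fatal
  ct@assignments$gene_id[1] <- "g1"
  expect_error(integrateOrthogroups(ct, c(g1 = "TTT", q2 = "TTA"), s), "g1")
})

test_that("padded alignment backend satisfies alignment invariants", {
  seqs <- c(a = "ACGTACGT", b = "ACG", c = "ACGTA")
  aln <- alignSequences(seqs, backend = "padded")
  expect_equal(ncol(aln@mat), 8L)
  strs <- alignmentStrings(aln)
  for (nm in names(seqs)) {
    expect_identical(gsub("-", "", strs[[nm]]), unname(seqs[[nm]]))
  }
  expect_error(alignSequences(character(0)), "no sequences")
  expect_error(alignSequences(seqs, backend = list(cmd = "/nonexistent")),
               class = "okit_backend_error")
})
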