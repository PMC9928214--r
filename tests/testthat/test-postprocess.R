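# ORF finding, duplicate removal, meta-assembly, coverage filtering.

test_that("simple complete ORF is found with exact coordinates", {
  r <- findOrfs("ATGAAATAG", min_aa = 2, allow_partial = FALSE)
  expect_equal(nrow(r), 1L)
  expect_equal(r$protein, "MK")
  expect_equal(c(r$cds_start, r$cds_end), c(0L, 9L))
  expect_equal(r$frame, 1L)
  expect_equal(r$cds, "ATGAAATAG")
  expect_true(r$complete5 && r$complete3)
})

test_that("poly-A sequence yields no long ORFs", {
  expect_equal(nrow(findOrfs(strrep("A", 300), min_aa = 50)), 0L)
})

test_that("reverse-strand ORF reports negative frame and forward coords", {
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  s <- paste0(strrep("C", 10), rc("ATGAAATAG"), strrep("C", 11))
  r <- findOrfs(s, min_aa = 2, allow_partial = FALSE)
  expect_equal(nrow(r), 1L)
  expect_equal(r$protein, "MK")
  expect_true(r$frame < 0)
  expect_equal(c(r$cds_start, r$cds_end), c(10L, 19L))
  expect_equal(r$cds, "ATGAAATAG")
})

test_that("ORF finder agrees with the regex enumeration oracle", {
  set.seed(101)
  for (i in 1:200) {
    L <- sample(30:400, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    min_aa <- sample(2:20, 1)
    partial <- sample(c(TRUE, FALSE), 1)
    got <- findOrfs(s, min_aa = min_aa, allow_partial = partial)
    want <- oracle_orfs(s, min_aa = min_aa, allow_partial = partial)
    got <- got[order(got$frame, got$cds_start), , drop = FALSE]
    expect_equal(nrow(got), nrow(want), info = sprintf("seq %d", i))
    if (nrow(got)) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[, c("frame", "cds_start", "cds_end", "protein",
                           "complete5", "complete3")],
                   want, info = sprintf("seq %d", i))
    }
  }
})

test_that("non-nucleotide input is rejected", {
  expect_error(findOrfs("MKLV", min_aa = 1), "nucleotide")
})

test_that("bestOrf prefers length, then completeness, then position", {
  m <- data.frame(transcript_id = "t", frame = 1L,
                  cds_start = c(0L, 30L), cds_end = c(300L, 270L),
                  cds = "x", protein = c(strrep("A", 100), strrep("A", 80)),
                  complete5 = TRUE, complete3 = TRUE)
  expect_equal(nchar(bestOrf(m)$protein), 100L)
  m2 <- m
  m2$protein <- strrep("A", 90)
  m2$complete5 <- c(TRUE, FALSE)
  expect_true(bestOrf(m2)$complete5)
  m3 <- m
  m3$protein <- strrep("A", 90)
  expect_equal(bestOrf(m3)$cds_start, 0L)
  expect_error(bestOrf(m[0, ]), "no ORF")
})

test_that("dedup removes duplicates and exact subsequences", {
  d <- dedupSequences(c(s1 = "ATG", s2 = "ATGATG"))
  expect_identical(names(d$kept), "s2")
  expect_identical(names(d$removed), "s1")
  ## identical sequences: smallest id kept
  d2 <- dedupSequences(c(b = "ATGCC", a = "ATGCC"))
  expect_identical(names(d2$kept), "a")
  ## disjoint kept
  d3 <- dedupSequences(c(x = "AAAA", y = "CCCC"))
  expect_equal(length(d3$kept), 2L)
})

test_that("dedup kept set is substring-free and dedup is idempotent", {
  set.seed(7)
  for (rep_i in 1:20) {
    n <- sample(5:15, 1)
    base <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(8:40, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    ## inject substrings and duplicates
    extra <- c(substr(base[1], 2, nchar(base[1]) - 1), base[2])
    seqs <- setNames(c(base, extra), sprintf("s%02d", seq_len(n + 2)))
    d <- dedupSequences(seqs)
    expect_setequal(c(names(d$kept), names(d$removed)), names(seqs))
    for (i in seq_along(d$kept)) {
      for (j in seq_along(d$kept)) {
        if (i != j) expect_false(grepl(d$kept[[i]], d$kept[[j]], fixed = TRUE))
      }
    }
    d2 <- dedupSequences(d$kept)
    expect_identical(d2$kept, d$kept)
    expect_length(d2$removed, 0)
  }
})

test_that("two contigs with an exact planted overlap merge to one", {
  set.seed(11)
  full <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                collapse = "")
  c1 <- substr(full, 1, 100)
  c2 <- substr(full, 61, 160)   # 40 nt overlap
  res <- metaAssemble(c(left = c1, right = c2), min_overlap = 40)
  expect_equal(nrow(res), 1L)
  expect_equal(res$seq, full)
  expect_setequal(res$sources[[1]], c("left", "right"))
})

test_that("disjoint contigs stay separate; containment is absorbed", {
  res <- metaAssemble(c(a = strrep("ACGT", 30), b = strrep("TTGA", 30)),
                      min_overlap = 40)
  expect_equal(nrow(res), 2L)

  set.seed(12)
  big <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  inner <- substr(big, 50, 140)
  res2 <- metaAssemble(c(host = big, sub = inner), min_overlap = 40)
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$seq, big)
  expect_setequal(res2$sources[[1]], c("host", "sub"))
})

test_that("every input contig aligns end-to-end within some output", {
  set.seed(13)
  cfg <- simConfig(seed = 13, n_taxa = 2L, n_orthogroups = 4L)
  sim <- simulateScaffold(cfg)
  genes <- sim$sequences[1:4]
  frags <- fragmentTranscripts(genes, cfg)
  for (g in names(genes)) {
    f <- frags[grep(paste0("^", g, "_f"), names(frags))]
    res <- metaAssemble(f)
    for (fi in f) {
      expect_true(any(vapply(res$seq, grepl, logical(1), pattern = fi,
                             fixed = TRUE)))
    }
    expect_setequal(unlist(res$sources), names(f))
  }
})

test_that("coverage filter drops rows below the non-gap threshold", {
  aln <- OrthoAlignment(c(
    full = strrep("A", 100),
    sparse = paste0(strrep("A", 10), strrep("-", 90))))
  out <- coverageFilter(aln, min_cov = 0.3)
  expect_identical(alignmentIds(out), "full")
  ## gap-free rows always kept; min_cov = 0 is the identity
  expect_equal(nrow(coverageFilter(aln, min_cov = 1)@mat), 1L)
  expect_identical(alignmentIds(coverageFilter(aln, min_cov = 0)),
                   alignmentIds(aln))
  expect_error(coverageFilter(OrthoAlignment(c(a = "", b = "")), 0.3),
               "empty")
})
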