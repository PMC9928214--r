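# Hit parsing, best-hit orthogroup assignment, classifier merging,
# low-copy selection.

hits12_line <- function(q, t, bits, e = 1e-30, id = 90, len = 100) {
  sprintf("%s\t%s\t%.1f\t%d\t5\t1\t1\t100\t1\t100\t%g\t%.1f",
          q, t, id, len, e, bits)
}

small_scaffold <- function() {
  Scaffold(data.frame(
    gene_id = c("a1", "a2", "b1", "b2"),
    taxon = c("T1", "T2", "T1", "T2"),
    og_id = c("og1", "og1", "og2", "og2")))
}

test_that("similarity dialect parses 12-column rows and flags bad ones", {
  f <- withr::local_tempfile(lines = c(
    "# comment", hits12_line("q1", "a1", 210), hits12_line("q1", "b1", 180)))
  h <- parseHits(f, "similarity_tab12")
  expect_equal(nrow(h), 2L)
  expect_equal(h$bit_score, c(210, 180))
  expect_equal(h$query_id, c("q1", "q1"))

  f2 <- withr::local_tempfile(lines = c("# only", "# comments"))
  expect_equal(nrow(parseHits(f2, "similarity_tab12")), 0L)

  f3 <- withr::local_tempfile(lines = c(
    hits12_line("q1", "a1", 210), "q2\tb1\t90\t100\t5\t1\t1\t100\t1\t100\t1e-9"))
  expect_error(parseHits(f3, "similarity_tab12"), "line 2")

  f4 <- withr::local_tempfile(lines = c(
    "q1\ta1\t90\t100\t5\t1\t1\t100\t1\t100\tnot_a_number\t210"))
  expect_error(parseHits(f4, "similarity_tab12"), "line 1")
})

test_that("profile dialect takes the profile as target and zero identity", {
  f <- withr::local_tempfile(lines = c(
    "# hmm table", "og1  -  q1  -  1e-40  120.5  rest ignored",
    "og2  -  q1  -  1e-10  35.0  x"))
  h <- parseHits(f, "profile_tblout")
  expect_equal(h$target_id, c("og1", "og2"))
  expect_equal(h$query_id, c("q1", "q1"))
  expect_equal(h$identity_pct, c(0, 0))
  expect_equal(h$bit_score, c(120.5, 35.0))
})

test_that("assignment picks the best passing hit with stated tie-breaks", {
  s <- small_scaffold()
  tm <- scaffoldTargetMap(s)
  h <- data.frame(query_id = c("q1", "q1"), target_id = c("a1", "b1"),
                  identity_pct = 90, aln_len = 100L,
                  e_value = c(1e-50, 1e-40), bit_score = c(210, 180))
  ct <- assignOrthogroups(h, s, tm)
  expect_equal(ct@assignments$og_id, "og1")

  ## equal bits -> lower e-value wins
  h$bit_score <- c(200, 200)
  ct <- assignOrthogroups(h, s, tm)
  expect_equal(ct@assignments$og_id, "og1")
  ## equal again -> lexicographically smallest og
  h$e_value <- c(1e-40, 1e-40)
  h$target_id <- c("b1", "a1")  # og2 first in the file
  ct <- assignOrthogroups(h, s, tm)
  expect_equal(ct@assignments$og_id, "og1")

  ## below threshold -> unclassified
  h2 <- data.frame(query_id = "q9", target_id = "a1", identity_pct = 50,
                   aln_len = 80L, e_value = 1e-3, bit_score = 30)
  ct2 <- assignOrthogroups(h2, s, tm)
  expect_equal(nrow(ct2@assignments), 0L)
  expect_identical(ct2@unclassified, "q9")

  ## passing hit with unmappable target is fatal
  h3 <- data.frame(query_id = "q1", target_id = "zz", identity_pct = 90,
                   aln_len = 100L, e_value = 1e-30, bit_score = 150)
  expect_error(assignOrthogroups(h3, s, tm), "zz")
})

test_that("assignment is invariant under permutation of hit rows", {
  s <- small_scaffold()
  tm <- scaffoldTargetMap(s)
  set.seed(42)
  h <- data.frame(
    query_id = rep(sprintf("q%d", 1:20), each = 4),
    target_id = sample(c("a1", "a2", "b1", "b2"), 80, replace = TRUE),
    identity_pct = 90, aln_len = 100L,
    e_value = 10^-sample(10:60, 80, replace = TRUE),
    bit_score = sample(60:300, 80, replace = TRUE))
  ref <- assignOrthogroups(h, s, tm)
  for (i in 1:5) {
    perm <- h[sample.int(nrow(h)), ]
    expect_identical(assignOrthogroups(perm, s, tm)@assignments,
                     ref@assignments)
  }
})

test_that("merging keeps singletons, flags conflicts, prefers profile", {
  s <- small_scaffold()
  mk <- function(genes, ogs, classifier) {
    new("ClassificationTable",
        assignments = data.frame(
          gene_id = genes, og_id = ogs, classifier = classifier,
          score = 100, conflict = FALSE, similarity_og = NA_character_,
          stringsAsFactors = FALSE),
        unclassified = character(0), scaffold = s@name, metadata = list())
  }
  sim <- mk(c("q1", "q2", "q3"), c("og1", "og1", "og2"), "similarity")
  prof <- mk(c("q2", "q3", "q4"), c("og1", "og1", "og2"), "profile")
  m <- mergeClassifications(sim, prof)
  a <- m@assignments
  expect_equal(nrow(a), 4L)
  expect_true(nrow(a) >= max(nrow(sim@assignments), nrow(prof@assignments)))
  expect_equal(a$classifier[a$gene_id == "q1"], "similarity")
  expect_equal(a$classifier[a$gene_id == "q4"], "profile")
  expect_equal(a$classifier[a$gene_id == "q2"], "both")
  expect_false(a$conflict[a$gene_id == "q2"])
  ## disagreement: profile og kept, similarity og recorded
  expect_true(a$conflict[a$gene_id == "q3"])
  expect_equal(a$og_id[a$gene_id == "q3"], "og1")
  expect_equal(a$similarity_og[a$gene_id == "q3"], "og2")
  ## conflicts only among genes classified by both
  expect_true(all(a$gene_id[a$conflict] %in%
                    intersect(sim@assignments$gene_id,
                              prof@assignments$gene_id)))

  prof2 <- prof; prof2@scaffold <- "other"
  expect_error(mergeClassifications(sim, prof2), "different scaffolds")
})

test_that("low-copy selection applies all three thresholds", {
  m <- data.frame(
    gene_id = sprintf("g%02d", 1:11),
    taxon = c("A", "B", "C", "D",          # og1: 1,1,1,1
              "A", "B", "B", "C", "D",     # og2: 1,2,1,1
              "A", "B"),                   # og3: 1,1,0,0
    og_id = c(rep("og1", 4), rep("og2", 5), rep("og3", 2)))
  s <- Scaffold(m)
  expect_identical(selectLowCopy(s, lowCopyRule(1, 4, 0)), "og1")
  expect_identical(selectLowCopy(s, lowCopyRule(1, 3, 1)), "og1")
  expect_setequal(selectLowCopy(s, lowCopyRule(2, 3, 1)), c("og1", "og2"))
  expect_setequal(selectLowCopy(s, lowCopyRule(1, 2, 2)), c("og1", "og3"))
  expect_error(selectLowCopy(s, lowCopyRule(1, 9, 0)), "9 taxa")
})

test_that("noiseless generative hits recover scaffold truth exactly", {
  sim <- simulateScaffold(simConfig(seed = 21, n_taxa = 3L,
                                    n_orthogroups = 12L))
  hits <- simulateHits(sim$sequences, sim$scaffold)
  ct <- assignOrthogroups(hits, sim$scaffold,
                          orthokit:::.consensusTargetMap(sim$scaffold))
  truth <- setNames(sim$truth$og_id, sim$truth$gene_id)
  expect_equal(length(ct@unclassified), 0L)
  expect_identical(ct@assignments$og_id,
                   unname(truth[ct@assignments$gene_id]))
})

test_that("metadata attachment carries annotation and counts", {
  s <- Scaffold(make_membership <- data.frame(
    gene_id = c("g1", "g2"), taxon = c("A", "B"), og_id = c("og1", "og1")),
    annotation = list(og1 = c(go = "GO:1")))
  ct <- new("ClassificationTable",
            assignments = data.frame(gene_id = "q", og_id = "og1",
                                     classifier = "similarity", score = 99,
                                     conflict = FALSE,
                                     similarity_og = NA_character_),
            unclassified = character(0), scaffold = s@name, metadata = list())
  ct <- attachMetadata(ct, s)
  expect_equal(ct@metadata$og1$annotation[["go"]], "GO:1")
  expect_equal(unname(ct@metadata$og1$counts), c(1L, 1L))
})

test_that("classification TSV round-trips", {
  ct <- new("ClassificationTable",
            assignments = data.frame(
              gene_id = c("q1", "q2"), og_id = c("og1", "og2"),
              classifier = c("both", "similarity"), score = c(210, 55.5),
              conflict = c(TRUE, FALSE),
              similarity_og = c("og3", NA_character_),
              stringsAsFactors = FALSE),
            unclassified = c("q9"), scaffold = "sc", metadata = list())
  f <- withr::local_tempfile()
  writeClassification(ct, f)
  ct2 <- readClassification(f)
  expect_identical(ct2@assignments, ct@assignments)
  expect_identical(ct2@unclassified, ct@unclassified)
  expect_identical(ct2@scaffold, "sc")
})
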