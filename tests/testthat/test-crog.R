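# Core-orthogroup analytics: master sets, intersections, capture,
# count/z-score matrices, ranking, correlation.

mk_table <- function(genes_ogs, scaffold = "sc") {
  n <- length(genes_ogs)
  new("ClassificationTable",
      assignments = data.frame(
        gene_id = if (n) names(genes_ogs) else character(0),
        og_id = unname(genes_ogs),
        classifier = rep_len("similarity", n), score = rep_len(100, n),
        conflict = rep_len(FALSE, n),
        similarity_og = rep_len(NA_character_, n), stringsAsFactors = FALSE),
      unclassified = character(0), scaffold = scaffold, metadata = list())
}

test_that("genus masters are unions over the genus's genomes", {
  tables <- list(
    A1 = mk_table(c(g1 = "og1", g2 = "og2")),
    A2 = mk_table(c(g3 = "og2", g4 = "og3")),
    B1 = mk_table(c(g5 = "og2", g6 = "og4")))
  genus_of <- c(A1 = "GenA", A2 = "GenA", B1 = "GenB")
  m <- genusMasters(tables, genus_of)
  expect_setequal(m$GenA, c("og1", "og2", "og3"))
  expect_setequal(m$GenB, c("og2", "og4"))
  expect_error(genusMasters(tables, genus_of[-1]), "without a genus")
  ## empty classification gives an empty set
  m2 <- genusMasters(list(X = mk_table(setNames(character(0), character(0)))),
                     c(X = "GenX"))
  expect_length(m2$GenX, 0)
})

test_that("the CROG set is the exact intersection of master sets", {
  expect_identical(crogSet(list(a = c("og1", "og2"), b = c("og2", "og3"))),
                   "og2")
  expect_warning(out <- crogSet(list(a = "og1", b = "og2")), "empty")
  expect_length(out, 0)
  expect_identical(crogSet(list(a = c("og1", "og2"), b = c("og2", "og1"))),
                   c("og1", "og2"))
  expect_error(crogSet(list(a = "og1")), "at least 2")
  ## equals a brute-force fold of pairwise intersections
  set.seed(61)
  masters <- lapply(1:5, function(i) {
    sample(sprintf("og%02d", 1:30), sample(10:25, 1))
  })
  names(masters) <- sprintf("gen%d", 1:5)
  fold <- masters[[1]]
  for (i in 2:5) fold <- fold[fold %in% masters[[i]]]
  expect_setequal(crogSet(masters), fold)
})

test_that("capture percentage counts CROGs with at least one gene", {
  crogs <- c("og1", "og2")
  expect_equal(capturePct(mk_table(c(g1 = "og1")), crogs), 50)
  expect_equal(capturePct(mk_table(c(g1 = "og1", g2 = "og2")), crogs), 100)
  expect_equal(capturePct(mk_table(c(g1 = "og9")), crogs), 0)
  expect_error(capturePct(mk_table(c(g1 = "og1")), character(0)), "empty")
})

test_that("the count matrix tallies genes per CROG per genome", {
  tables <- list(
    G1 = mk_table(c(a = "og1", b = "og1", c = "og2")),
    G2 = mk_table(c(d = "og1")))
  m <- crogCountMatrix(tables, c("og1", "og2"))
  expect_equal(m["og1", "G1"], 2L)
  expect_equal(m["og2", "G2"], 0L)
  ## row sums conserve each genome's genes inside CROGs
  expect_equal(sum(m[, "G1"]), 3L)
  expect_error(crogCountMatrix(tables, "og1", cohort = c("G1", "G9")), "G9")
})

test_that("z-score rows standardize exactly and sd-0 rows are dropped", {
  counts <- rbind(r1 = c(1, 2, 3), r2 = c(2, 2, 2), r3 = c(5, 0, 1))
  colnames(counts) <- c("g1", "g2", "g3")
  zs <- zscoreMatrix(counts, ddof = 1)
  expect_identical(zs$dropped, "r2")
  expect_equal(unname(zs$zmatrix["r1", ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(zs$zmatrix)) < 1e-9))
  expect_true(all(abs(apply(zs$zmatrix, 1, sd) - 1) < 1e-9))
  ## all-constant input drops everything
  zs2 <- zscoreMatrix(rbind(a = c(1, 1, 1), b = c(4, 4, 4)))
  expect_equal(nrow(zs2$zmatrix), 0L)
  expect_setequal(zs2$dropped, c("a", "b"))
  expect_error(zscoreMatrix(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("top-z ranking is descending with lexicographic tie-break", {
  z <- rbind(og_b = c(2, 0), og_a = c(2, 1), og_c = c(-1, 3))
  colnames(z) <- c("g1", "g2")
  t1 <- topZ(z, "g1", k = 1)
  expect_identical(t1$og_id, "og_a")  # tie at z=2 -> smaller og id
  t_all <- topZ(z, "g1", k = 10)
  expect_identical(t_all$og_id, c("og_a", "og_b", "og_c"))
  expect_error(topZ(z, "g1", k = 0), "k must")
  expect_error(topZ(z, "g9"), "not a column")
})

test_that("capture correlation is squared Pearson over shared genomes", {
  cap <- c(a = 10, b = 20, c = 30, d = 40)
  lin <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(captureCorrelation(cap, lin)$r_squared, 1)
  expect_equal(captureCorrelation(cap, -lin)$r_squared, 1)
  expect_equal(captureCorrelation(cap, lin)$n, 4L)
  expect_error(captureCorrelation(cap[1:2], lin), "at least 3")
  expect_error(captureCorrelation(cap, c(a = 1, b = 1, c = 1, d = 1)),
               "zero variance")
})

test_that("a planted shared set is recovered on a 3-genus/6-genome cohort", {
  set.seed(62)
  shared <- sprintf("core%02d", 1:15)
  genera <- c("GenA", "GenB", "GenC")
  tables <- list(); genus_of <- character(0)
  gid <- 0
  for (gen in genera) {
    for (k in 1:2) {
      genome <- sprintf("%s_g%d", gen, k)
      private <- sprintf("%s_priv%02d", genome, 1:sample(3:6, 1))
      ogs <- c(shared, private)
      genes <- setNames(
        sample(ogs, length(ogs) + 20, replace = TRUE),
        sprintf("gene%04d", gid + seq_len(length(ogs) + 20)))
      ## guarantee every planted og is present at least once
      genes[seq_along(ogs)] <- ogs
      gid <- gid + length(genes)
      tables[[genome]] <- mk_table(genes)
      genus_of[genome] <- gen
    }
  }
  rep_ <- crogReport(tables, genus_of)
  expect_setequal(rep_@crogs, shared)
  ## z-matrix rows standardized; dropped + kept partition the counts rows
  expect_true(all(abs(rowMeans(rep_@zmatrix)) < 1e-9))
  expect_true(all(abs(apply(rep_@zmatrix, 1, sd) - 1) < 1e-9))
  expect_setequal(c(rownames(rep_@zmatrix), rep_@droppedSd0),
                  rownames(rep_@counts))
  ## every genome holds every CROG here: capture 100
  expect_true(all(rep_@capture == 100))
  ord <- clusterOrdering(rep_@zmatrix)
  expect_setequal(ord$row_order, seq_len(nrow(rep_@zmatrix)))
  expect_setequal(ord$col_order, seq_len(ncol(rep_@zmatrix)))
})
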