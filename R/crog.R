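# Core-orthogroup (CROG) analytics: genus master sets, cross-genus
# intersection, capture percentages, gene-count and z-score matrices,
# high-z inspection, capture-vs-external-score correlation.

.ogCounts <- function(ct) {
  a <- ct@assignments
  tab <- table(a$og_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Genus-level master orthogroup sets
#'
#' The master set of a genus is the union, over the genus's genomes, of the
#' orthogroups with at least one assigned gene.
#'
#' @param tables named list: genome to [ClassificationTable-class].
#' @param genus_of named character vector: genome to genus.
#' @return named list: genus to sorted character vector of orthogroup ids.
#' @export
genusMasters <- function(tables, genus_of) {
  missing <- setdiff(names(tables), names(genus_of))
  if (length(missing)) {
    .okitStop(sprintf("genome(s) without a genus: %s",
                      paste(missing, collapse = ", ")))
  }
  genera <- unique(unname(genus_of[names(tables)]))
  masters <- lapply(genera, function(g) {
    genomes <- names(tables)[genus_of[names(tables)] == g]
    sort(unique(unlist(lapply(tables[genomes], function(ct) {
      unique(ct@assignments$og_id)
    }), use.names = FALSE)))
  })
  stats::setNames(masters, genera)
}

#' Core orthogroups: intersection of all genus master sets
#'
#' @param masters named list from [genusMasters()], at least 2 genera.
#' @return sorted character vector of orthogroup ids present in every
#'   master set (may be empty, with a warning).
#' @export
crogSet <- function(masters) {
  if (length(masters) < 2L) {
    .okitStop("core-orthogroup intersection needs at least 2 genera")
  }
  out <- Reduce(intersect, masters)
  if (!length(out)) warning("master sets share no orthogroup: empty CROG set")
  sort(out)
}

#' Percentage of CROGs captured by a genome
#'
#' 100 times the fraction of the CROG set with at least one assigned gene in
#' the genome: a genome-annotation completeness proxy.
#'
#' @param table the genome's [ClassificationTable-class].
#' @param crogs character vector of core orthogroup ids (non-empty).
#' @return a percentage in `[0, 100]`.
#' @export
capturePct <- function(table, crogs) {
  if (!length(crogs)) .okitStop("empty CROG set")
  present <- unique(table@assignments$og_id)
  100 * length(intersect(present, crogs)) / length(crogs)
}

#' CROG-by-genome gene count matrix
#'
#' @param tables named list: genome to [ClassificationTable-class].
#' @param crogs CROG ids (rows).
#' @param cohort genomes to include as columns (default: all of `tables`).
#' @return integer matrix, rows `crogs` x columns `cohort`; a cell is the
#'   number of that genome's genes assigned to that CROG.
#' @export
crogCountMatrix <- function(tables, crogs, cohort = names(tables)) {
  missing <- setdiff(cohort, names(tables))
  if (length(missing)) {
    .okitStop(sprintf("cohort genome(s) without classification: %s",
                      paste(missing, collapse = ", ")))
  }
  m <- matrix(0L, nrow = length(crogs), ncol = length(cohort),
              dimnames = list(crogs, cohort))
  for (g in cohort) {
    cnt <- .ogCounts(tables[[g]])
    hit <- intersect(names(cnt), crogs)
    m[hit, g] <- cnt[hit]
  }
  m
}

#' Row-standardize a count matrix to z-scores
#'
#' Per-row z = (x - row mean) / row sd with the configured degrees-of-
#' freedom correction (sample sd, `ddof = 1`, by default). Rows with zero
#' standard deviation carry no comparative signal and are removed and
#' reported, the standard pre-plotting step for count clustermaps.
#'
#' @param counts numeric matrix with at least 2 columns.
#' @param ddof delta degrees of freedom for the row sd (default 1).
#' @return list with `zmatrix` (rows with sd > 0, each standardized to mean
#'   0 and sd 1) and `dropped` (row names with sd 0).
#' @export
zscoreMatrix <- function(counts, ddof = 1L) {
  if (ncol(counts) < 2L) {
    .okitStop("z-scores need at least 2 genome columns")
  }
  mu <- rowMeans(counts)
  n <- ncol(counts)
  ss <- rowSums((counts - mu)^2)
  sdv <- sqrt(ss / (n - ddof))
  zero <- sdv == 0
  z <- (counts[!zero, , drop = FALSE] - mu[!zero]) / sdv[!zero]
  list(zmatrix = z, dropped = rownames(counts)[zero])
}

#' Top-k orthogroups by z-score in one genome
#'
#' @param zmatrix matrix from [zscoreMatrix()].
#' @param genome column to rank.
#' @param k how many rows (default 150); all rows if fewer.
#' @return data.frame `og_id`, `z`, descending z, ties broken by og id.
#' @export
topZ <- function(zmatrix, genome, k = 150L) {
  if (k < 1L) .okitStop("k must be >= 1")
  if (!genome %in% colnames(zmatrix)) {
    .okitStop(sprintf("genome '%s' is not a column of the z-matrix", genome))
  }
  z <- zmatrix[, genome]
  ord <- order(-z, rownames(zmatrix), method = "radix")
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(og_id = rownames(zmatrix)[sel], z = unname(z[sel]),
             stringsAsFactors = FALSE)
}

#' Squared correlation of capture percentages with external scores
#'
#' Squared Pearson correlation between per-genome CROG capture percentages
#' and an external per-genome quality score (e.g. a single-copy-ortholog
#' completeness score), over the genomes present in both maps.
#'
#' @param capture named numeric: genome to capture percentage.
#' @param external_scores named numeric: genome to external score.
#' @return list with `r_squared` and `n` (genomes used).
#' @export
captureCorrelation <- function(capture, external_scores) {
  shared <- intersect(names(capture), names(external_scores))
  if (length(shared) < 3L) {
    .okitStop("correlation needs at least 3 shared genomes")
  }
  x <- capture[shared]; y <- external_scores[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .okitStop("zero variance in capture or external scores")
  }
  list(r_squared = stats::cor(x, y)^2, n = length(shared))
}

#' Row/column display order by hierarchical clustering
#'
#' Average-linkage Euclidean clustering of the z-matrix, returning the leaf
#' orders used to draw clustermap-style heatmaps (rendering itself is left
#' to the caller).
#'
#' @param zmatrix matrix from [zscoreMatrix()].
#' @return list with integer vectors `row_order` and `col_order`.
#' @export
clusterOrdering <- function(zmatrix) {
  row_order <- if (nrow(zmatrix) > 2L) {
    stats::hclust(stats::dist(zmatrix), method = "average")$order
  } else seq_len(nrow(zmatrix))
  col_order <- if (ncol(zmatrix) > 2L) {
    stats::hclust(stats::dist(t(zmatrix)), method = "average")$order
  } else seq_len(ncol(zmatrix))
  list(row_order = row_order, col_order = col_order)
}

#' Full core-orthogroup report for a cohort
#'
#' Convenience driver chaining [genusMasters()], [crogSet()],
#' [crogCountMatrix()], [zscoreMatrix()] and [capturePct()].
#'
#' @param tables named list: genome to [ClassificationTable-class].
#' @param genus_of named character: genome to genus.
#' @param cohort genomes for the count/z matrices (default all).
#' @param ddof row-sd degrees-of-freedom correction (default 1).
#' @return a [CrogReport-class].
#' @export
crogReport <- function(tables, genus_of, cohort = names(tables), ddof = 1L) {
  masters <- genusMasters(tables, genus_of)
  crogs <- crogSet(masters)
  counts <- crogCountMatrix(tables, crogs, cohort)
  zs <- zscoreMatrix(counts, ddof = ddof)
  capture <- vapply(names(tables), function(g) {
    capturePct(tables[[g]], crogs)
  }, numeric(1))
  new("CrogReport",
      genusOf = genus_of[names(tables)],
      masters = masters, crogs = crogs, counts = counts,
      zmatrix = zs$zmatrix, droppedSd0 = zs$dropped, capture = capture)
}

setMethod("show", "CrogReport", function(object) {
  cat(sprintf("CrogReport: %d genera, %d genomes, %d CROGs\n",
              length(object@masters), length(object@genusOf),
              length(object@crogs)))
  cat(sprintf("  z-matrix %d x %d (%d rows dropped, sd = 0)\n",
              nrow(object@zmatrix), ncol(object@zmatrix),
              length(object@droppedSd0)))
  if (length(object@capture)) {
    cat(sprintf("  capture %%: %s\n",
                paste(sprintf("%s=%.1f", names(object@capture),
                              object@capture), collapse = ", ")))
  }
})
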