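#' @import methods
NULL

#' Gene-family scaffold
#'
#' A `Scaffold` holds a pre-computed orthogroup circumscription over a set of
#' reference taxa: the gene-to-orthogroup membership table, optional
#' per-orthogroup sequences, free-text annotations, super-orthogroup cluster
#' labels at multiple stringencies, and the derived orthogroup-by-taxon gene
#' count matrix. The membership table is the single source of truth: counts
#' are always recomputed from it, never read from disk.
#'
#' @slot name scaffold label.
#' @slot method clustering-method label (e.g. orthology-based vs
#'   consensus-domain); opaque to the package.
#' @slot taxa ordered character vector of taxon labels. The order is the
#'   first-appearance order in the membership table and is used by every
#'   matrix derived from the scaffold.
#' @slot membership data.frame with columns `gene_id`, `taxon`, `og_id`.
#' @slot sequences named list, orthogroup id to named character vector of
#'   member sequences (may be empty).
#' @slot annotation named list, orthogroup id to named character vector
#'   (annotation source to free text).
#' @slot superOg named list, orthogroup id to named character vector
#'   (stringency label to super-orthogroup id).
#' @slot counts integer matrix, orthogroups x taxa, derived from membership.
#'
#' @seealso [readScaffold()], [writeScaffold()], [scaffoldCounts()]
#' @export
setClass("Scaffold",
  representation(
    name = "character",
    method = "character",
    taxa = "character",
    membership = "data.frame",
    sequences = "list",
    annotation = "list",
    superOg = "list",
    counts = "matrix"
  )
)

setValidity("Scaffold", function(object) {
  m <- object@membership
  msgs <- character(0)
  need <- c("gene_id", "taxon", "og_id")
  if (!all(need %in% names(m))) {
    return(sprintf("membership must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(m$gene_id)) {
    dup <- m$gene_id[duplicated(m$gene_id)][1L]
    ogs <- unique(m$og_id[m$gene_id == dup])
    msgs <- c(msgs, sprintf(
      "gene '%s' appears more than once (orthogroups: %s)",
      dup, paste(ogs, collapse = ", ")))
  }
  if (!setequal(object@taxa, unique(m$taxon)) && nrow(m) > 0) {
    msgs <- c(msgs, "taxa slot must match taxa present in membership")
  }
  expected <- .countsFromMembership(m, object@taxa)
  cn <- object@counts
  ## counts must reproduce membership; extra all-zero rows are allowed
  ## (orthogroups retained as assignable targets after a taxon hold-out)
  if (!all(rownames(expected) %in% rownames(cn)) ||
      !isTRUE(all(cn[rownames(expected), , drop = FALSE] == expected))) {
    msgs <- c(msgs, "counts matrix inconsistent with membership")
  } else {
    extra <- setdiff(rownames(cn), rownames(expected))
    if (length(extra) && any(cn[extra, , drop = FALSE] != 0L)) {
      msgs <- c(msgs, "rows without membership must have zero counts")
    }
  }
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Orthogroup classification table
#'
#' Result of classifying query coding sequences into scaffold orthogroups.
#' Each classified gene appears exactly once in `assignments`; queries with no
#' passing hit are listed in `unclassified`. `assignments` carries the
#' classifier provenance (`similarity`, `profile` or `both`), the supporting
#' score, a `conflict` flag set when the two classifiers disagreed, and (for
#' conflicts) the similarity classifier's candidate in `similarity_og`.
#'
#' @slot assignments data.frame with columns `gene_id`, `og_id`, `classifier`,
#'   `score`, `conflict`, `similarity_og`.
#' @slot unclassified character vector of query ids with no passing hit.
#' @slot scaffold name of the scaffold classified against.
#' @slot metadata named list, orthogroup id to attached scaffold metadata
#'   (annotation text and per-taxon counts); filled by [attachMetadata()].
#' @seealso [assignOrthogroups()], [mergeClassifications()]
#' @export
setClass("ClassificationTable",
  representation(
    assignments = "data.frame",
    unclassified = "character",
    scaffold = "character",
    metadata = "list"
  )
)

setValidity("ClassificationTable", function(object) {
  a <- object@assignments
  need <- c("gene_id", "og_id", "classifier", "score", "conflict", "similarity_og")
  if (!all(need %in% names(a))) {
    return(sprintf("assignments must have columns %s", paste(need, collapse = ", ")))
  }
  msgs <- character(0)
  if (anyDuplicated(a$gene_id)) {
    msgs <- c(msgs, "each gene may be assigned at most once")
  }
  if (length(intersect(a$gene_id, object@unclassified))) {
    msgs <- c(msgs, "assignments and unclassified must be disjoint")
  }
  bad <- !a$classifier %in% c("similarity", "profile", "both")
  if (any(bad)) msgs <- c(msgs, "classifier must be similarity/profile/both")
  if (any(a$conflict & a$classifier != "both")) {
    msgs <- c(msgs, "conflict flag only valid for merged (both) assignments")
  }
  if (length(msgs)) msgs else TRUE
})

#' Multiple sequence alignment matrix
#'
#' Rectangular character alignment with gap character `-`. Ungapping any row
#' reproduces the source sequence exactly; this invariant is what makes
#' column trimming, row coverage filtering and back-translation safe to
#' compose in any order.
#'
#' @slot mat character matrix of single residues, rows named by sequence id.
#' @slot taxa named character vector mapping row id to taxon (may be empty).
#' @seealso [trimAlignment()], [coverageFilter()], [backtranslate()]
#' @export
setClass("OrthoAlignment",
  representation(mat = "matrix", taxa = "character")
)

setValidity("OrthoAlignment", function(object) {
  m <- object@mat
  if (!is.character(m)) return("alignment matrix must be character")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    return("alignment rows must have unique ids")
  }
  if (length(m) && any(nchar(m) != 1L)) {
    return("alignment cells must be single characters")
  }
  TRUE
})

#' Gaussian mixture model of a Ks distribution
#'
#' Fitted by [fitKsMixture()]: a univariate normal mixture over synonymous
#' substitution rates (Ks), the standard device for spotting large-scale
#' (whole-genome) duplication events as secondary peaks in the Ks
#' distribution. Component count is selected by BIC; components carrying at
#' least a configurable share of the weight are flagged significant.
#'
#' @slot k selected component count.
#' @slot weights,means,sigmas per-component parameters; weights sum to 1.
#' @slot loglik log-likelihood of the selected fit.
#' @slot bic BIC of the selected fit (the model-selection score).
#' @slot bicByK BIC for each candidate k (named numeric).
#' @slot significant logical per component: weight >= the significance
#'   threshold used at fit time.
#' @slot n number of Ks values fitted (after range filtering).
#' @slot ksRange the `[ks_min, ks_max]` filter window applied.
#' @slot loglikTrace per-iteration log-likelihood of the winning EM run
#'   (monotone non-decreasing).
#' @seealso [ksPlotData()]
#' @export
setClass("KsMixture",
  representation(
    k = "integer",
    weights = "numeric",
    means = "numeric",
    sigmas = "numeric",
    loglik = "numeric",
    bic = "numeric",
    bicByK = "numeric",
    significant = "logical",
    n = "integer",
    ksRange = "numeric",
    loglikTrace = "numeric"
  )
)

setValidity("KsMixture", function(object) {
  msgs <- character(0)
  if (abs(sum(object@weights) - 1) > 1e-9) msgs <- c(msgs, "weights must sum to 1")
  if (any(object@sigmas <= 0)) msgs <- c(msgs, "sigmas must be positive")
  if (length(object@weights) != object@k ||
      length(object@means) != object@k ||
      length(object@sigmas) != object@k) {
    msgs <- c(msgs, "parameter vectors must have length k")
  }
  if (length(msgs)) msgs else TRUE
})

#' Core-orthogroup (CROG) report
#'
#' Container for core-orthogroup analytics over a cohort of genomes grouped
#' into genera: per-genus master orthogroup sets (unions over the genus's
#' genomes), their intersection (the CROGs), the CROG-by-genome gene count
#' matrix, the row-standardized z-score matrix (rows with zero standard
#' deviation dropped), and per-genome capture percentages.
#'
#' @slot genusOf named character, genome to genus.
#' @slot masters named list, genus to character vector of orthogroup ids.
#' @slot crogs character vector: orthogroups present in every master set.
#' @slot counts integer matrix, CROGs x genomes.
#' @slot zmatrix numeric matrix of row z-scores (subset of counts rows).
#' @slot droppedSd0 orthogroup ids removed because their count row had zero
#'   standard deviation.
#' @slot capture named numeric, genome to percentage of CROGs captured.
#' @seealso [crogReport()], [zscoreMatrix()], [capturePct()]
#' @export
setClass("CrogReport",
  representation(
    genusOf = "character",
    masters = "list",
    crogs = "character",
    counts = "matrix",
    zmatrix = "matrix",
    droppedSd0 = "character",
    capture = "numeric"
  )
)

setValidity("CrogReport", function(object) {
  msgs <- character(0)
  for (g in names(object@masters)) {
    if (!all(object@crogs %in% object@masters[[g]])) {
      msgs <- c(msgs, sprintf("crogs must be a subset of master set '%s'", g))
      break
    }
  }
  if (length(object@capture) &&
      (any(object@capture < 0) || any(object@capture > 100))) {
    msgs <- c(msgs, "capture percentages must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})
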