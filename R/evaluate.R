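# Leave-one-taxon-out benchmarking of orthogroup classifiers.

#' Hold one taxon out of a scaffold
#'
#' Removes every gene of the taxon from the scaffold membership and returns
#' the reduced scaffold together with the truth map (removed gene to its
#' original orthogroup). Orthogroups emptied by the removal are retained in
#' the reduced scaffold as assignable targets and reported in `emptied`.
#'
#' @param s a [Scaffold-class].
#' @param taxon taxon to remove (must be present).
#' @return list: `reduced` ([Scaffold-class]), `truth` (named character,
#'   gene to orthogroup), `emptied` (orthogroup ids with no members left).
#' @export
holdOut <- function(s, taxon) {
  if (!taxon %in% s@taxa) {
    .okitStop(sprintf("taxon '%s' is not in the scaffold", taxon))
  }
  m <- s@membership
  removed <- m[m$taxon == taxon, , drop = FALSE]
  kept <- m[m$taxon != taxon, , drop = FALSE]
  truth <- stats::setNames(removed$og_id, removed$gene_id)
  emptied <- setdiff(unique(removed$og_id), unique(kept$og_id))
  reduced <- Scaffold(kept, name = s@name, method = s@method,
                      sequences = s@sequences,
                      annotation = s@annotation, superOg = s@superOg)
  ## emptied orthogroups stay assignable: reinstate zero-count rows
  if (length(emptied)) {
    counts <- reduced@counts
    extra <- matrix(0L, nrow = length(emptied), ncol = ncol(counts),
                    dimnames = list(emptied, colnames(counts)))
    reduced@counts <- rbind(counts, extra)
  }
  ## drop the held-out taxon's members from per-orthogroup sequence lists
  if (length(reduced@sequences)) {
    held_genes <- removed$gene_id
    reduced@sequences <- lapply(reduced@sequences, function(x) {
      x[setdiff(names(x), held_genes)]
    })
  }
  list(reduced = reduced, truth = truth, emptied = emptied)
}

#' Score a re-classification against the held-out truth
#'
#' A true positive is a gene reassigned to its original orthogroup. Recall
#' divides by all held-out genes (whether the classifier assigned them or
#' not); precision divides by the genes the classifier assigned anywhere;
#' F-score is their harmonic mean. Zero denominators yield 0 with a
#' warning.
#'
#' @param truth named character vector, gene to original orthogroup.
#' @param predicted a [ClassificationTable-class] over a subset of the
#'   truth genes.
#' @param taxon,classifier labels carried into the report.
#' @return one-row data.frame: `taxon`, `classifier`, `tp`, `assigned`,
#'   `truth_total`, `recall`, `precision`, `fscore`.
#' @export
scoreClassification <- function(truth, predicted, taxon = NA_character_,
                                classifier = NA_character_) {
  a <- predicted@assignments
  alien <- setdiff(a$gene_id, names(truth))
  if (length(alien)) {
    .okitStop(sprintf("predicted gene(s) not in the truth set: %s",
                      paste(utils::head(alien, 5), collapse = ", ")))
  }
  assigned <- nrow(a)
  truth_total <- length(truth)
  tp <- sum(a$og_id == truth[a$gene_id])
  if (assigned == 0L || truth_total == 0L) {
    warning("zero denominator in precision/recall: reporting 0")
  }
  precision <- if (assigned > 0L) tp / assigned else 0
  recall <- if (truth_total > 0L) tp / truth_total else 0
  fscore <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  data.frame(taxon = taxon, classifier = classifier,
             tp = as.integer(tp), assigned = as.integer(assigned),
             truth_total = as.integer(truth_total),
             recall = recall, precision = precision, fscore = fscore,
             stringsAsFactors = FALSE)
}

#' Leave-one-taxon-out evaluation over a whole scaffold
#'
#' For each requested taxon: hold it out, regenerate synthetic
#' classification hits from the reduced scaffold ([simulateHits()]), assign
#' with [assignOrthogroups()], and score. This is the benchmarking protocol
#' used to compare classifiers at varying evolutionary distances; the
#' taxa-to-remove vs taxon-to-score split makes double-removal designs
#' (removing a sister taxon along with the scored one) expressible.
#'
#' @param s a [Scaffold-class] with per-orthogroup sequences.
#' @param sequences named character vector of all gene sequences.
#' @param taxa taxa to evaluate (default: all scaffold taxa).
#' @param also_remove optional character vector of additional taxa removed
#'   (but not scored) alongside each evaluated taxon.
#' @param min_bits,max_e assignment thresholds.
#' @param noise_rate fraction of predictions whose orthogroup label is
#'   corrupted before scoring (default 0: noiseless). Corruption is applied
#'   to an exact `round(noise_rate * n)` subset so the realized rate equals
#'   the nominal one.
#' @param seed seed for hit generation and label noise.
#' @return data.frame with one row per taxon (rbind of
#'   [scoreClassification()] rows).
#' @export
evaluateClassifier <- function(s, sequences, taxa = scaffoldTaxa(s),
                               also_remove = character(0),
                               min_bits = 50, max_e = 1e-5,
                               noise_rate = 0, seed = 1L) {
  rows <- lapply(taxa, function(tx) {
    ho <- holdOut(s, tx)
    reduced <- ho$reduced
    for (extra in setdiff(also_remove, tx)) {
      if (extra %in% reduced@taxa) reduced <- holdOut(reduced, extra)$reduced
    }
    queries <- sequences[names(ho$truth)]
    hits <- simulateHits(queries, reduced, seed = seed)
    ct <- assignOrthogroups(hits, reduced,
                            target_map = .consensusTargetMap(reduced),
                            min_bits = min_bits, max_e = max_e,
                            classifier = "similarity")
    if (noise_rate > 0 && nrow(ct@assignments)) {
      old_seed <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      set.seed(seed + 7L)
      ## corrupt an exact fraction of the predictions: noise_rate is the
      ## realized corruption rate, not just its expectation
      n_a <- nrow(ct@assignments)
      n_flip <- round(noise_rate * n_a)
      flip <- seq_len(n_a) %in% sample.int(n_a, n_flip)
      pool <- orthogroupIds(reduced)
      ct@assignments$og_id[flip] <- vapply(
        which(flip), function(i) {
          sample(setdiff(pool, ct@assignments$og_id[i]), 1L)
        }, character(1))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }
    scoreClassification(ho$truth, ct, taxon = tx, classifier = "similarity")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
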