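# Orthogroup sequence integration and post-alignment processing.

#' Construct an alignment matrix
#'
#' @param seqs named character vector of equal-length aligned strings
#'   (gap character `-`).
#' @param taxa optional named character vector mapping row id to taxon.
#' @return an [OrthoAlignment-class].
#' @export
OrthoAlignment <- function(seqs, taxa = character(0)) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    .okitStop("aligned sequences must have unique names")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    .okitStop("aligned sequences must all have the same length")
  }
  width <- if (length(seqs)) lens[[1L]] else 0L
  mat <- matrix("", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  if (width > 0L) {
    for (i in seq_along(seqs)) {
      mat[i, ] <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    }
  }
  new("OrthoAlignment", mat = mat, taxa = taxa)
}

#' @describeIn OrthoAlignment rows as named character strings.
#' @param aln an `OrthoAlignment`.
#' @export
alignmentStrings <- function(aln) {
  m <- aln@mat
  stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

#' @describeIn OrthoAlignment row ids.
#' @export
alignmentIds <- function(aln) rownames(aln@mat)

setMethod("show", "OrthoAlignment", function(object) {
  cat(sprintf("OrthoAlignment: %d sequences x %d columns\n",
              nrow(object@mat), ncol(object@mat)))
})

#' Integrate classified sequences into their orthogroups
#'
#' Builds, per orthogroup, the sequence set to align: the scaffold members'
#' sequences first (scaffold order), then the newly classified query
#' sequences (stable input order).
#'
#' @param ct a [ClassificationTable-class].
#' @param seqs named character vector holding a sequence for every
#'   classified gene.
#' @param s the [Scaffold-class].
#' @param skip_unchanged drop orthogroups that gained no new member
#'   (default FALSE).
#' @return named list: orthogroup id to named character vector of sequences.
#' @export
integrateOrthogroups <- function(ct, seqs, s, skip_unchanged = FALSE) {
  a <- ct@assignments
  missing <- setdiff(a$gene_id, names(seqs))
  if (length(missing)) {
    .okitStop(sprintf("classified gene(s) without a sequence: %s",
                      paste(utils::head(missing, 5), collapse = ", ")))
  }
  out <- list()
  for (og in orthogroupIds(s)) {
    scaffold_seqs <- s@sequences[[og]]
    if (is.null(scaffold_seqs)) scaffold_seqs <- character(0)
    new_ids <- a$gene_id[a$og_id == og]
    if (skip_unchanged && !length(new_ids)) next
    clash <- intersect(new_ids, names(scaffold_seqs))
    if (length(clash)) {
      .okitStop(sprintf("id '%s' present in both scaffold and queries for %s",
                        clash[1L], og))
    }
    out[[og]] <- c(scaffold_seqs, seqs[new_ids])
  }
  ## orthogroups present only in the classification (no scaffold row) are
  ## impossible by construction: assignments always point at scaffold ogs
  out
}

#' Trim predominantly-gap alignment columns
#'
#' Keeps exactly the columns whose non-gap fraction is at least `gt`
#' (the gap-threshold convention of common alignment trimmers); all-gap
#' columns are always removed, even at `gt = 0`. Column order is preserved
#' and the operation is idempotent at fixed `gt`.
#'
#' @param aln an [OrthoAlignment-class].
#' @param gt minimum non-gap fraction per kept column, in `[0, 1]`
#'   (default 0.1).
#' @return the trimmed [OrthoAlignment-class].
#' @export
trimAlignment <- function(aln, gt = 0.1) {
  if (gt < 0 || gt > 1) .okitStop("gt must be in [0, 1]")
  m <- aln@mat
  if (nrow(m) == 0L || ncol(m) == 0L) .okitStop("empty alignment")
  nongap <- colMeans(m != "-")
  keep <- nongap >= gt & nongap > 0
  new("OrthoAlignment", mat = m[, keep, drop = FALSE], taxa = aln@taxa)
}

#' @rdname coverageFilter
#' @details `removeLowCoverageRows()` is the same operation applied in the
#'   post-alignment cleaning step (shared implementation).
#' @export
removeLowCoverageRows <- function(aln, min_cov = 0.3) {
  coverageFilter(aln, min_cov)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue becomes its source codon and each gap becomes `---`, so the
#' codon alignment is exactly three times the protein alignment length.
#' Every CDS must translate (standard code) to its ungapped protein row; a
#' trailing stop codon is permitted and dropped.
#'
#' @param protein_aln an [OrthoAlignment-class] of amino acids.
#' @param cds named character vector: row id to coding sequence.
#' @return codon [OrthoAlignment-class].
#' @export
backtranslate <- function(protein_aln, cds) {
  m <- protein_aln@mat
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    rid <- rownames(m)[i]
    if (!rid %in% names(cds)) {
      .okitStop(sprintf("no CDS provided for row '%s'", rid))
    }
    codons <- .splitCodons(toupper(cds[[rid]]))
    if (length(codons) && .geneticCode()[codons[length(codons)]] == "*") {
      codons <- codons[-length(codons)]
    }
    row <- m[i, ]
    residues <- which(row != "-")
    if (length(residues) != length(codons)) {
      .okitStop(sprintf(
        "row '%s': CDS has %d codons but ungapped protein has %d residues",
        rid, length(codons), length(residues)))
    }
    aa <- unname(.geneticCode()[codons])
    mism <- which(aa != row[residues])
    if (length(mism)) {
      .okitStop(sprintf(
        "row '%s': codon %d translates to %s but aligned residue is %s",
        rid, mism[1L], aa[mism[1L]], row[residues][mism[1L]]))
    }
    cells <- rep("---", length(row))
    cells[residues] <- codons
    out[i] <- paste(cells, collapse = "")
  }
  OrthoAlignment(stats::setNames(out, rownames(m)), taxa = protein_aln@taxa)
}

#' Align sequences through a pluggable backend
#'
#' The built-in `"padded"` backend right-pads every sequence with gaps to
#' the longest sequence's length: a deterministic stand-in that satisfies
#' all alignment-matrix invariants and lets the downstream trimming,
#' filtering and tree steps run without any external program. External
#' aligners are invoked through a backend spec `list(cmd=, args=)` whose
#' arguments may reference `{input}` and `{output}` FASTA paths.
#'
#' After trimming or row removal changed the sequence set, callers may
#' re-run the backend once on the surviving ungapped sequences
#' (`realign = TRUE` in the pipeline drivers); realignment is bounded to a
#' single iteration.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param backend `"padded"` or a `list(cmd, args)` spec.
#' @param taxa optional row id to taxon map.
#' @return an [OrthoAlignment-class].
#' @export
alignSequences <- function(seqs, backend = "padded", taxa = character(0)) {
  if (!length(seqs)) .okitStop("no sequences to align")
  if (identical(backend, "padded")) {
    width <- max(nchar(seqs))
    padded <- vapply(seqs, function(x) {
      paste0(x, strrep("-", width - nchar(x)))
    }, character(1))
    return(OrthoAlignment(padded, taxa = taxa))
  }
  if (!is.list(backend) || is.null(backend$cmd)) {
    .okitStop("backend must be \"padded\" or list(cmd=, args=)")
  }
  tin <- tempfile(fileext = ".fasta"); tout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tin, tout)), add = TRUE)
  .writeFasta(seqs, tin)
  args <- vapply(backend$args, function(a) {
    a <- gsub("{input}", tin, a, fixed = TRUE)
    gsub("{output}", tout, a, fixed = TRUE)
  }, character(1))
  status <- tryCatch(
    suppressWarnings(system2(backend$cmd, args, stdout = tout, stderr = TRUE)),
    error = function(e) structure(conditionMessage(e), status = 127L))
  if (is.integer(attr(status, "status")) || !file.exists(tout) ||
      file.size(tout) == 0) {
    .okitStop(sprintf("alignment backend '%s' failed: %s", backend$cmd,
                      paste(utils::head(status, 3), collapse = " | ")),
              class = "okit_backend_error")
  }
  OrthoAlignment(.readFasta(tout), taxa = taxa)
}
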