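# Scaffold construction, accessors and directory I/O.

.countsFromMembership <- function(membership, taxa = NULL) {
  if (is.null(taxa)) taxa <- unique(membership$taxon)
  ogs <- unique(membership$og_id)
  counts <- matrix(0L, nrow = length(ogs), ncol = length(taxa),
                   dimnames = list(ogs, taxa))
  if (nrow(membership)) {
    tab <- table(factor(membership$og_id, levels = ogs),
                 factor(membership$taxon, levels = taxa))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Construct a gene-family scaffold from a membership table
#'
#' @param membership data.frame with columns `gene_id`, `taxon`, `og_id`; one
#'   row per gene. Taxon order of the scaffold is first-appearance order in
#'   this table.
#' @param name,method free-text labels.
#' @param sequences optional named list: orthogroup id to named character
#'   vector of member sequences.
#' @param annotation optional named list: orthogroup id to named character
#'   vector (source to text).
#' @param superOg optional named list: orthogroup id to named character
#'   vector (stringency label to super-orthogroup id).
#' @return A [Scaffold-class] object. Gene ids must be globally unique; a
#'   gene listed under two orthogroups is an error naming both.
#' @examples
#' m <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
#'                 taxon   = c("A", "B", "A", "B"),
#'                 og_id   = c("og1", "og1", "og2", "og2"))
#' s <- Scaffold(m, name = "demo")
#' scaffoldCounts(s)
#' @export
Scaffold <- function(membership, name = "scaffold", method = "unspecified",
                     sequences = list(), annotation = list(), superOg = list()) {
  membership <- as.data.frame(membership, stringsAsFactors = FALSE)
  need <- c("gene_id", "taxon", "og_id")
  if (!all(need %in% names(membership))) {
    .okitStop(sprintf("membership must have columns %s",
                      paste(need, collapse = ", ")))
  }
  membership <- membership[, need]
  for (col in need) membership[[col]] <- as.character(membership[[col]])
  rownames(membership) <- NULL
  if (anyDuplicated(membership$gene_id)) {
    dup <- unique(membership$gene_id[duplicated(membership$gene_id)])[1L]
    ogs <- unique(membership$og_id[membership$gene_id == dup])
    .okitStop(sprintf(
      "gene '%s' is listed in more than one orthogroup (%s)",
      dup, paste(ogs, collapse = ", ")))
  }
  taxa <- unique(membership$taxon)
  new("Scaffold", name = name, method = method, taxa = taxa,
      membership = membership, sequences = sequences,
      annotation = annotation, superOg = superOg,
      counts = .countsFromMembership(membership, taxa))
}

#' @describeIn Scaffold scaffold taxa, in canonical (first-appearance) order.
#' @param s a `Scaffold`.
#' @export
scaffoldTaxa <- function(s) s@taxa

#' @describeIn Scaffold orthogroup-by-taxon gene count matrix.
#' @export
scaffoldCounts <- function(s) s@counts

#' @describeIn Scaffold orthogroup ids, in first-appearance order.
#' @export
orthogroupIds <- function(s) rownames(s@counts)

#' @describeIn Scaffold membership table (gene_id, taxon, og_id).
#' @export
scaffoldMembership <- function(s) s@membership

#' @describeIn Scaffold gene ids of one orthogroup, optionally one taxon.
#' @param og orthogroup id.
#' @param taxon optional taxon restriction.
#' @export
orthogroupMembers <- function(s, og, taxon = NULL) {
  m <- s@membership
  keep <- m$og_id == og
  if (!is.null(taxon)) keep <- keep & m$taxon == taxon
  m$gene_id[keep]
}

#' @describeIn Scaffold per-orthogroup sequence list.
#' @export
scaffoldSequences <- function(s) s@sequences

setMethod("show", "Scaffold", function(object) {
  cat(sprintf("Scaffold '%s' (%s)\n", object@name, object@method))
  cat(sprintf("  %d orthogroups, %d taxa, %d genes\n",
              nrow(object@counts), length(object@taxa),
              nrow(object@membership)))
  if (length(object@taxa)) {
    cat("  taxa:", paste(utils::head(object@taxa, 8), collapse = ", "),
        if (length(object@taxa) > 8) "..." else "", "\n")
  }
})

#' Read a scaffold from a directory
#'
#' Expects a `membership.tsv` (columns gene_id, taxon, og_id; `#` comment
#' lines skipped), an optional `annotation.tsv` (og_id, source, text), an
#' optional `superog.tsv` (og_id, stringency, cluster) and optional
#' per-orthogroup FASTA files named `<og_id>.fna` (nucleotide) or
#' `<og_id>.faa` (protein). The gene count matrix is always recomputed from
#' membership; nothing on disk is trusted to carry it.
#'
#' @param dir_path directory containing scaffold files.
#' @param name,method labels; default name is the directory basename.
#' @return A [Scaffold-class].
#' @seealso [writeScaffold()] for the inverse; the two compose to the
#'   identity.
#' @export
readScaffold <- function(dir_path, name = basename(dir_path),
                         method = "unspecified") {
  mem_path <- file.path(dir_path, "membership.tsv")
  if (!file.exists(mem_path)) {
    .okitStop(sprintf("membership file not found: %s", mem_path))
  }
  lines <- readLines(mem_path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      .okitStop(sprintf("membership line %d does not have 3 tab-separated fields",
                        bad[1L]))
    }
    membership <- data.frame(
      gene_id = vapply(parts, `[[`, "", 1L),
      taxon = vapply(parts, `[[`, "", 2L),
      og_id = vapply(parts, `[[`, "", 3L),
      stringsAsFactors = FALSE)
  } else {
    membership <- data.frame(gene_id = character(0), taxon = character(0),
                             og_id = character(0), stringsAsFactors = FALSE)
  }

  annotation <- list()
  ann_path <- file.path(dir_path, "annotation.tsv")
  if (file.exists(ann_path)) {
    alines <- readLines(ann_path)
    alines <- alines[!grepl("^#", alines) & nzchar(alines)]
    for (ln in alines) {
      p <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(p) < 3L) .okitStop(sprintf("malformed annotation line: %s", ln))
      annotation[[p[1L]]] <- c(annotation[[p[1L]]],
                               stats::setNames(paste(p[-(1:2)], collapse = "\t"), p[2L]))
    }
  }

  superOg <- list()
  sog_path <- file.path(dir_path, "superog.tsv")
  if (file.exists(sog_path)) {
    slines <- readLines(sog_path)
    slines <- slines[!grepl("^#", slines) & nzchar(slines)]
    for (ln in slines) {
      p <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(p) != 3L) .okitStop(sprintf("malformed superog line: %s", ln))
      superOg[[p[1L]]] <- c(superOg[[p[1L]]], stats::setNames(p[3L], p[2L]))
    }
  }

  sequences <- list()
  fas <- list.files(dir_path, pattern = "\\.(fna|faa)$", full.names = TRUE)
  for (f in fas) {
    og <- sub("\\.(fna|faa)$", "", basename(f))
    sequences[[og]] <- .readFasta(f)
  }

  Scaffold(membership, name = name, method = method, sequences = sequences,
           annotation = annotation, superOg = superOg)
}

#' Write a scaffold to a directory
#'
#' Inverse of [readScaffold()]; writing then reading reproduces the scaffold
#' exactly, and a second write is byte-identical. Ids containing the tab
#' field delimiter are rejected rather than escaped.
#'
#' @param s a [Scaffold-class].
#' @param dir_path target directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
writeScaffold <- function(s, dir_path) {
  ok <- dir.exists(dir_path) || dir.create(dir_path, recursive = TRUE,
                                           showWarnings = FALSE)
  if (!ok || file.access(dir_path, 2L) != 0L) {
    .okitStop(sprintf("cannot write to directory: %s", dir_path))
  }
  m <- s@membership
  .checkNoTabs(c(m$gene_id, m$taxon, m$og_id), "scaffold identifiers")
  writeLines(paste(m$gene_id, m$taxon, m$og_id, sep = "\t"),
             file.path(dir_path, "membership.tsv"))
  if (length(s@annotation)) {
    rows <- character(0)
    for (og in names(s@annotation)) {
      ann <- s@annotation[[og]]
      rows <- c(rows, paste(og, names(ann), unname(ann), sep = "\t"))
    }
    writeLines(rows, file.path(dir_path, "annotation.tsv"))
  }
  if (length(s@superOg)) {
    rows <- character(0)
    for (og in names(s@superOg)) {
      sog <- s@superOg[[og]]
      rows <- c(rows, paste(og, names(sog), unname(sog), sep = "\t"))
    }
    writeLines(rows, file.path(dir_path, "superog.tsv"))
  }
  for (og in names(s@sequences)) {
    seqs <- s@sequences[[og]]
    ext <- if (.isNucleotide(seqs)) ".fna" else ".faa"
    .writeFasta(seqs, file.path(dir_path, paste0(og, ext)))
  }
  invisible(dir_path)
}
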