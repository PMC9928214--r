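# Classification of query coding sequences into scaffold orthogroups from
# similarity (12-column tabular) and profile (per-target table) search hits.

#' Parse a sequence-search hit table
#'
#' Two dialects are supported. `"similarity_tab12"` is the standard 12-column
#' tab-separated protein/nucleotide similarity format (query, target,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' tstart, tend, e-value, bit score). `"profile_tblout"` is the
#' whitespace-separated per-target table emitted by profile searches, with
#' `#` comment lines; the target is the profile name, and because the format
#' carries no percent identity the `identity_pct` field is set to 0.
#'
#' @param path file to parse.
#' @param dialect `"similarity_tab12"` or `"profile_tblout"`.
#' @return data.frame with columns `query_id`, `target_id`, `identity_pct`,
#'   `aln_len`, `e_value`, `bit_score`; one row per data line.
#' @export
parseHits <- function(path, dialect = c("similarity_tab12", "profile_tblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .okitStop(sprintf("hit file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(query_id = character(0), target_id = character(0),
                      identity_pct = numeric(0), aln_len = integer(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)

  num_or_die <- function(x, ln, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      .okitStop(sprintf("line %d: non-numeric %s field '%s'",
                        ln[bad[1L]], what, x[bad[1L]]))
    }
    v
  }

  if (dialect == "similarity_tab12") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 12L)
    if (length(bad)) {
      .okitStop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                        line_no[bad[1L]], lengths(parts)[bad[1L]]))
    }
    f <- function(i) vapply(parts, `[[`, "", i)
    data.frame(
      query_id = f(1L), target_id = f(2L),
      identity_pct = num_or_die(f(3L), line_no, "identity"),
      aln_len = as.integer(num_or_die(f(4L), line_no, "alignment length")),
      e_value = num_or_die(f(11L), line_no, "e-value"),
      bit_score = num_or_die(f(12L), line_no, "bit score"),
      stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- which(lengths(parts) < 6L)
    if (length(bad)) {
      .okitStop(sprintf("line %d: expected at least 6 whitespace-separated columns",
                        line_no[bad[1L]]))
    }
    f <- function(i) vapply(parts, `[[`, "", i)
    data.frame(
      query_id = f(3L), target_id = f(1L),
      identity_pct = 0,
      aln_len = 0L,
      e_value = num_or_die(f(5L), line_no, "e-value"),
      bit_score = num_or_die(f(6L), line_no, "score"),
      stringsAsFactors = FALSE)
  }
}

#' Assign queries to orthogroups by best passing hit
#'
#' Each query is assigned to the orthogroup of its best hit passing the
#' bit-score and e-value thresholds. "Best" is maximal bit score; ties go to
#' the smaller e-value, then to the lexicographically smallest orthogroup
#' id, so the result is fully deterministic and invariant under permutation
#' of the hit rows. Queries with no passing hit are reported as
#' unclassified.
#'
#' @param hits data.frame as returned by [parseHits()].
#' @param s the [Scaffold-class] classified against.
#' @param target_map named character vector mapping hit target ids to
#'   orthogroup ids. For profile hits the profile name typically *is* the
#'   orthogroup id; see [scaffoldTargetMap()] for similarity targets.
#' @param min_bits,max_e passing-hit thresholds (defaults 50 and 1e-5).
#' @param classifier provenance label stored on the assignments
#'   (`"similarity"` or `"profile"`).
#' @return A [ClassificationTable-class].
#' @export
assignOrthogroups <- function(hits, s, target_map, min_bits = 50,
                              max_e = 1e-5,
                              classifier = c("similarity", "profile")) {
  classifier <- match.arg(classifier)
  pass <- hits$bit_score >= min_bits & hits$e_value <= max_e
  h <- hits[pass, , drop = FALSE]
  queries <- unique(hits$query_id)
  if (nrow(h)) {
    unmapped <- setdiff(unique(h$target_id), names(target_map))
    if (length(unmapped)) {
      .okitStop(sprintf(
        "passing hit target(s) not mappable to an orthogroup: %s",
        paste(utils::head(unmapped, 5), collapse = ", ")))
    }
    h$og_id <- unname(target_map[h$target_id])
    ## deterministic best hit: bit score desc, e-value asc, og_id asc
    ord <- order(h$query_id, -h$bit_score, h$e_value, h$og_id,
                 method = "radix")
    h <- h[ord, , drop = FALSE]
    best <- h[!duplicated(h$query_id), , drop = FALSE]
    assignments <- data.frame(
      gene_id = best$query_id, og_id = best$og_id,
      classifier = classifier, score = best$bit_score,
      conflict = FALSE, similarity_og = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    assignments <- data.frame(
      gene_id = character(0), og_id = character(0),
      classifier = character(0), score = numeric(0),
      conflict = logical(0), similarity_og = character(0),
      stringsAsFactors = FALSE)
  }
  ord2 <- order(assignments$gene_id, method = "radix")
  assignments <- assignments[ord2, , drop = FALSE]
  rownames(assignments) <- NULL
  new("ClassificationTable",
      assignments = assignments,
      unclassified = sort(setdiff(queries, assignments$gene_id)),
      scaffold = s@name, metadata = list())
}

#' Map scaffold gene ids to their orthogroups
#'
#' Convenience for similarity searches against scaffold member sequences,
#' where hit targets are scaffold gene ids.
#'
#' @param s a [Scaffold-class].
#' @return named character vector, gene id to orthogroup id.
#' @export
scaffoldTargetMap <- function(s) {
  stats::setNames(s@membership$og_id, s@membership$gene_id)
}

#' Merge similarity- and profile-based classifications
#'
#' A gene classified by only one classifier keeps that assignment. When both
#' agree, the single record is labelled `both`. When they disagree, the
#' profile-based orthogroup is kept (profile searches are the more sensitive
#' classifier at long evolutionary distances), the record is flagged
#' `conflict = TRUE`, and the similarity candidate is preserved in the
#' `similarity_og` column for auditing.
#'
#' @param sim,prof [ClassificationTable-class] objects from the similarity
#'   and profile classifiers, over the same query set and scaffold.
#' @return A merged [ClassificationTable-class].
#' @export
mergeClassifications <- function(sim, prof) {
  if (!identical(sim@scaffold, prof@scaffold)) {
    .okitStop(sprintf("classifications reference different scaffolds: '%s' vs '%s'",
                      sim@scaffold, prof@scaffold))
  }
  a_sim <- sim@assignments
  a_prof <- prof@assignments
  both_ids <- intersect(a_sim$gene_id, a_prof$gene_id)
  sim_only <- a_sim[!a_sim$gene_id %in% both_ids, , drop = FALSE]
  prof_only <- a_prof[!a_prof$gene_id %in% both_ids, , drop = FALSE]

  if (length(both_ids)) {
    si <- a_sim[match(both_ids, a_sim$gene_id), , drop = FALSE]
    pi_ <- a_prof[match(both_ids, a_prof$gene_id), , drop = FALSE]
    agree <- si$og_id == pi_$og_id
    merged <- data.frame(
      gene_id = both_ids,
      og_id = pi_$og_id,
      classifier = "both",
      score = pmax(si$score, pi_$score),
      conflict = !agree,
      similarity_og = ifelse(agree, NA_character_, si$og_id),
      stringsAsFactors = FALSE)
  } else {
    merged <- a_sim[0, , drop = FALSE]
  }
  out <- rbind(sim_only, prof_only, merged)
  out <- out[order(out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  new("ClassificationTable",
      assignments = out,
      unclassified = sort(intersect(sim@unclassified, prof@unclassified)),
      scaffold = sim@scaffold,
      metadata = c(sim@metadata, prof@metadata[setdiff(names(prof@metadata),
                                                       names(sim@metadata))]))
}

#' Attach scaffold metadata to classified orthogroups
#'
#' Fills the table's metadata slot with, per assigned orthogroup, the
#' scaffold annotation text and the per-taxon gene counts.
#'
#' @param ct a [ClassificationTable-class].
#' @param s the [Scaffold-class] it was classified against.
#' @return `ct` with metadata attached.
#' @export
attachMetadata <- function(ct, s) {
  ogs <- unique(ct@assignments$og_id)
  meta <- lapply(ogs, function(og) {
    list(annotation = s@annotation[[og]],
         counts = if (og %in% rownames(s@counts)) s@counts[og, ] else NULL)
  })
  names(meta) <- ogs
  ct@metadata <- meta
  ct
}

#' Low-copy gene family selection rule
#'
#' @param max_copies_per_taxon maximum members any single taxon may have.
#' @param min_taxa_present minimum number of taxa with at least one member.
#' @param max_taxa_missing maximum number of taxa with zero members.
#' @return a `lowCopyRule` list.
#' @export
lowCopyRule <- function(max_copies_per_taxon = 1L, min_taxa_present = 1L,
                        max_taxa_missing = 0L) {
  stopifnot(max_copies_per_taxon >= 1L, min_taxa_present >= 1L,
            max_taxa_missing >= 0L)
  structure(list(max_copies_per_taxon = as.integer(max_copies_per_taxon),
                 min_taxa_present = as.integer(min_taxa_present),
                 max_taxa_missing = as.integer(max_taxa_missing)),
            class = "lowCopyRule")
}

#' Select single/low-copy orthogroups
#'
#' Returns the orthogroups commonly used for species-tree inference: those
#' where no scaffold taxon exceeds `max_copies_per_taxon` members, at least
#' `min_taxa_present` taxa have a member, and at most `max_taxa_missing`
#' taxa have none.
#'
#' @param s a [Scaffold-class].
#' @param rule a [lowCopyRule()].
#' @return character vector of orthogroup ids, in scaffold order.
#' @export
selectLowCopy <- function(s, rule = lowCopyRule()) {
  counts <- s@counts
  if (rule$min_taxa_present > ncol(counts)) {
    .okitStop(sprintf("rule requires %d taxa present but scaffold has %d taxa",
                      rule$min_taxa_present, ncol(counts)))
  }
  present <- rowSums(counts >= 1L)
  missing <- rowSums(counts == 0L)
  ok <- apply(counts, 1L, max) <= rule$max_copies_per_taxon &
    present >= rule$min_taxa_present &
    missing <= rule$max_taxa_missing
  rownames(counts)[ok]
}

setMethod("show", "ClassificationTable", function(object) {
  a <- object@assignments
  cat(sprintf("ClassificationTable vs scaffold '%s'\n", object@scaffold))
  cat(sprintf("  %d classified (%d conflicts), %d unclassified\n",
              nrow(a), sum(a$conflict), length(object@unclassified)))
  if (nrow(a)) {
    cat("  classifiers:",
        paste(sprintf("%s=%d", names(table(a$classifier)),
                      as.integer(table(a$classifier))), collapse = ", "), "\n")
  }
})

#' Write / read a classification table as TSV
#'
#' Columns: gene_id, og_id, classifier, score, conflict, similarity_og; the
#' unclassified queries are appended as comment lines `# unclassified:`.
#'
#' @param ct a [ClassificationTable-class].
#' @param path output file.
#' @return the path (write) or a [ClassificationTable-class] (read).
#' @export
writeClassification <- function(ct, path) {
  a <- ct@assignments
  header <- paste(c("gene_id", "og_id", "classifier", "score", "conflict",
                    "similarity_og"), collapse = "\t")
  rows <- paste(a$gene_id, a$og_id, a$classifier,
                format(a$score, trim = TRUE, scientific = FALSE),
                ifelse(a$conflict, "true", "false"),
                ifelse(is.na(a$similarity_og), ".", a$similarity_og),
                sep = "\t")
  footer <- if (length(ct@unclassified)) {
    paste0("# unclassified: ", paste(ct@unclassified, collapse = ","))
  } else character(0)
  meta <- paste0("# scaffold: ", ct@scaffold)
  writeLines(c(meta, header, rows, footer), path)
  invisible(path)
}

#' @rdname writeClassification
#' @export
readClassification <- function(path) {
  lines <- readLines(path)
  scaff <- sub("^# scaffold: ", "", grep("^# scaffold: ", lines, value = TRUE))
  if (!length(scaff)) scaff <- NA_character_
  uncl_line <- grep("^# unclassified: ", lines, value = TRUE)
  unclassified <- if (length(uncl_line)) {
    strsplit(sub("^# unclassified: ", "", uncl_line[1L]), ",", fixed = TRUE)[[1L]]
  } else character(0)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) > 1L) {
    parts <- strsplit(body[-1L], "\t", fixed = TRUE)
    a <- data.frame(
      gene_id = vapply(parts, `[[`, "", 1L),
      og_id = vapply(parts, `[[`, "", 2L),
      classifier = vapply(parts, `[[`, "", 3L),
      score = as.numeric(vapply(parts, `[[`, "", 4L)),
      conflict = vapply(parts, `[[`, "", 5L) == "true",
      similarity_og = ifelse(vapply(parts, `[[`, "", 6L) == ".",
                             NA_character_, vapply(parts, `[[`, "", 6L)),
      stringsAsFactors = FALSE)
  } else {
    a <- data.frame(gene_id = character(0), og_id = character(0),
                    classifier = character(0), score = numeric(0),
                    conflict = logical(0), similarity_og = character(0),
                    stringsAsFactors = FALSE)
  }
  new("ClassificationTable", assignments = a, unclassified = unclassified,
      scaffold = scaff[1L], metadata = list())
}
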