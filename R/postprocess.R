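# Transcript post-processing: ORF extraction, duplicate/subsequence removal,
# targeted greedy overlap-consensus meta-assembly, coverage filtering.

.FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Find open reading frames in a transcript
#'
#' Exhaustive six-frame ORF finder with the standard genetic code. Within
#' each reading frame the sequence is split into stop-free regions; each
#' region yields at most one *maximal* ORF: from its first ATG to the
#' terminating stop, or -- when `allow_partial` and the region is truncated
#' by a transcript end -- from the region boundary. The terminal stop codon,
#' when present, is included in the reported CDS (but never in the protein).
#'
#' Coordinates are 0-based half-open on the input transcript's forward
#' strand; a negative frame marks an ORF read off the reverse complement,
#' whose `cds` field is the coding (reverse-complement) strand sequence.
#'
#' A reported ORF always has an anchor: a start codon, a terminating stop,
#' or both. A stop-free, start-free run truncated at both transcript ends
#' is not a gene model and is never reported (so homopolymer runs yield
#' nothing even with `allow_partial`).
#'
#' @param seq nucleotide string.
#' @param id transcript id recorded in the output.
#' @param min_aa minimum protein length in residues (default 100).
#' @param allow_partial report ORFs truncated by transcript ends, flagged by
#'   `complete5`/`complete3` (has start codon / has stop codon).
#' @return data.frame with columns `transcript_id`, `frame`, `cds_start`,
#'   `cds_end`, `cds`, `protein`, `complete5`, `complete3`, sorted by protein
#'   length descending, ties by frame (+1,+2,+3,-1,-2,-3) then `cds_start`.
#' @examples
#' findOrfs("ATGAAATAG", min_aa = 2)
#' @export
findOrfs <- function(seq, id = "transcript", min_aa = 100L,
                     allow_partial = TRUE) {
  if (!.isNucleotide(seq)) {
    .okitStop(sprintf("'%s' is not a nucleotide sequence", id))
  }
  if (min_aa < 1L) .okitStop("min_aa must be >= 1")
  seq <- toupper(seq)
  L <- nchar(seq)
  gc <- .geneticCode()
  out <- list()

  for (strand in c(1L, -1L)) {
    strand_seq <- if (strand == 1L) seq else .revComp(seq)
    for (off in 0:2) {
      n_codons <- (L - off) %/% 3L
      if (n_codons < 1L) next
      starts <- off + seq(0L, by = 3L, length.out = n_codons) + 1L
      codons <- substring(strand_seq, starts, starts + 2L)
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      ## stop-free regions of consecutive codon indices
      grp <- cumsum(is_stop)
      for (g in unique(grp[!is_stop])) {
        idx <- which(grp == g & !is_stop)
        terminated <- (idx[length(idx)] < n_codons) # followed by a stop
        at_5p <- idx[1L] == 1L
        if (allow_partial && at_5p && terminated) {
          ## 5'-truncated but anchored by its stop codon
          start_codon <- idx[1L]
        } else {
          ## an ORF needs an anchor: a start codon, or the stop above --
          ## a doubly-partial run with neither is not a gene model
          m <- idx[aa[idx] == "M"]
          if (!length(m)) next
          start_codon <- m[1L]
        }
        prot_idx <- start_codon:idx[length(idx)]
        complete5 <- aa[start_codon] == "M"
        complete3 <- terminated
        if (!allow_partial && !(complete5 && complete3)) next
        if (length(prot_idx) < min_aa) next
        end_codon <- idx[length(idx)] + as.integer(terminated) # incl. stop
        s0 <- off + (start_codon - 1L) * 3L      # 0-based on this strand
        e0 <- off + end_codon * 3L
        if (strand == 1L) {
          cs <- s0; ce <- e0
        } else {
          cs <- L - e0; ce <- L - s0
        }
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id,
          frame = strand * (off + 1L),
          cds_start = cs, cds_end = ce,
          cds = substr(strand_seq, s0 + 1L, e0),
          protein = paste(aa[prot_idx], collapse = ""),
          complete5 = complete5, complete3 = complete3,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      cds_start = integer(0), cds_end = integer(0),
                      cds = character(0), protein = character(0),
                      complete5 = logical(0), complete3 = logical(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  ord <- order(-nchar(res$protein), match(res$frame, .FRAME_ORDER),
               res$cds_start)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pick the single best ORF of a transcript
#'
#' Longest protein wins; ties prefer the more complete model (start and stop
#' codon present beats partial), then the lowest `cds_start`.
#'
#' @param models data.frame from [findOrfs()] for one transcript.
#' @return single-row data.frame.
#' @export
bestOrf <- function(models) {
  if (is.null(models) || nrow(models) == 0L) {
    .okitStop("no ORF available", class = "okit_no_orf")
  }
  completeness <- as.integer(models$complete5) + as.integer(models$complete3)
  ord <- order(-nchar(models$protein), -completeness, models$cds_start)
  models[ord[1L], , drop = FALSE]
}

#' Remove duplicated and exact subsequences
#'
#' Filters a sequence set so that no kept sequence is an exact duplicate or
#' exact substring of another kept sequence. Among identical sequences the
#' one with the lexicographically smallest id is kept. The operation is
#' idempotent and partitions the input: `kept` plus `removed` is the input.
#'
#' @param seqs named character vector of sequences.
#' @return list with named character vectors `kept` and `removed`
#'   (input order preserved within each).
#' @export
dedupSequences <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    .okitStop("sequences must have unique names")
  }
  n <- length(seqs)
  if (n == 0L) return(list(kept = seqs, removed = seqs))
  ## longest first; identical sequences resolved by smallest id
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  kept_idx <- integer(0)
  for (i in ord) {
    contained <- FALSE
    for (j in kept_idx) {
      if (grepl(seqs[[i]], seqs[[j]], fixed = TRUE)) { contained <- TRUE; break }
    }
    if (!contained) kept_idx <- c(kept_idx, i)
  }
  kept_idx <- sort(kept_idx)
  list(kept = seqs[kept_idx], removed = seqs[setdiff(seq_len(n), kept_idx)])
}

## best merge candidate between ordered contigs a, b (character vectors of
## bases). Returns list(type, k, pos, identity) or NULL.
## type "overlap": suffix of a == prefix of b over k bases (Hamming identity
## >= min_id); type "contain": b inside a at 0-based pos, k = length(b).
.bestJoin <- function(a, b, min_overlap, min_identity) {
  la <- length(a); lb <- length(b)
  ## containment of b in a (full-length overlap)
  if (lb <= la && lb >= min_overlap) {
    best <- NULL
    a_str <- paste(a, collapse = ""); b_str <- paste(b, collapse = "")
    hit <- regexpr(b_str, a_str, fixed = TRUE)
    if (hit > 0L) {
      best <- list(type = "contain", k = lb, pos = as.integer(hit) - 1L,
                   identity = 1)
    } else if (min_identity < 1) {
      for (p in 0:(la - lb)) {
        idt <- sum(a[(p + 1L):(p + lb)] == b) / lb
        if (idt >= min_identity && (is.null(best) || idt > best$identity)) {
          best <- list(type = "contain", k = lb, pos = p, identity = idt)
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  ## longest admissible suffix(a)-prefix(b) overlap
  kmax <- min(la, lb)
  if (kmax >= min_overlap) {
    for (k in kmax:min_overlap) {
      idt <- sum(a[(la - k + 1L):la] == b[1:k]) / k
      if (idt >= min_identity) {
        return(list(type = "overlap", k = k, pos = la - k, identity = idt))
      }
    }
  }
  NULL
}

## majority consensus of two aligned base vectors; ties take the base of the
## contig whose id sorts first
.consensus2 <- function(x, y, x_wins) {
  disagree <- x != y
  if (any(disagree) && !x_wins) x[disagree] <- y[disagree]
  x
}

#' Greedy overlap-consensus meta-assembly of orthogroup contigs
#'
#' Merges overlapping contigs from a single orthogroup bucket in the style
#' of an overlap-layout-consensus assembler: repeatedly merge the ordered
#' pair with the longest suffix-prefix overlap of at least `min_overlap`
#' bases whose overlap identity (Hamming, exact-match seeded) is at least
#' `min_identity`. A contig contained in another counts as a full-length
#' overlap and is absorbed. Within an overlap the consensus base is the
#' majority; with two contigs every mismatch is a tie and the base of the
#' contig with the lexicographically earlier id wins. Ties in overlap length
#' are broken by the smallest (id, id) pair, so assembly is deterministic.
#'
#' @param seqs named character vector: contig id to nucleotide sequence.
#' @param min_overlap minimum overlap length in bases (default 40).
#' @param min_identity minimum overlap identity in (0, 1] (default 0.99).
#' @return data.frame with columns `id`, `seq` and list-column `sources`
#'   (input contig ids merged into each output contig); every input id
#'   appears in exactly one output's sources.
#' @export
metaAssemble <- function(seqs, min_overlap = 40L, min_identity = 0.99) {
  if (min_overlap < 1L) .okitStop("min_overlap must be >= 1")
  if (min_identity <= 0 || min_identity > 1) {
    .okitStop("min_identity must be in (0, 1]")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    .okitStop("contigs must have unique names")
  }
  items <- lapply(names(seqs), function(nm) {
    list(id = nm, chars = strsplit(toupper(seqs[[nm]]), "", fixed = TRUE)[[1L]],
         sources = nm)
  })

  repeat {
    if (length(items) < 2L) break
    best <- NULL
    for (i in seq_along(items)) {
      for (j in seq_along(items)) {
        if (i == j) next
        cand <- .bestJoin(items[[i]]$chars, items[[j]]$chars,
                          min_overlap, min_identity)
        if (is.null(cand)) next
        key <- c(items[[i]]$id, items[[j]]$id)
        if (is.null(best) || cand$k > best$cand$k ||
            (cand$k == best$cand$k &&
             (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          best <- list(i = i, j = j, cand = cand, key = key)
        }
      }
    }
    if (is.null(best)) break
    a <- items[[best$i]]; b <- items[[best$j]]
    a_wins <- a$id <= b$id
    cand <- best$cand
    if (cand$type == "contain") {
      region <- (cand$pos + 1L):(cand$pos + cand$k)
      merged_chars <- a$chars
      merged_chars[region] <- .consensus2(a$chars[region], b$chars, a_wins)
    } else {
      la <- length(a$chars)
      ov <- .consensus2(a$chars[(cand$pos + 1L):la], b$chars[1:cand$k], a_wins)
      merged_chars <- c(a$chars[seq_len(cand$pos)], ov,
                        b$chars[seq_len(length(b$chars) - cand$k) + cand$k])
    }
    merged <- list(id = min(a$id, b$id), chars = merged_chars,
                   sources = sort(c(a$sources, b$sources)))
    items <- c(items[-c(best$i, best$j)], list(merged))
  }

  data.frame(
    id = vapply(items, `[[`, "", "id"),
    seq = vapply(items, function(x) paste(x$chars, collapse = ""), ""),
    sources = I(lapply(items, `[[`, "sources")),
    stringsAsFactors = FALSE)
}

#' Remove alignment rows with low global coverage
#'
#' Drops every row whose non-gap fraction over all alignment columns is
#' below `min_cov`: the test that a targeted assembled transcript actually
#' spans its orthogroup's reference gene models. At `min_cov = 0` this is
#' the identity.
#'
#' @param aln an [OrthoAlignment-class].
#' @param min_cov minimum non-gap fraction in `[0, 1]` (default 0.3).
#' @return the filtered [OrthoAlignment-class].
#' @export
coverageFilter <- function(aln, min_cov = 0.3) {
  if (min_cov < 0 || min_cov > 1) .okitStop("min_cov must be in [0, 1]")
  m <- aln@mat
  if (nrow(m) == 0L || ncol(m) == 0L) .okitStop("empty alignment")
  cov <- rowMeans(m != "-")
  keep <- cov >= min_cov
  new("OrthoAlignment", mat = m[keep, , drop = FALSE],
      taxa = aln@taxa[intersect(names(aln@taxa), rownames(m)[keep])])
}
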