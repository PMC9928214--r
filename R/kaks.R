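# Pairwise Ka/Ks estimation by Nei-Gojobori (1986) codon counting with
# Jukes-Cantor correction, and paralog/ortholog pair detection from search
# hits. This is the built-in estimator; maximum-likelihood backends remain
# pluggable at the pipeline level.

## Per-codon synonymous site count: at each of the 3 positions, the fraction
## of the 3 single-base neighbors that are synonymous, with neighbors that
## are stop codons excluded from the denominator. N-sites = 3 - S-sites, so
## S + N = 3 per codon by construction.
.ng86Sites <- function() {
  tab <- .okit_env$ng86_sites
  if (!is.null(tab)) return(tab)
  gc <- .geneticCode()
  sense <- names(gc)[gc != "*"]
  tab <- stats::setNames(numeric(length(sense)), sense)
  for (codon in sense) {
    aa <- gc[[codon]]
    s <- 0
    for (pos in 1:3) {
      base <- substr(codon, pos, pos)
      syn <- 0L; valid <- 0L
      for (alt in setdiff(.BASES, base)) {
        nb <- codon
        substr(nb, pos, pos) <- alt
        if (gc[[nb]] == "*") next
        valid <- valid + 1L
        if (gc[[nb]] == aa) syn <- syn + 1L
      }
      if (valid > 0L) s <- s + syn / valid
    }
    tab[[codon]] <- s
  }
  .okit_env$ng86_sites <- tab
  tab
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

## average synonymous/nonsynonymous difference counts between two sense
## codons over all orderings of single-base steps; paths through stop codons
## are excluded entirely. NULL when every path is blocked.
.ng86Diffs <- function(ca, cb) {
  gc <- .geneticCode()
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  sd_tot <- 0; nd_tot <- 0; n_paths <- 0L
  for (order_ in .permutations(pos)) {
    cur <- ca; sd_ <- 0L; nd_ <- 0L; ok <- TRUE
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd_ <- sd_ + 1L else nd_ <- nd_ + 1L
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd_; nd_tot <- nd_tot + nd_; n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(NULL)
  c(sd = sd_tot / n_paths, nd = nd_tot / n_paths)
}

.jukesCantor <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -(3 / 4) * log(1 - (4 / 3) * p)
}

#' Nei-Gojobori (1986) Ka/Ks estimation for an aligned codon pair
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon from the
#' fractions of synonymous single-base neighbors (neighbors that are stop
#' codons are excluded from the denominator), averages site totals between
#' the two sequences, and counts synonymous/nonsynonymous differences,
#' averaging over all orderings of single-base steps for multi-difference
#' codons with equal weights; substitution paths passing through a stop
#' codon are excluded entirely. Proportions are corrected for multiple hits
#' with the Jukes-Cantor formula d = -(3/4) ln(1 - (4/3) p), reported as
#' `NA` (saturated) when p >= 3/4.
#'
#' Codon positions containing a gap, an ambiguity code, or a stop codon in
#' either sequence are skipped and do not count toward `codons_compared`;
#' the same applies to the (biologically marginal) case of a codon pair
#' whose every substitution path is blocked by stop codons.
#'
#' @param cds_a,cds_b aligned coding sequences: equal length, divisible
#'   by 3.
#' @return one-row data.frame with `codons_compared`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio` (Ka/Ks; `NA` when Ks is 0 or
#'   undefined). The function is symmetric in its arguments, and
#'   `S + N == 3 * codons_compared` exactly.
#' @examples
#' ng86("ATG", "ATA")  # Nd = 1, mean N = 8/3, Ka = -(3/4) log(1/2)
#' @export
ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    .okitStop("aligned CDS pair must have equal lengths")
  }
  if (nchar(cds_a) %% 3L != 0L) {
    .okitStop("aligned CDS length must be divisible by 3")
  }
  ca <- .splitCodons(cds_a); cb <- .splitCodons(cds_b)
  sites <- .ng86Sites()
  gc <- .geneticCode()
  S_a <- 0; S_b <- 0; Sd <- 0; Nd <- 0; compared <- 0L
  for (i in seq_along(ca)) {
    x <- ca[[i]]; y <- cb[[i]]
    if (grepl("[^ACGT]", x) || grepl("[^ACGT]", y)) next
    if (gc[[x]] == "*" || gc[[y]] == "*") next
    diffs <- .ng86Diffs(x, y)
    if (is.null(diffs)) next
    compared <- compared + 1L
    S_a <- S_a + sites[[x]]; S_b <- S_b + sites[[y]]
    Sd <- Sd + diffs[["sd"]]; Nd <- Nd + diffs[["nd"]]
  }
  S <- (S_a + S_b) / 2
  N <- 3 * compared - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- .jukesCantor(pS)
  Ka <- .jukesCantor(pN)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  data.frame(codons_compared = compared, S = S, N = N, Sd = Sd, Nd = Nd,
             pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio)
}

#' Detect paralog or ortholog gene pairs from search hits
#'
#' Paralog mode works on a self-search: each gene contributes its best
#' non-self same-species hit with alignment length at least `min_aln`, and
#' the union of these directed choices is deduplicated as unordered pairs.
#' Ortholog mode works on a two-species search and returns reciprocal best
#' hits between the species. "Best" is maximal bit score, ties by smaller
#' e-value then lexicographic target id.
#'
#' @param hits data.frame as from [parseHits()].
#' @param species_of named character vector, gene id to species.
#' @param mode `"paralog"` or `"ortholog"`.
#' @param min_aln minimum alignment length (default 0).
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`) and
#'   `kind`.
#' @export
detectPairs <- function(hits, species_of, mode = c("paralog", "ortholog"),
                        min_aln = 0L) {
  mode <- match.arg(mode)
  h <- hits[hits$query_id != hits$target_id & hits$aln_len >= min_aln, ,
            drop = FALSE]
  unknown <- setdiff(unique(c(h$query_id, h$target_id)), names(species_of))
  if (length(unknown)) {
    .okitStop(sprintf("gene(s) without species: %s",
                      paste(utils::head(unknown, 5), collapse = ", ")))
  }
  best_per_query <- function(hh) {
    if (!nrow(hh)) return(hh)
    ord <- order(hh$query_id, -hh$bit_score, hh$e_value, hh$target_id,
                 method = "radix")
    hh <- hh[ord, , drop = FALSE]
    hh[!duplicated(hh$query_id), , drop = FALSE]
  }
  if (mode == "paralog") {
    same <- species_of[h$query_id] == species_of[h$target_id]
    best <- best_per_query(h[same, , drop = FALSE])
    if (!nrow(best)) {
      return(data.frame(id_a = character(0), id_b = character(0),
                        kind = character(0), stringsAsFactors = FALSE))
    }
    a <- pmin(best$query_id, best$target_id)
    b <- pmax(best$query_id, best$target_id)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    out <- data.frame(id_a = a[keep], id_b = b[keep], kind = "paralog",
                      stringsAsFactors = FALSE)
  } else {
    sp <- unique(species_of[unique(c(h$query_id, h$target_id))])
    if (length(sp) != 2L) {
      .okitStop(sprintf(
        "ortholog mode requires exactly 2 species in the hits, found %d",
        length(sp)))
    }
    cross <- species_of[h$query_id] != species_of[h$target_id]
    best <- best_per_query(h[cross, , drop = FALSE])
    choice <- stats::setNames(best$target_id, best$query_id)
    recip <- names(choice)[!is.na(choice[choice]) &
                             choice[choice] == names(choice)]
    a <- pmin(recip, choice[recip]); b <- pmax(recip, choice[recip])
    keep <- !duplicated(paste(a, b, sep = "\r"))
    out <- data.frame(id_a = unname(a[keep]), id_b = unname(b[keep]),
                      kind = "ortholog", stringsAsFactors = FALSE)
  }
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ka/Ks table for a list of gene pairs
#'
#' Runs [ng86()] on each pair's (pre-aligned, equal-length) coding
#' sequences.
#'
#' @param pairs data.frame from [detectPairs()].
#' @param cds named character vector of coding sequences.
#' @return data.frame: `id_a`, `id_b`, `kind`, `codons_compared`, `Ka`,
#'   `Ks`, `ratio`.
#' @export
kaksTable <- function(pairs, cds) {
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(cds))
  if (length(missing)) {
    .okitStop(sprintf("pair gene(s) without CDS: %s",
                      paste(utils::head(missing, 5), collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- ng86(cds[[pairs$id_a[i]]], cds[[pairs$id_b[i]]])
    cbind(pairs[i, c("id_a", "id_b", "kind")],
          est[, c("codons_compared", "Ka", "Ks", "ratio")])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id_a = character(0), id_b = character(0), kind = character(0),
               codons_compared = integer(0), Ka = numeric(0), Ks = numeric(0),
               ratio = numeric(0))
  rownames(out) <- NULL
  out
}
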