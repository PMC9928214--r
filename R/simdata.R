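# Seeded synthetic-data generators: gene-family scaffolds with substitution
# and gene birth/death, fragmented transcripts with planted overlaps, Ks
# draws from planted mixture components, and generative classification hits.
# Every module of the package is testable from these with no download and
# no external program.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Synthetic-data configuration
#'
#' Defaults describe the study conditions the package's own benchmarks run
#' under: a 5-taxon, 50-orthogroup scaffold with 100-codon genes, moderate
#' per-site divergence, light gene birth/death, 3-fragment transcript
#' shredding with planted overlaps well above the assembler's minimum, and
#' a two-component Ks mixture (weights 0.6/0.4, means 0.2/1.5, sigmas
#' 0.05/0.3) emulating a background small-scale-duplication peak plus an
#' older whole-genome-duplication peak.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param n_taxa,n_orthogroups scaffold dimensions.
#' @param birth_rate expected extra gene copies per taxon per orthogroup
#'   (Poisson); `0` disables duplication.
#' @param death_rate probability a taxon lost an orthogroup entirely.
#' @param sub_rate per-site substitution probability per taxon copy.
#' @param gene_len_codons coding length excluding the stop codon (>= 10).
#' @param fragmentation list `n_fragments`, `min_frac`, `overlap_frac`.
#' @param ks_components data.frame with columns `weight`, `mean`, `sigma`.
#' @return a `simConfig` list.
#' @export
simConfig <- function(seed = 1L, n_taxa = 5L, n_orthogroups = 50L,
                      birth_rate = 0.1, death_rate = 0.1, sub_rate = 0.05,
                      gene_len_codons = 100L,
                      fragmentation = list(n_fragments = 3L, min_frac = 0.4,
                                           overlap_frac = 0.2),
                      ks_components = data.frame(
                        weight = c(0.6, 0.4), mean = c(0.2, 1.5),
                        sigma = c(0.05, 0.3))) {
  stopifnot(gene_len_codons >= 10L,
            birth_rate >= 0, death_rate >= 0, death_rate <= 1,
            sub_rate >= 0, sub_rate <= 1)
  if (abs(sum(ks_components$weight) - 1) > 1e-9) {
    .okitStop("ks component weights must sum to 1")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 n_orthogroups = as.integer(n_orthogroups),
                 birth_rate = birth_rate, death_rate = death_rate,
                 sub_rate = sub_rate,
                 gene_len_codons = as.integer(gene_len_codons),
                 fragmentation = fragmentation,
                 ks_components = ks_components),
            class = "simConfig")
}

.senseCodons <- function() {
  gc <- .geneticCode()
  names(gc)[gc != "*"]
}

## mutate one codon: each position substituted with prob `rate`, uniform
## over the 3 alternative bases; draws creating a stop codon are redrawn so
## simulated CDSs stay open
.mutateCodon <- function(codon, rate) {
  gc <- .geneticCode()
  repeat {
    bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(3L) < rate
    if (!any(hit)) return(codon)
    for (p in which(hit)) {
      bases[p] <- sample(setdiff(.BASES, bases[p]), 1L)
    }
    out <- paste(bases, collapse = "")
    if (gc[[out]] != "*") return(out)
  }
}

#' Simulate a gene-family scaffold with known truth
#'
#' Per orthogroup a random root CDS (ATG start, no internal stop, one
#' terminal stop codon) is evolved independently into each taxon's copies:
#' copy number is 0 with probability `death_rate`, otherwise 1 plus a
#' Poisson(`birth_rate`) number of duplicates, and every copy mutates each
#' site with probability `sub_rate` (uniform over alternative bases; codons
#' mutating to stops are redrawn). Output is byte-identical for a fixed
#' seed.
#'
#' @param cfg a [simConfig()].
#' @return list: `scaffold` (a [Scaffold-class] carrying the member
#'   sequences), `sequences` (flat named character vector of all gene
#'   CDSs), `truth` (the full membership data.frame).
#' @export
simulateScaffold <- function(cfg) {
  .withSeed(cfg$seed, {
    sense <- .senseCodons()
    taxa <- sprintf("tax%d", seq_len(cfg$n_taxa))
    ogs <- sprintf("og%03d", seq_len(cfg$n_orthogroups))
    mem <- list(); seq_list <- list(); flat <- character(0)
    for (og in ogs) {
      root <- paste(c("ATG",
                      sample(sense, cfg$gene_len_codons - 1L, replace = TRUE),
                      sample(.STOP_CODONS, 1L)), collapse = "")
      root_codons <- .splitCodons(root)
      og_seqs <- character(0)
      for (tx in taxa) {
        n_copies <- if (stats::runif(1L) < cfg$death_rate) 0L else
          1L + stats::rpois(1L, cfg$birth_rate)
        for (cp in seq_len(n_copies)) {
          ## start and stop codons are conserved; only internal sites evolve
          n_cod <- length(root_codons)
          codons <- c(root_codons[1L],
                      vapply(root_codons[-c(1L, n_cod)], .mutateCodon, "",
                             rate = cfg$sub_rate),
                      root_codons[n_cod])
          gid <- sprintf("%s_%s_c%d", og, tx, cp)
          og_seqs[gid] <- paste(codons, collapse = "")
          mem[[length(mem) + 1L]] <- data.frame(
            gene_id = gid, taxon = tx, og_id = og, stringsAsFactors = FALSE)
        }
      }
      seq_list[[og]] <- og_seqs
      flat <- c(flat, og_seqs)
    }
    membership <- do.call(rbind, mem)
    s <- Scaffold(membership, name = sprintf("sim-seed%d", cfg$seed),
                  method = "simulated", sequences = seq_list)
    list(scaffold = s, sequences = flat, truth = membership)
  })
}

#' Shred genes into overlapping transcript fragments
#'
#' Each gene yields `n_fragments` exact substrings (no error injection)
#' covering the full gene, each at least `min_frac` of the gene length,
#' with consecutive fragments overlapping by at least `overlap_frac` of the
#' gene length -- the regime in which targeted meta-assembly can restore
#' full-length models from a fragmented assembly.
#'
#' @param genes named character vector of full-length gene sequences.
#' @param cfg a [simConfig()] (uses `fragmentation` and `seed`).
#' @param min_overlap assembler minimum overlap used only to warn when the
#'   planted overlaps would be too short to reassemble (default 40).
#' @return named character vector of fragments (`<gene>_f<i>`).
#' @export
fragmentTranscripts <- function(genes, cfg, min_overlap = 40L) {
  fr <- cfg$fragmentation
  n <- as.integer(fr$n_fragments)
  stopifnot(n >= 1L, fr$min_frac > 0, fr$min_frac <= 1,
            fr$overlap_frac >= 0, fr$overlap_frac < 1)
  .withSeed(cfg$seed + 1L, {
    out <- character(0)
    for (g in names(genes)) {
      L <- nchar(genes[[g]])
      if (n == 1L) {
        out[sprintf("%s_f1", g)] <- genes[[g]]
        next
      }
      o <- ceiling(fr$overlap_frac * L)
      if (o < min_overlap) {
        warning(sprintf(
          "gene '%s': planted overlap %d nt is below the assembler minimum %d",
          g, o, min_overlap))
      }
      ell <- max(ceiling(fr$min_frac * L), ceiling((L + (n - 1L) * o) / n))
      ell <- min(ell, L)
      starts <- round(seq(0L, L - ell, length.out = n))
      for (i in seq_len(n)) {
        out[sprintf("%s_f%d", g, i)] <-
          substr(genes[[g]], starts[i] + 1L, starts[i] + ell)
      }
    }
    out
  })
}

#' Draw Ks values from the planted mixture
#'
#' @param cfg a [simConfig()] (uses `ks_components` and `seed`).
#' @param n number of draws (>= 1).
#' @return numeric vector of n non-negative Ks values; negative draws are
#'   resampled (truncation at 0).
#' @export
sampleKs <- function(cfg, n) {
  if (n < 1L) .okitStop("n must be >= 1")
  comp <- cfg$ks_components
  .withSeed(cfg$seed + 2L, {
    idx <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    x <- stats::rnorm(n, comp$mean[idx], comp$sigma[idx])
    while (any(x < 0)) {
      bad <- which(x < 0)
      x[bad] <- stats::rnorm(length(bad), comp$mean[idx[bad]],
                             comp$sigma[idx[bad]])
    }
    x
  })
}

## majority consensus of an orthogroup's (equal-length) member sequences;
## ties take the alphabetically first base
.ogConsensus <- function(seqs) {
  if (length(seqs) == 1L) return(unname(seqs[[1L]]))
  lens <- nchar(seqs)
  width <- min(lens)
  mat <- matrix("", nrow = length(seqs), ncol = width)
  for (i in seq_along(seqs)) {
    mat[i, ] <- strsplit(substr(seqs[[i]], 1L, width), "", fixed = TRUE)[[1L]]
  }
  apply(mat, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    cands <- names(tab)[tab == tab[1L]]
    sort(cands)[1L]
  }) |> paste(collapse = "")
}

## identity map for consensus-based targets: hit target ids are og ids
.consensusTargetMap <- function(s) {
  ogs <- orthogroupIds(s)
  stats::setNames(ogs, ogs)
}

#' Generate classification hits from scaffold consensus identity
#'
#' Stand-in for an external similarity search in tests and fixtures: each
#' query is compared position-wise to every orthogroup's majority-consensus
#' sequence, and hits are emitted with bit score proportional to identity
#' (and e-value decaying exponentially in it). Because each simulated gene
#' is a lightly mutated copy of its own orthogroup's root, the generative
#' truth is the argmax of this score, which is what makes noiseless
#' recovery an exact oracle for the classifier.
#'
#' @param queries named character vector of query sequences.
#' @param s a [Scaffold-class] with member sequences.
#' @param min_identity identity below which no hit row is emitted
#'   (default 0.4, keeping tables small).
#' @param seed unused randomness guard kept for interface stability; hit
#'   generation is deterministic.
#' @return data.frame in the parsed-hit layout of [parseHits()], with
#'   `target_id` equal to the orthogroup id (see `.consensusTargetMap`).
#' @export
simulateHits <- function(queries, s, min_identity = 0.4, seed = 1L) {
  cons <- lapply(s@sequences[lengths(s@sequences) > 0L], .ogConsensus)
  cons_chars <- lapply(cons, function(x) strsplit(x, "", fixed = TRUE)[[1L]])
  rows <- list()
  for (q in names(queries)) {
    qs <- strsplit(queries[[q]], "", fixed = TRUE)[[1L]]
    for (og in names(cons)) {
      cs <- cons_chars[[og]]
      w <- min(length(qs), length(cs))
      idt <- sum(qs[seq_len(w)] == cs[seq_len(w)]) / max(length(qs), length(cs))
      if (idt < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q, target_id = og,
        identity_pct = round(100 * idt, 2),
        aln_len = w,
        e_value = 10^(-50 * idt),
        bit_score = round(500 * idt, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), target_id = character(0),
                      identity_pct = numeric(0), aln_len = integer(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write hits in the 12-column similarity dialect
#'
#' Emits parsed-layout hits back to the standard 12-column tab-separated
#' format (placeholder zeros for the coordinate fields the layout does not
#' carry), so pipeline fixtures can exercise [parseHits()].
#'
#' @param hits data.frame in the [parseHits()] layout.
#' @param path output file.
#' @export
writeHitsTable <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.2f\t%d\t0\t0\t0\t0\t0\t0\t%g\t%.1f",
                   hits$query_id, hits$target_id, hits$identity_pct,
                   as.integer(hits$aln_len), hits$e_value, hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}
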