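# Independent brute-force oracles. These deliberately re-derive results
# from first principles (explicit neighbor enumeration, regex scans,
# exhaustive path sums) rather than calling package internals, so each
# checked operation has a second, independent route to the same answer.

.oracle_gc <- as.list(as.character(Biostrings::GENETIC_CODE))
names(.oracle_gc) <- names(Biostrings::GENETIC_CODE)
.oracle_bases <- c("A", "C", "G", "T")

oracle_is_stop <- function(codon) identical(.oracle_gc[[codon]], "*")

## NG86 synonymous site count of one codon from its single-base neighbors
oracle_syn_sites <- function(codon) {
  total <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    nbs <- vapply(setdiff(.oracle_bases, ref), function(alt) {
      x <- codon; substr(x, p, p) <- alt; x
    }, character(1))
    nbs <- nbs[!vapply(nbs, oracle_is_stop, logical(1))]
    if (length(nbs)) {
      syn <- vapply(nbs, function(x) {
        identical(.oracle_gc[[x]], .oracle_gc[[codon]])
      }, logical(1))
      total <- total + mean(syn)
    }
  }
  total
}

## all orderings of a set, as a list (recursive enumeration)
oracle_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(oracle_orderings(v[-i]), function(rest) c(v[i], rest))
  }))
}

## NG86 difference counts between two codons: enumerate every substitution
## path, drop paths visiting a stop codon, average the rest
oracle_codon_diffs <- function(ca, cb) {
  pos <- which(charToRaw(ca) != charToRaw(cb))
  if (!length(pos)) return(list(sd = 0, nd = 0, n_paths = 1L))
  acc_s <- c(); acc_n <- c()
  for (ord in oracle_orderings(pos)) {
    cur <- ca; s <- 0L; n <- 0L; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(cb, p, p)
      if (oracle_is_stop(nxt)) { blocked <- TRUE; break }
      if (identical(.oracle_gc[[nxt]], .oracle_gc[[cur]])) s <- s + 1L
      else n <- n + 1L
      cur <- nxt
    }
    if (!blocked) { acc_s <- c(acc_s, s); acc_n <- c(acc_n, n) }
  }
  if (!length(acc_s)) return(NULL)
  list(sd = mean(acc_s), nd = mean(acc_n), n_paths = length(acc_s))
}

## full NG86 counts for an aligned pair
oracle_ng86 <- function(a, b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(toupper(a)); cb <- split3(toupper(b))
  Sa <- 0; Sb <- 0; Sd <- 0; Nd <- 0; compared <- 0L
  for (i in seq_along(ca)) {
    x <- ca[i]; y <- cb[i]
    if (grepl("[^ACGT]", x) || grepl("[^ACGT]", y)) next
    if (oracle_is_stop(x) || oracle_is_stop(y)) next
    d <- oracle_codon_diffs(x, y)
    if (is.null(d)) next
    compared <- compared + 1L
    Sa <- Sa + oracle_syn_sites(x)
    Sb <- Sb + oracle_syn_sites(y)
    Sd <- Sd + d$sd; Nd <- Nd + d$nd
  }
  S <- (Sa + Sb) / 2
  list(codons_compared = compared, S = S, N = 3 * compared - S,
       Sd = Sd, Nd = Nd)
}

## regex-driven six-frame ORF oracle: translate each frame, split on stops,
## pick the maximal ORF per stop-free region per the reporting rule
oracle_orfs <- function(seq, min_aa, allow_partial) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
  }
  res <- list()
  for (strand in c(1L, -1L)) {
    ss <- if (strand == 1L) seq else rc(seq)
    for (off in 0:2) {
      nc <- (L - off) %/% 3
      if (nc < 1) next
      codons <- substring(ss, off + 3 * (seq_len(nc) - 1) + 1,
                          off + 3 * seq_len(nc))
      aa <- vapply(codons, function(x) {
        v <- .oracle_gc[[x]]; if (is.null(v)) "X" else v
      }, character(1), USE.NAMES = FALSE)
      aa_str <- paste(aa, collapse = "")
      ## stop-free regions via regex over the protein string
      m <- gregexpr("[^*]+", aa_str)[[1L]]
      if (m[1L] == -1L) next
      for (r in seq_along(m)) {
        r0 <- m[r]; rl <- attr(m, "match.length")[r]
        region <- substr(aa_str, r0, r0 + rl - 1)
        terminated <- (r0 + rl - 1) < nc
        if (allow_partial && r0 == 1L && terminated) {
          start_in_region <- 1L
        } else {
          start_in_region <- regexpr("M", region, fixed = TRUE)
          if (start_in_region == -1L) next
        }
        prot <- substr(region, start_in_region, rl)
        c5 <- substr(prot, 1, 1) == "M"
        if (!allow_partial && !(c5 && terminated)) next
        if (nchar(prot) < min_aa) next
        start_codon <- r0 + start_in_region - 1L
        end_codon <- r0 + rl - 1L + as.integer(terminated)
        s0 <- off + (start_codon - 1L) * 3L
        e0 <- off + end_codon * 3L
        coords <- if (strand == 1L) c(s0, e0) else c(L - e0, L - s0)
        res[[length(res) + 1L]] <- data.frame(
          frame = strand * (off + 1L), cds_start = coords[1L],
          cds_end = coords[2L], protein = prot,
          complete5 = c5, complete3 = terminated)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(frame = integer(0), cds_start = integer(0),
                      cds_end = integer(0), protein = character(0),
                      complete5 = logical(0), complete3 = logical(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$frame, out$cds_start), , drop = FALSE]
}

## random coding sequence without internal stops, 'ATG' start, one stop
random_cds <- function(n_codons) {
  sense <- names(.oracle_gc)[!vapply(names(.oracle_gc), oracle_is_stop,
                                     logical(1))]
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

## random additive tree + its exact path-length matrix
random_additive_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, br = function(k) stats::runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
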