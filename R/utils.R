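# Internal helpers shared across modules.

.okit_env <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
.geneticCode <- function() {
  gc <- .okit_env$genetic_code
  if (is.null(gc)) {
    gc <- as.character(Biostrings::GENETIC_CODE)
    names(gc) <- names(Biostrings::GENETIC_CODE)
    .okit_env$genetic_code <- gc
  }
  gc
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

## structured conditions so the CLI can map failures to exit codes
.okitStop <- function(msg, class = "okit_input_error", call. = FALSE) {
  stop(structure(
    class = c(class, "okit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

.isNucleotide <- function(x) {
  all(grepl("^[ACGTUNacgtun]*$", x))
}

.splitCodons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) {
    .okitStop(sprintf("sequence length %d is not a multiple of 3", n))
  }
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

## translate a CDS string with the standard code; stop codons become '*',
## codons with ambiguity become 'X'
.translateCds <- function(x, drop_trailing_stop = FALSE) {
  codons <- .splitCodons(toupper(x))
  gc <- .geneticCode()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  if (drop_trailing_stop && length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  paste(aa, collapse = "")
}

.revComp <- function(x) {
  x <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## named character vector -> FASTA on disk
#' @importFrom Biostrings BStringSet writeXStringSet readBStringSet
.writeFasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

.readFasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

## tab-containing fields would corrupt the TSV interchange format; reject
.checkNoTabs <- function(x, what) {
  bad <- x[grepl("\t", x, fixed = TRUE)]
  if (length(bad)) {
    .okitStop(sprintf("%s may not contain tab characters: %s",
                      what, paste(unique(bad), collapse = ", ")))
  }
  invisible(x)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "", ...)
}
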