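#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, either case).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    if (!nzchar(s) || is.na(s)) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# PHRED+33 string -> integer vector
phred_to_int <- function(q) {
  if (is.na(q) || !nzchar(q)) return(integer(0))
  as.integer(charToRaw(q)) - 33L
}

# integer vector -> PHRED+33 string
int_to_phred <- function(q) {
  if (length(q) == 0) return("")
  rawToChar(as.raw(as.integer(q) + 33L))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic TSV writer (fixed eol, no quoting, no row names)
write_tsv_plain <- function(df, path) {
  write.table(df, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
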