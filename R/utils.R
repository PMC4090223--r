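#' Reverse complement of DNA/RNA sequences
#'
#' Vectorised reverse complement. The output alphabet follows the input: a
#' sequence containing U (RNA) is complemented in RNA space, otherwise DNA.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
#' revcomp("ACGU")
revcomp <- function(x) {
  vapply(x, function(s) {
    rna <- grepl("U", s, fixed = TRUE)
    comp <- chartr("ACGTU", "TGCAA", s)
    if (rna) comp <- chartr("T", "U", comp)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA and RNA alphabets
#' @param x character vector.
#' @return character vector with T replaced by U (`as_rna`) or U by T
#'   (`as_dna`).
#' @export
as_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", x)

#' GC fraction of sequences
#' @param x character vector of DNA/RNA sequences.
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n == 0, NA_real_, gc / n)
}

# encode RNA/DNA string to integer code A=0 C=1 G=2 U/T=3 (0-based, for C++)
encode_seq <- function(x) {
  s <- toupper(as_rna(x))
  if (grepl("[^ACGU]", s)) {
    bad <- which(strsplit(s, "")[[1]] %in% c("A", "C", "G", "U") == FALSE)
    abort(sprintf("invalid characters at positions %s in sequence",
                  paste(head(bad, 5), collapse = ", ")))
  }
  match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "U")) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
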