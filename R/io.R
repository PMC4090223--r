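#' Read and write sequence files
#'
#' Thin tibble-first wrappers around Biostrings for the pipeline's external
#' formats: FASTA for genomes/catalogs/UTRs, FASTQ for raw reads (dummy
#' qualities accepted), BED6 for annotation intervals with the class encoded
#' in the name column (`class|name`).
#'
#' @param path file path.
#' @return `read_fasta()`: tibble with `id`, `sequence`. `read_fastq()`:
#'   tibble with `library`, `read_id`, `sequence`, `quality`. `read_bed()`:
#'   tibble with `chrom`, `start`, `end`, `class`, `name`, `strand`.
#' @name io
NULL

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' @rdname io
#' @param df data frame with `id` and `sequence` columns.
#' @export
write_fasta <- function(df, path) {
  x <- Biostrings::DNAStringSet(setNames(df$sequence, df$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @param library library identifier attached to every read.
#' @export
read_fastq <- function(path, library) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(library = library,
         read_id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' @rdname io
#' @param reads tibble with `read_id`, `sequence`, `quality` (one library).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(b)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  parts <- strsplit(b$name, "|", fixed = TRUE)
  tibble(chrom = b$chrom, start = as.integer(b$start),
         end = as.integer(b$end),
         class = vapply(parts, `[`, character(1), 1),
         name = vapply(parts, function(p) p[length(p)], character(1)),
         strand = b$strand)
}

#' @rdname io
#' @param annotations tibble with `chrom`, `start`, `end`, `class`, `name`,
#'   `strand`.
#' @export
write_bed <- function(annotations, path) {
  out <- annotations |>
    transmute(.data$chrom, .data$start, .data$end,
              name = paste(.data$class, .data$name, sep = "|"),
              score = 0L, .data$strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv_ <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df <- df[, !list_cols, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to disk in standard formats
#'
#' Serializes a [synthetic_study()] as the pipeline's external interfaces:
#' `genome.fa`, `annots.bed` (class encoded in the name column),
#' `catalog_mature.fa` / `catalog_precursor.fa` (known miRNAs only — spiked
#' novel hairpins stay hidden in the truth table), `reads_<lib>.fq` and
#' `truth.tsv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- study$genome
  write_fasta(tibble(id = names(g$genome), sequence = unname(g$genome)),
              file.path(dir, "genome.fa"))
  write_bed(g$annotations, file.path(dir, "annots.bed"))
  known <- study$catalog |> filter(.data$type == "known")
  write_fasta(known |> transmute(id = .data$id, sequence = .data$mature),
              file.path(dir, "catalog_mature.fa"))
  write_fasta(known |> transmute(id = .data$id, sequence = .data$precursor),
              file.path(dir, "catalog_precursor.fa"))
  for (l in study$config$libraries) {
    rd <- study$reads$reads |> filter(.data$library == l)
    write_fastq(rd, file.path(dir, sprintf("reads_%s.fq", l)))
  }
  write_tsv_(study$reads$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
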