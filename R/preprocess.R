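#' Trim the 3' adapter from raw reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' at most one mismatch and an overlap of at least 6 nt. Reads with no
#' detectable adapter overlap are rejected (the insert may have run past the
#' read end, so its length cannot be confirmed), as are reads whose insert
#' is empty after trimming.
#'
#' @param reads character vector of raw read sequences.
#' @param adapter 3' adapter sequence (>= 6 nt).
#' @param min_overlap minimum read/adapter overlap (default 6).
#' @param max_mismatch maximum mismatches tolerated in the overlap.
#' @return a tibble with columns `read`, `insert` (NA when rejected) and
#'   `status` (`trimmed`, `no_adapter`, `empty_insert`, `empty_read`).
#' @export
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACGTTGGAATTC", "TGGAATTCTCGG")
trim_adapter <- function(reads, adapter, min_overlap = 6L, max_mismatch = 1L) {
  if (nchar(adapter) < 6) abort("adapter must be at least 6 nt")
  adapter <- toupper(adapter)
  reads <- toupper(reads)
  n <- nchar(reads)
  alen <- nchar(adapter)
  insert <- rep(NA_character_, length(reads))
  status <- rep("no_adapter", length(reads))
  status[n == 0] <- "empty_read"

  # fast path: the full adapter (or the read-limited prefix) matches exactly
  o_full <- pmin(alen, n)
  hit <- n > 0 &
    substr(reads, n - o_full + 1L, n) == substr(adapter, 1L, o_full) &
    o_full >= min_overlap
  insert[hit] <- substr(reads[hit], 1L, (n - o_full)[hit])
  status[hit] <- "trimmed"

  # slow path: scan overlaps longest-first with a mismatch budget
  todo <- which(!hit & n >= min_overlap)
  for (i in todo) {
    r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    a <- strsplit(adapter, "", fixed = TRUE)[[1]]
    for (o in seq(min(alen, n[i]), min_overlap)) {
      mm <- sum(r[(n[i] - o + 1L):n[i]] != a[1:o])
      if (mm <= max_mismatch) {
        insert[i] <- substr(reads[i], 1L, n[i] - o)
        status[i] <- "trimmed"
        break
      }
    }
  }
  empty <- status == "trimmed" & !nzchar(insert)
  insert[empty] <- NA_character_
  status[empty] <- "empty_insert"
  tibble(read = reads, insert = insert, status = status)
}

#' Clean raw reads: adapter removal, length and quality filters
#'
#' The full read-cleaning stage for one or two libraries: trims the 3'
#' adapter ([trim_adapter()]), then keeps inserts of 18-30 nt containing no
#' N bases. When quality strings are present, reads with more than 20% of
#' bases under Phred 10 are rejected as low quality. Every raw read is
#' accounted for: raw = clean + rejected, by rejection reason.
#'
#' @param reads a data frame with columns `library`, `sequence` and
#'   optionally `read_id`, `quality` (Phred+33), as produced by
#'   [simulate_libraries()] or [read_fastq()].
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len insert length bounds (defaults 18 and 30 nt).
#' @return a list of class `mir_clean`: `reads` (tibble: library, read_id,
#'   sequence, length), `stats` (tibble: library, raw_reads, clean_reads,
#'   unique_tags), `rejects` (tibble: library, reason, n).
#' @export
clean_reads <- function(reads, adapter, min_len = 18L, max_len = 30L) {
  reads <- as_tibble(reads)
  if (!all(c("library", "sequence") %in% names(reads)))
    abort("`reads` needs columns `library` and `sequence`")
  if (!"read_id" %in% names(reads))
    reads$read_id <- sprintf("read_%07d", seq_len(nrow(reads)))

  tr <- trim_adapter(reads$sequence, adapter)
  out <- reads |>
    mutate(insert = tr$insert, reason = tr$status)

  # low-quality rule: > 20% of insert bases below Phred 10
  if ("quality" %in% names(out)) {
    ql <- !is.na(out$insert) &
      vapply(seq_len(nrow(out)), function(i) {
        if (is.na(out$insert[i])) return(FALSE)
        q <- utf8ToInt(substr(out$quality[i], 1, nchar(out$insert[i]))) - 33L
        length(q) > 0 && mean(q < 10) > 0.2
      }, logical(1))
    out$reason[ql] <- "low_quality"
    out$insert[ql] <- NA_character_
  }

  len <- nchar(out$insert)
  too_short <- out$reason == "trimmed" & len < min_len
  too_long <- out$reason == "trimmed" & len > max_len
  has_n <- out$reason == "trimmed" & grepl("N", out$insert, fixed = TRUE)
  out$reason[too_short] <- "too_short"
  out$reason[too_long] <- "too_long"
  out$reason[has_n] <- "contains_N"
  out$reason[out$reason == "trimmed"] <- "clean"

  clean <- out |>
    filter(.data$reason == "clean") |>
    transmute(.data$library, .data$read_id, sequence = .data$insert,
              length = nchar(.data$insert))
  rejects <- out |>
    filter(.data$reason != "clean") |>
    count(.data$library, .data$reason, name = "n")
  stats <- reads |>
    count(.data$library, name = "raw_reads") |>
    left_join(clean |>
                group_by(.data$library) |>
                summarise(clean_reads = n(),
                          unique_tags = dplyr::n_distinct(.data$sequence)),
              by = "library") |>
    mutate(clean_reads = dplyr::coalesce(.data$clean_reads, 0L),
           unique_tags = dplyr::coalesce(.data$unique_tags, 0L))
  structure(list(reads = clean, stats = stats, rejects = rejects),
            class = "mir_clean")
}

#' @export
print.mir_clean <- function(x, ...) {
  print(x$stats)
  invisible(x)
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' The unique-tag table at the heart of the pipeline: one row per distinct
#' insert sequence, one count column per library (`count_<library>`). Counts
#' conserve the clean totals: the column sums equal each library's clean
#' read count.
#'
#' @param clean a `mir_clean` from [clean_reads()], or a tibble with columns
#'   `library` and `sequence` (one row per read).
#' @return a tibble with `sequence` and one `count_<lib>` column per library.
#' @export
collapse_tags <- function(clean) {
  reads <- if (inherits(clean, "mir_clean")) clean$reads else as_tibble(clean)
  if (nrow(reads) == 0)
    return(tibble(sequence = character()))
  reads |>
    count(.data$library, .data$sequence) |>
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L, names_prefix = "count_") |>
    arrange(.data$sequence)
}

tag_count_cols <- function(tags) {
  cols <- grep("^count_", names(tags), value = TRUE)
  if (length(cols) < 1) abort("no count_<library> columns found")
  cols
}

#' Common and library-specific tag percentages
#'
#' The two-library overlap summary on both bases: percentage of unique tags
#' (and of total reads) that are common to both libraries or specific to
#' one. Percentages on each basis sum to 100.
#'
#' @param tags a tag table from [collapse_tags()] with two count columns.
#' @return a tibble with columns `basis` (`unique_tags`/`total_reads`),
#'   `common_pct`, and one `<lib>_specific_pct` per library.
#' @export
overlap_stats <- function(tags) {
  cols <- tag_count_cols(tags)
  if (length(cols) != 2) abort("overlap_stats needs exactly two libraries")
  a <- tags[[cols[1]]]; b <- tags[[cols[2]]]
  libs <- sub("^count_", "", cols)
  common <- a > 0 & b > 0
  only_a <- a > 0 & !common
  only_b <- b > 0 & !common
  pct <- function(x, tot) if (tot == 0) 0 else 100 * x / tot
  n <- nrow(tags); reads <- sum(a) + sum(b)
  out <- tibble(
    basis = c("unique_tags", "total_reads"),
    common_pct = c(pct(sum(common), n), pct(sum(a[common]) + sum(b[common]), reads)),
    spec_a = c(pct(sum(only_a), n), pct(sum(a[only_a]), reads)),
    spec_b = c(pct(sum(only_b), n), pct(sum(b[only_b]), reads))
  )
  names(out)[3:4] <- paste0(libs, "_specific_pct")
  out
}

#' Read-length distribution per library
#'
#' Length histogram of clean reads (counts and percentages) per library,
#' computed from the collapsed tag table. The modal length of a healthy
#' small-RNA library sits at 22 nt, the canonical mature miRNA length.
#'
#' @param tags a tag table from [collapse_tags()].
#' @return a tibble with `library`, `length`, `count`, `pct` (percentages
#'   sum to 100 within each library); empty libraries yield no rows.
#' @export
length_distribution <- function(tags) {
  if (nrow(tags) == 0)
    return(tibble(library = character(), length = integer(),
                  count = integer(), pct = double()))
  cols <- tag_count_cols(tags)
  tags |>
    mutate(length = nchar(.data$sequence)) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "library",
                        values_to = "n", names_prefix = "count_") |>
    group_by(.data$library, .data$length) |>
    summarise(count = sum(.data$n), .groups = "drop_last") |>
    filter(sum(.data$count) > 0) |>
    mutate(pct = 100 * .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(.data$library, .data$length)
}
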