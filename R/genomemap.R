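#' Build an exact-match genome index
#'
#' Wraps a genome (named character vector of chromosome sequences, or a
#' `synthetic_genome`) for exact-match tag lookup on both strands.
#'
#' @param genome named character vector of chromosome sequences, or a
#'   `synthetic_genome` from [generate_genome()].
#' @return a list of class `genome_index` with the chromosome sequences and
#'   their Biostrings representation.
#' @export
build_genome_index <- function(genome) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  if (inherits(genome, "synthetic_study")) genome <- genome$genome$genome
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  bad <- gregexpr("[^ACGT]", genome)
  for (i in seq_along(genome)) {
    pos <- bad[[i]]
    if (pos[1] != -1)
      abort(sprintf("non-ACGT characters in %s at positions %s",
                    names(genome)[i], paste(head(pos, 5), collapse = ", ")))
  }
  structure(
    list(seqs = genome, bs = Biostrings::DNAStringSet(genome)),
    class = "genome_index"
  )
}

#' Map tags to the genome by exact match
#'
#' Finds every exact occurrence of each tag on either strand. Hit counts are
#' recorded even beyond `max_hits`; over-threshold tags are flagged rather
#' than dropped, so downstream stages can apply the repeat-derived filter
#' explicitly.
#'
#' @param tags tag table from [collapse_tags()] (or a character vector of
#'   tag sequences).
#' @param index a `genome_index` from [build_genome_index()].
#' @param max_hits hit-count threshold above which a tag is flagged
#'   (default 10, the repeat-exclusion rule).
#' @return list of class `mir_map`: `hits` (tibble: sequence, chrom, start,
#'   end, strand; 0-based half-open) and `tag_hits` (tibble: sequence,
#'   n_hits, over_threshold).
#' @export
map_tags <- function(tags, index, max_hits = 10L) {
  stopifnot(inherits(index, "genome_index"))
  seqs <- if (is.character(tags)) unique(tags) else tags$sequence
  chroms <- names(index$seqs)
  hit_rows <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    rc <- revcomp(s)
    rows <- list()
    for (ch in chroms) {
      subj <- index$bs[[ch]]
      fwd <- Biostrings::matchPattern(s, subj)
      if (length(fwd))
        rows[[length(rows) + 1L]] <- tibble(
          sequence = s, chrom = ch,
          start = Biostrings::start(fwd) - 1L, end = Biostrings::end(fwd),
          strand = "+")
      rev <- Biostrings::matchPattern(rc, subj)
      if (length(rev))
        rows[[length(rows) + 1L]] <- tibble(
          sequence = s, chrom = ch,
          start = Biostrings::start(rev) - 1L, end = Biostrings::end(rev),
          strand = "-")
    }
    hit_rows[[i]] <- if (length(rows)) bind_rows(rows) else NULL
  }
  hits <- bind_rows(hit_rows)
  if (nrow(hits) == 0)
    hits <- tibble(sequence = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character())
  tag_hits <- tibble(sequence = seqs) |>
    left_join(hits |> count(.data$sequence, name = "n_hits"),
              by = "sequence") |>
    mutate(n_hits = dplyr::coalesce(.data$n_hits, 0L),
           over_threshold = .data$n_hits > max_hits)
  structure(list(hits = hits |> arrange(.data$sequence, .data$chrom,
                                        .data$start),
                 tag_hits = tag_hits, max_hits = max_hits),
            class = "mir_map")
}

# cascade priority, highest first
annotation_cascade <- c("known_miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                        "repeat", "exon", "unannotated")

# best known-miRNA assignment for a set of tag sequences: the tag must be an
# exact substring of a precursor and overlap its mature arm; ties broken by
# larger mature overlap, then lexicographic id
match_catalog <- function(seqs, catalog) {
  known <- if ("type" %in% names(catalog))
    catalog |> filter(.data$type == "known") else catalog
  if (nrow(known) == 0)
    return(tibble(sequence = character(), mirna_id = character()))
  out <- lapply(seqs, function(s) {
    pos <- vapply(known$precursor, function(p)
      as.integer(regexpr(s, p, fixed = TRUE)), integer(1), USE.NAMES = FALSE)
    cand <- which(pos > 0)
    if (!length(cand)) return(NULL)
    t_start <- pos[cand]
    t_end <- t_start + nchar(s) - 1L
    ov <- pmax(0L, pmin(t_end, known$mature_end[cand]) -
                 pmax(t_start, known$mature_start[cand]) + 1L)
    cand <- cand[ov > 0]; ov <- ov[ov > 0]
    if (!length(cand)) return(NULL)
    ord <- order(-ov, known$id[cand])
    tibble(sequence = s, mirna_id = known$id[cand[ord[1]]])
  })
  bind_rows(out)
}

#' Classify tags through the annotation cascade
#'
#' Assigns exactly one class to every tag, in priority order known_miRNA >
#' rRNA > tRNA > snRNA > snoRNA > repeat > exon > unannotated. A tag is a
#' known miRNA only if it matches a catalog precursor exactly as a substring
#' and overlaps the mature arm (the perfect-match rule for conserved
#' miRNAs); otherwise the class is the highest-priority annotation interval
#' overlapped by any of its genome hits. Mapped tags with no overlap are
#' `unannotated`; tags with no genome hit are also `unannotated` but carry
#' `n_hits = 0` and never enter novel-miRNA discovery.
#'
#' @param tags tag table from [collapse_tags()].
#' @param map a `mir_map` from [map_tags()].
#' @param annotations tibble of intervals: `chrom`, `start`, `end` (0-based
#'   half-open), `class`, `name`.
#' @param catalog known-miRNA catalog (columns `id`, `mature`, `precursor`,
#'   `mature_start`, `mature_end`; rows with `type != "known"` are ignored).
#' @return tibble: `sequence`, `class`, `feature_id`, `n_hits`,
#'   `over_threshold`.
#' @export
classify_tags <- function(tags, map, annotations, catalog) {
  stopifnot(inherits(map, "mir_map"))
  seqs <- tags$sequence
  if (nrow(annotations) > 0) {
    bad <- annotations$start < 0
    if (any(bad)) abort("annotation interval with negative start")
  }
  cat_hits <- match_catalog(seqs, catalog)

  # overlap class per tag from its genome hits
  hit_cls <- NULL
  if (nrow(map$hits) > 0 && nrow(annotations) > 0) {
    pieces <- lapply(split(map$hits, map$hits$chrom), function(h) {
      ann <- annotations |> filter(.data$chrom == h$chrom[1])
      if (nrow(ann) == 0) return(NULL)
      q <- IRanges::IRanges(start = h$start + 1L, end = h$end)
      s <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
      ov <- IRanges::findOverlaps(q, s)
      if (!length(ov)) return(NULL)
      tibble(sequence = h$sequence[S4Vectors::queryHits(ov)],
             class = ann$class[S4Vectors::subjectHits(ov)],
             feature_id = ann$name[S4Vectors::subjectHits(ov)])
    })
    hit_cls <- bind_rows(pieces)
  }
  prio <- function(cl) match(cl, annotation_cascade)
  best_ov <- if (!is.null(hit_cls) && nrow(hit_cls) > 0) {
    hit_cls |>
      group_by(.data$sequence) |>
      slice_min(prio(.data$class), n = 1, with_ties = FALSE) |>
      ungroup()
  } else tibble(sequence = character(), class = character(),
                feature_id = character())

  tibble(sequence = seqs) |>
    left_join(cat_hits, by = "sequence") |>
    left_join(best_ov, by = "sequence") |>
    left_join(map$tag_hits, by = "sequence") |>
    transmute(
      .data$sequence,
      class = dplyr::case_when(
        !is.na(.data$mirna_id) ~ "known_miRNA",
        !is.na(.data$class) ~ .data$class,
        TRUE ~ "unannotated"),
      feature_id = dplyr::coalesce(.data$mirna_id, .data$feature_id),
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      over_threshold = dplyr::coalesce(.data$over_threshold, FALSE))
}

#' Class distribution of tags on the unique and total-read bases
#'
#' @param classified output of [classify_tags()].
#' @param tags tag table with per-library counts.
#' @return tibble: `class`, `unique_tags`, `unique_pct`, `total_reads`,
#'   `total_pct`.
#' @export
class_distribution <- function(classified, tags) {
  cols <- tag_count_cols(tags)
  joined <- classified |>
    left_join(tags, by = "sequence") |>
    mutate(reads = rowSums(dplyr::pick(dplyr::all_of(cols))))
  joined |>
    group_by(.data$class) |>
    summarise(unique_tags = n(), total_reads = sum(.data$reads),
              .groups = "drop") |>
    mutate(unique_pct = 100 * .data$unique_tags / sum(.data$unique_tags),
           total_pct = 100 * .data$total_reads / sum(.data$total_reads)) |>
    arrange(match(.data$class, annotation_cascade))
}

#' Quantify known miRNAs from classified tags
#'
#' Sums per-library tag counts over every tag assigned to each catalog
#' miRNA (isomiRs collapse onto their miRNA); catalog entries with no
#' matching tag are reported with zero counts.
#'
#' @param classified output of [classify_tags()].
#' @param tags tag table with per-library counts.
#' @param catalog known-miRNA catalog.
#' @return tibble: `id` plus one `count_<lib>` column per library.
#' @export
quantify_known_mirnas <- function(classified, tags, catalog) {
  cols <- tag_count_cols(tags)
  known_ids <- if ("type" %in% names(catalog))
    catalog$id[catalog$type == "known"] else catalog$id
  counted <- classified |>
    filter(.data$class == "known_miRNA") |>
    left_join(tags, by = "sequence") |>
    group_by(id = .data$feature_id) |>
    summarise(dplyr::across(dplyr::all_of(cols), sum), .groups = "drop")
  tibble(id = known_ids) |>
    left_join(counted, by = "id") |>
    mutate(dplyr::across(dplyr::all_of(cols), ~ dplyr::coalesce(.x, 0L))) |>
    arrange(.data$id)
}
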