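#' Select candidate tags for novel miRNA discovery
#'
#' Keeps tags that survived the annotation cascade unassigned
#' (`unannotated`), map to the genome at least once, and have at most
#' `max_hits` genomic hits (tags with more than 10 hits are treated as
#' repeat-derived and removed).
#'
#' @param classified output of [classify_tags()].
#' @param max_hits genomic hit-count ceiling (default 10).
#' @return the retained rows of `classified`.
#' @export
select_candidate_tags <- function(classified, max_hits = 10L) {
  classified |>
    filter(.data$class == "unannotated",
           .data$n_hits >= 1L,
           .data$n_hits <= max_hits)
}

#' Extract precursor windows around candidate tag loci
#'
#' For each candidate tag, takes its first genomic hit in coordinate order
#' and extracts the tag plus `flank` nt upstream and downstream, clipped at
#' chromosome ends. Minus-strand hits are reverse-complemented so the tag
#' always reads forward within the returned window.
#'
#' @param candidates output of [select_candidate_tags()].
#' @param map a `mir_map` from [map_tags()].
#' @param genome named character vector of chromosomes (or
#'   `synthetic_genome`).
#' @param flank flank length in nt on each side (default 150).
#' @return tibble: `sequence`, `chrom`, `start`, `end`, `strand` (tag locus),
#'   `window_start`, `window_end` (window locus, 0-based half-open),
#'   `window` (sequence), `tag_offset` (0-based tag start within window).
#' @export
extract_flanks <- function(candidates, map, genome, flank = 150L) {
  if (inherits(genome, "synthetic_genome")) genome <- genome$genome
  first_hits <- map$hits |>
    filter(.data$sequence %in% candidates$sequence) |>
    group_by(.data$sequence) |>
    arrange(.data$chrom, .data$start, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  first_hits |>
    rowwise() |>
    mutate(
      chrlen = nchar(genome[[.data$chrom]]),
      window_start = max(0L, .data$start - flank),
      window_end = min(.data$chrlen, .data$end + flank),
      fwd = substr(genome[[.data$chrom]], .data$window_start + 1L,
                   .data$window_end),
      window = if (.data$strand == "+") .data$fwd else revcomp(.data$fwd),
      tag_offset = if (.data$strand == "+") .data$start - .data$window_start
                   else .data$window_end - .data$end
    ) |>
    ungroup() |>
    select("sequence", "chrom", "start", "end", "strand",
           "window_start", "window_end", "window", "tag_offset")
}

#' Evaluate a precursor window as a miRNA hairpin
#'
#' Folds the window under the frozen energy model and applies the novel
#' miRNA criteria to the candidate tag: the tag must reside in the stem of
#' the stem-loop (at least `stem_frac` of its bases paired, with every
#' partner on one opposing arm), be 20-22 nt long, and the window must fold
#' below `mfe_max` kcal/mol. The MFEI quality flag (window MFEI above
#' `mfei_min`) is reported separately and only folded into the verdict in
#' strict mode, since the MFE/length criteria define the candidate set and
#' MFEI is a posterior quality band.
#'
#' @param window precursor window sequence (tag plus flanks).
#' @param tag candidate tag sequence (must occur at `tag_offset`).
#' @param tag_offset 0-based tag start within the window.
#' @param mfe_max window MFE ceiling in kcal/mol (default -20; the window
#'   must fold strictly below it).
#' @param mfei_min MFEI quality threshold (default 0.85, exclusive).
#' @param stem_frac minimum fraction of tag bases paired (default 0.75).
#' @param strict_mfei if `TRUE`, `mfei_ok` joins the verdict.
#' @param model energy model.
#' @return one-row tibble: `mfe`, `amfe`, `mfei`, `in_stem`, `length_ok`,
#'   `mfe_ok`, `mfei_ok`, `verdict`, `structure`.
#' @export
evaluate_hairpin <- function(window, tag, tag_offset,
                             mfe_max = -20, mfei_min = 0.85,
                             stem_frac = 0.75, strict_mfei = FALSE,
                             model = energy_model()) {
  if (nchar(window) < nchar(tag))
    abort("internal error: window shorter than tag")
  if (substr(window, tag_offset + 1L, tag_offset + nchar(tag)) !=
      toupper(as_dna(tag)) &&
      substr(as_rna(window), tag_offset + 1L, tag_offset + nchar(tag)) !=
      toupper(as_rna(tag)))
    abort("tag does not occur at `tag_offset` within the window")
  f <- fold_hairpin(window, model)
  ix <- (tag_offset + 1L):(tag_offset + nchar(tag))
  partners <- f$pairs[ix]
  paired <- !is.na(partners)
  frac <- mean(paired)
  p <- partners[paired]
  one_arm <- length(p) == 0 ||
    all(p > tag_offset + nchar(tag)) || all(p <= tag_offset)
  in_stem <- frac >= stem_frac && length(p) > 0 && one_arm
  length_ok <- nchar(tag) >= 20 && nchar(tag) <= 22
  mfe_ok <- f$mfe < mfe_max
  q <- compute_mfei(f$mfe, window)
  mfei_ok <- q$mfei > mfei_min
  verdict <- in_stem && length_ok && mfe_ok && (!strict_mfei || mfei_ok)
  tibble(mfe = f$mfe, amfe = q$amfe, mfei = q$mfei,
         in_stem = in_stem, length_ok = length_ok, mfe_ok = mfe_ok,
         mfei_ok = mfei_ok, verdict = verdict, structure = f$structure)
}

#' Novel miRNA candidate table
#'
#' The full discovery stage: select unannotated low-multiplicity tags,
#' extract 150 nt flanked windows, fold each window and apply the hairpin
#' criteria. Candidates are disjoint from the known catalog by construction
#' (catalog tags classify as `known_miRNA` upstream of selection).
#'
#' @param classified output of [classify_tags()].
#' @param tags tag table with per-library counts.
#' @param map a `mir_map` from [map_tags()].
#' @param genome named character vector of chromosomes (or
#'   `synthetic_genome`).
#' @param flank flank length (default 150 nt).
#' @param max_hits genomic hit ceiling (default 10).
#' @inheritParams evaluate_hairpin
#' @return tibble sorted by (chrom, start): tag sequence, locus, window
#'   coordinates, MFE/AMFE/MFEI, criteria flags, verdict, per-library
#'   counts.
#' @export
novel_candidates <- function(classified, tags, map, genome, flank = 150L,
                             max_hits = 10L, mfe_max = -20, mfei_min = 0.85,
                             stem_frac = 0.75, strict_mfei = FALSE,
                             model = energy_model()) {
  cand <- select_candidate_tags(classified, max_hits = max_hits)
  cols <- tag_count_cols(tags)
  if (nrow(cand) == 0) {
    out <- tibble(sequence = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  window_start = integer(), window_end = integer(),
                  mfe = double(), amfe = double(), mfei = double(),
                  in_stem = logical(), length_ok = logical(),
                  mfe_ok = logical(), mfei_ok = logical(),
                  verdict = logical())
    for (cl in cols) out[[cl]] <- integer()
    return(out)
  }
  wins <- extract_flanks(cand, map, genome, flank = flank)
  evals <- purrr::pmap(
    list(wins$window, wins$sequence, wins$tag_offset),
    function(w, s, off)
      evaluate_hairpin(w, s, off, mfe_max = mfe_max, mfei_min = mfei_min,
                       stem_frac = stem_frac, strict_mfei = strict_mfei,
                       model = model)
  ) |> bind_rows()
  wins |>
    select(-"window", -"tag_offset") |>
    bind_cols(evals |> select(-"structure")) |>
    left_join(tags |> select("sequence", dplyr::all_of(cols)),
              by = "sequence") |>
    arrange(.data$chrom, .data$start)
}
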