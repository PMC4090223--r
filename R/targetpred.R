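#' Positional mismatch scores of a miRNA:target duplex
#'
#' Scores every miRNA position of a duplex: Watson-Crick pair = 0, G:U
#' wobble = 0.5 (a G:U base counts as half a mismatch), unpaired = 1.
#'
#' @param duplex a `mir_duplex` from [duplex_hybridize()], or a character
#'   vector of pair states (`"WC"`, `"GU"`, `"open"`).
#' @return list with `scores` (numeric per miRNA position, 5' end first)
#'   and `total`.
#' @export
#' @examples
#' score_mismatches(c("WC", "WC", "GU", "open", "WC"))
score_mismatches <- function(duplex) {
  states <- if (inherits(duplex, "mir_duplex")) duplex$pair_state else duplex
  if (!all(states %in% c("WC", "GU", "open")))
    abort("pair states must be WC, GU or open")
  scores <- c(WC = 0, GU = 0.5, open = 1)[states]
  list(scores = unname(scores), total = sum(scores))
}

#' Apply the six target-site rules to a duplex
#'
#' Evaluates the rule set for an acceptable miRNA:target duplex, positions
#' numbered from the miRNA 5' end:
#' \enumerate{
#'   \item no more than 4 mismatches in total (G:U counts 0.5);
#'   \item no run of more than 2 consecutive mismatched positions;
#'   \item no two adjacent mismatched positions within positions 2-12;
#'   \item no mismatch at position 10 or 11;
#'   \item at most 2.5 mismatches within positions 1-12;
#'   \item duplex MFE at least 75% of the MFE of the miRNA bound to its
#'     perfect complement (compared in magnitude).
#' }
#' For the summed rules (1, 5) a G:U contributes its 0.5 weight; for the
#' presence/adjacency rules (2, 3, 4) any position scoring above zero counts
#' as "a mismatch present" by default (`gu_strict = TRUE`), since fractional
#' adjacency is not meaningful. `gu_strict = FALSE` treats G:U as a
#' non-mismatch for rules 2-4.
#'
#' @param duplex a `mir_duplex` (or pair-state vector).
#' @param mfe_duplex duplex MFE; taken from `duplex` when it is a
#'   `mir_duplex`.
#' @param mfe_perfect MFE of the miRNA bound to its perfect complement; if
#'   missing and `duplex` is a `mir_duplex`, computed from its miRNA.
#' @param gu_strict whether G:U counts as a present mismatch for rules 2-4.
#' @param mfe_ratio_min rule-6 threshold (default 0.75).
#' @return one-row tibble: `r1`..`r6`, `mismatch_total`, `mfe_ratio`,
#'   `verdict`, plus a `scores` list-column with the positional vector.
#' @export
apply_rules <- function(duplex, mfe_duplex = NULL, mfe_perfect = NULL,
                        gu_strict = TRUE, mfe_ratio_min = 0.75) {
  sm <- score_mismatches(duplex)
  s <- sm$scores
  L <- length(s)
  if (inherits(duplex, "mir_duplex")) {
    mfe_duplex <- mfe_duplex %||% duplex$mfe
    if (is.null(mfe_perfect)) mfe_perfect <- perfect_complement_mfe(duplex$mirna)
  }
  if (is.null(mfe_duplex) || is.null(mfe_perfect))
    abort("`mfe_duplex` and `mfe_perfect` are required")
  if (mfe_perfect >= 0) abort("perfect-complement MFE must be negative")

  rc <- rules_core(s, mfe_duplex, mfe_perfect, gu_strict, mfe_ratio_min)
  out <- tibble(
    r1 = rc$r[1], r2 = rc$r[2], r3 = rc$r[3],
    r4 = rc$r[4], r5 = rc$r[5], r6 = rc$r[6],
    mismatch_total = rc$total,
    mfe_ratio = rc$ratio
  )
  out$verdict <- rc$verdict
  out$scores <- list(s)
  out
}

# numeric rule evaluation shared by apply_rules() and scan_transcript()
rules_core <- function(s, mfe_duplex, mfe_perfect, gu_strict = TRUE,
                       mfe_ratio_min = 0.75) {
  L <- length(s)
  present <- if (gu_strict) s > 0 else s == 1
  runs <- rle(present)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  win512 <- seq2(2L, min(12L, L))      # positions 2..12
  adj <- win512[-length(win512)]
  r <- c(
    sum(s) <= 4,
    max_run <= 2,
    !any(present[adj] & present[adj + 1L]),
    !any(present[intersect(10:11, seq_len(L))]),
    sum(s[seq_len(min(12L, L))]) <= 2.5,
    abs(mfe_duplex) >= mfe_ratio_min * abs(mfe_perfect)
  )
  list(r = r, verdict = all(r), total = sum(s),
       ratio = mfe_duplex / mfe_perfect)
}

seq2 <- function(from, to) if (to < from) integer() else seq(from, to)

#' Scan a transcript for miRNA target sites
#'
#' Slides windows of the miRNA length plus/minus `site_pad` across the
#' transcript at step 1, hybridizes the miRNA against every window and
#' applies the six rules; overlapping passing windows are merged keeping the
#' lowest-MFE site.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcript transcript (3'UTR) sequence 5'->3'.
#' @param site_pad window slack on either side of the miRNA length
#'   (default 3).
#' @param gu_strict passed to [apply_rules()].
#' @param model energy model.
#' @param max_bulge bulge cap per side for hybridization.
#' @param merge_overlaps merge overlapping passing windows (set `FALSE` to
#'   see every passing window, e.g. for validation).
#' @return tibble of passing sites: `start`, `end` (0-based half-open on the
#'   transcript), `mfe`, `mfe_ratio`, `mismatch_total`, `r1`..`r6`.
#' @export
scan_transcript <- function(mirna, transcript, site_pad = 3L,
                            gu_strict = TRUE, model = energy_model(),
                            max_bulge = 3L, merge_overlaps = TRUE) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  empty <- tibble(start = integer(), end = integer(), mfe = double(),
                  mfe_ratio = double(), mismatch_total = double(),
                  r1 = logical(), r2 = logical(), r3 = logical(),
                  r4 = logical(), r5 = logical(), r6 = logical())
  if (Tn < L) return(empty)
  mfe_perfect <- perfect_complement_mfe(mirna, model, max_bulge)
  m_enc <- encode_seq(mirna)
  t_enc <- encode_seq(transcript)
  wlen <- min(L + site_pad, Tn)
  starts <- seq_len(Tn - (L - site_pad) + 1L) - 1L    # 0-based
  rows <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s0 <- starts[i]
    e0 <- min(Tn, s0 + wlen)
    if (e0 - s0 < L - site_pad) next
    w_enc <- t_enc[(s0 + 1L):e0]
    d <- duplex_mfe_cpp(m_enc, rev(w_enc), model, max_bulge = max_bulge)
    # pair-state scores in miRNA coordinates: WC 0, G:U 0.5, open 1
    partner <- length(w_enc) + 1L - d$partner_rev   # 1-based within window
    s <- rep(1, L)
    idx <- which(!is.na(partner))
    if (length(idx)) {
      mb <- m_enc[idx]; sb <- w_enc[partner[idx]]
      s[idx] <- ifelse((mb == 2L & sb == 3L) | (mb == 3L & sb == 2L), 0.5, 0)
    }
    rc <- rules_core(s, d$mfe, mfe_perfect, gu_strict)
    if (rc$verdict)
      rows[[i]] <- c(s0, e0, d$mfe, rc$ratio, rc$total, rc$r)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  hits <- if (length(rows)) {
    mat <- do.call(rbind, rows)
    tibble(start = as.integer(mat[, 1]), end = as.integer(mat[, 2]),
           mfe = mat[, 3], mfe_ratio = mat[, 4], mismatch_total = mat[, 5],
           r1 = mat[, 6] > 0, r2 = mat[, 7] > 0, r3 = mat[, 8] > 0,
           r4 = mat[, 9] > 0, r5 = mat[, 10] > 0, r6 = mat[, 11] > 0)
  } else empty
  if (nrow(hits) == 0 || !merge_overlaps) return(hits)
  # merge overlapping passing windows, keep the lowest-MFE representative
  hits <- hits |> arrange(.data$start)
  grp <- integer(nrow(hits)); g <- 1L; grp[1] <- 1L
  if (nrow(hits) > 1) {
    hi <- hits$end[1]
    for (i in 2:nrow(hits)) {
      if (hits$start[i] < hi) grp[i] <- g
      else { g <- g + 1L; grp[i] <- g }
      hi <- max(hi, hits$end[i])
    }
  }
  hits |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    slice_min(.data$mfe, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-".grp") |>
    arrange(.data$start)
}

#' Predict targets of a miRNA set over a 3'UTR set
#'
#' Runs [scan_transcript()] for every miRNA x UTR combination and collects
#' passing sites, per-miRNA site totals (zeros included) and per-rule
#' failure tallies over all evaluated duplex windows.
#'
#' @param mirnas data frame with columns `id`, `mature` (or `sequence`).
#' @param utrs data frame with columns `id`, `sequence`.
#' @inheritParams scan_transcript
#' @return list of class `mir_targets`: `sites` (tibble: mirna, transcript,
#'   start, end, mfe, mfe_ratio, mismatch_total, rule flags), `totals`
#'   (tibble: mirna, n_sites).
#' @export
predict_targets <- function(mirnas, utrs, site_pad = 3L, gu_strict = TRUE,
                            model = energy_model(), max_bulge = 3L) {
  mirnas <- as_tibble(mirnas)
  seq_col <- if ("mature" %in% names(mirnas)) "mature" else "sequence"
  pieces <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(utrs))) {
      sites <- scan_transcript(mirnas[[seq_col]][i], utrs$sequence[j],
                               site_pad = site_pad, gu_strict = gu_strict,
                               model = model, max_bulge = max_bulge)
      if (nrow(sites))
        pieces[[length(pieces) + 1L]] <-
          bind_cols(tibble(mirna = mirnas$id[i], transcript = utrs$id[j]),
                    sites)
    }
  }
  sites <- if (length(pieces)) bind_rows(pieces) else
    tibble(mirna = character(), transcript = character(), start = integer(),
           end = integer(), mfe = double(), mfe_ratio = double(),
           mismatch_total = double())
  totals <- tibble(mirna = mirnas$id) |>
    left_join(sites |> count(.data$mirna, name = "n_sites"), by = "mirna") |>
    mutate(n_sites = dplyr::coalesce(.data$n_sites, 0L))
  structure(list(sites = sites, totals = totals), class = "mir_targets")
}

#' @export
print.mir_targets <- function(x, ...) {
  print(x$totals)
  invisible(x)
}
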