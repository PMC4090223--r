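#' Fold a single RNA sequence into its minimum free energy structure
#'
#' Computes the MFE-optimal nested secondary structure (no pseudoknots) under
#' the package's frozen nearest-neighbour model, by Zuker-style dynamic
#' programming over stacking, hairpin/bulge/internal loops and multiloops.
#' This is the engine behind precursor hairpin evaluation.
#'
#' @param sequence RNA or DNA string, length >= 10; T and U are synonymous.
#' @param model energy model, see [energy_model()].
#' @return a list of class `mir_fold`: `sequence` (RNA), `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), `pairs` (1-based partner index or
#'   NA per position), `paired` (logical per position).
#' @seealso [fold_exhaustive()] for the brute-force reference,
#'   [compute_mfei()] for AMFE/MFEI.
#' @export
#' @examples
#' f <- fold_hairpin(paste0(strrep("G", 10), "AAAAA", strrep("C", 10)))
#' f$structure
#' f$mfe
fold_hairpin <- function(sequence, model = energy_model()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 10) abort("`sequence` must be at least 10 nt")
  s <- encode_seq(sequence)
  res <- fold_mfe_cpp(s, model)
  structure(
    list(sequence = toupper(as_rna(sequence)),
         structure = res$structure,
         mfe = res$mfe,
         pairs = res$pairs,
         paired = !is.na(res$pairs)),
    class = "mir_fold"
  )
}

#' @export
print.mir_fold <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", sprintf("%.2f", x$mfe),
      " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Exhaustive-enumeration folding reference
#'
#' Enumerates every nested secondary structure of a short sequence, scores
#' each by explicit loop decomposition under the same frozen energy table,
#' and returns the minimum. Independent of the dynamic-programming engine;
#' used to validate [fold_hairpin()] on sequences up to ~16 nt.
#'
#' @inheritParams fold_hairpin
#' @return list with `mfe`, `structure`, `n_structures`.
#' @export
fold_exhaustive <- function(sequence, model = energy_model()) {
  fold_exhaustive_cpp(encode_seq(sequence), model)
}

#' Score an explicit structure under the energy model
#'
#' Loop-decomposition energy of a given pairing; `NA` if the structure is
#' disallowed by the model (crossing pairs, hairpin loop < 3 nt, oversized
#' interior loop).
#'
#' @inheritParams fold_hairpin
#' @param pairs 1-based partner index per position (NA = unpaired), as in the
#'   `pairs` element of a `mir_fold`.
#' @return energy in kcal/mol, or NA.
#' @export
score_structure <- function(sequence, pairs, model = energy_model()) {
  pv <- ifelse(is.na(pairs), -1L, as.integer(pairs) - 1L)
  score_structure_cpp(encode_seq(sequence), pv, model)
}

#' Hybridize a miRNA against a target site
#'
#' Optimal intermolecular alignment (no intramolecular pairs) of a miRNA with
#' a candidate site under the frozen energy model, allowing bulge/internal
#' loops of up to `max_bulge` unpaired bases per side. Pair states are
#' reported in miRNA coordinates, position 1 = miRNA 5' end: `WC` for
#' Watson-Crick, `GU` for a G:U wobble, `open` for an unpaired position.
#'
#' @param mirna miRNA sequence 5'->3', 15-30 nt.
#' @param site target site sequence 5'->3' (the mRNA strand); its length must
#'   be within the miRNA length +/- 6.
#' @param model energy model.
#' @param max_bulge maximum unpaired bases per side of an interior loop.
#' @return a list of class `mir_duplex`: `mirna`, `site`, `mfe` (kcal/mol,
#'   includes the duplex initiation penalty; 0 if no stable duplex),
#'   `pair_state` (character per miRNA position), `partner` (1-based site
#'   position or NA per miRNA position).
#' @export
#' @examples
#' m <- "UGGAAUGUAAAGAAGUAUGUAU"
#' d <- duplex_hybridize(m, revcomp(m))
#' all(d$pair_state == "WC")
duplex_hybridize <- function(mirna, site, model = energy_model(),
                             max_bulge = 3) {
  L <- nchar(mirna); M <- nchar(site)
  if (L < 15 || L > 30) abort("miRNA length must be within 15-30 nt")
  if (abs(M - L) > 6) abort("site length must be within miRNA length +/- 6")
  a <- encode_seq(mirna)
  site_rna <- toupper(as_rna(site))
  t_rev <- rev(encode_seq(site))
  res <- duplex_mfe_cpp(a, t_rev, model, max_bulge = max_bulge)
  partner <- ifelse(is.na(res$partner_rev), NA_integer_,
                    M + 1L - res$partner_rev)
  mirna_rna <- toupper(as_rna(mirna))
  state <- rep("open", L)
  idx <- which(!is.na(partner))
  if (length(idx)) {
    mb <- substring(mirna_rna, idx, idx)
    sb <- substring(site_rna, partner[idx], partner[idx])
    duo <- paste0(mb, sb)
    state[idx] <- ifelse(duo %in% c("GU", "UG"), "GU", "WC")
  }
  structure(
    list(mirna = mirna_rna, site = site_rna, mfe = res$mfe,
         pair_state = state, partner = partner),
    class = "mir_duplex"
  )
}

#' @export
print.mir_duplex <- function(x, ...) {
  cat("miRNA 5'-", x$mirna, "-3'\n", sep = "")
  cat("states  ", paste0(substr(x$pair_state, 1, 1), collapse = ""),
      "  (W = WC, G = G:U, o = open)\n", sep = "")
  cat(sprintf("duplex MFE %.2f kcal/mol\n", x$mfe))
  invisible(x)
}

#' Brute-force duplex hybridization reference
#'
#' Plain recursive enumeration of every monotone miRNA:site alignment with
#' the same per-side bulge cap; returns the minimum energy. Independent of
#' the alignment DP; used to validate [duplex_hybridize()] on short inputs.
#'
#' @inheritParams duplex_hybridize
#' @return duplex MFE in kcal/mol.
#' @export
duplex_exhaustive <- function(mirna, site, model = energy_model(),
                              max_bulge = 3) {
  duplex_exhaustive_cpp(encode_seq(mirna), rev(encode_seq(site)),
                        model, max_bulge = max_bulge)
}

#' MFE of a miRNA bound to its perfect complement
#'
#' The reference energy for target rule 6: hybridization energy of the miRNA
#' against its exact reverse complement.
#'
#' @inheritParams duplex_hybridize
#' @return MFE in kcal/mol (strictly negative for any real miRNA).
#' @export
perfect_complement_mfe <- function(mirna, model = energy_model(),
                                   max_bulge = 3) {
  duplex_hybridize(mirna, revcomp(mirna), model, max_bulge = max_bulge)$mfe
}
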