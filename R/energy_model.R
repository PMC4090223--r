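#' The frozen nearest-neighbour energy model
#'
#' Loads the versioned parameter table shipped with the package: stacking
#' energies (kcal/mol) for Watson-Crick and G:U wobble pairs, size-indexed
#' hairpin/bulge/internal loop penalties, linear multiloop parameters and the
#' duplex initiation penalty. All folding and hybridization in the package is
#' computed under this single frozen table, which makes every energy
#' bit-reproducible and checkable against exhaustive enumeration.
#'
#' @param version parameter table version (currently only `"v1"`).
#' @return a list with elements `stack` (6x6 matrix over pair codes AU, UA,
#'   CG, GC, GU, UG), `hairpin`, `bulge`, `internal` (size-indexed penalty
#'   vectors), `ml_a`, `ml_b`, `ml_c` (multiloop closing/branch/unpaired),
#'   `duplex_init`, `extrap`, `maxloop`, `minloop`.
#' @export
#' @examples
#' em <- energy_model()
#' em$stack["GC", "CG"]   # 5'-GC-3' stacked on CG
energy_model <- function(version = "v1") {
  key <- paste0("energy_", version)
  if (!is.null(the[[key]])) return(the[[key]])
  path <- system.file("extdata", paste0("energy_params_", version, ".tsv"),
                      package = "mirdiverge")
  if (!nzchar(path)) abort(sprintf("unknown energy model version '%s'", version))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- tab[tab$param == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(st$key1, st$key2)] <- st$value
  stopifnot(all(stack <= 0))
  pick <- function(p) {
    x <- tab[tab$param == p, ]
    x$value[order(as.integer(x$key1))]
  }
  scalar <- function(p, k) tab$value[tab$param == p & tab$key1 == k]
  em <- list(
    stack = stack,
    hairpin = pick("hairpin"),      # sizes 3..30
    bulge = pick("bulge"),          # sizes 1..30
    internal = pick("internal"),    # sizes 2..30
    ml_a = scalar("multiloop", "a"),
    ml_b = scalar("multiloop", "b"),
    ml_c = scalar("multiloop", "c"),
    duplex_init = scalar("init", "duplex"),
    extrap = scalar("extrapolation", "coef"),
    maxloop = as.integer(scalar("maxloop", "interior")),
    minloop = as.integer(scalar("minloop", "hairpin"))
  )
  the[[key]] <- em
  em
}

#' Adjusted MFE and minimal folding free energy index
#'
#' `compute_mfei()` converts a minimum free energy into the two normalized
#' quantities used to separate miRNA precursors from other RNA classes:
#' AMFE = (-MFE / length) x 100 (kcal/mol per 100 nt) and
#' MFEI = AMFE / GC percentage. Precursor hairpins typically score MFEI above
#' 0.85 while tRNA (~0.64), rRNA (~0.59) and mRNA (~0.65) fall well below.
#'
#' @param mfe minimum free energy in kcal/mol (must be <= 0).
#' @param sequence the folded sequence (for length and GC content).
#' @return a one-row tibble with columns `mfe`, `amfe`, `mfei`, `gc_pct`.
#' @export
#' @examples
#' compute_mfei(-50, strrep("GC", 50))  # MFEI well above the 0.85 band
compute_mfei <- function(mfe, sequence) {
  stopifnot(length(mfe) == 1, length(sequence) == 1)
  if (is.na(mfe) || mfe > 0) abort("`mfe` must be <= 0")
  if (!nzchar(sequence)) abort("`sequence` must be non-empty")
  gc_pct <- gc_fraction(sequence) * 100
  if (gc_pct == 0) abort("MFEI undefined: sequence has zero GC content")
  amfe <- (-mfe / nchar(sequence)) * 100
  tibble(mfe = mfe, amfe = amfe, mfei = amfe / gc_pct, gc_pct = gc_pct)
}
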