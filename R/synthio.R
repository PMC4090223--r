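#' Configuration for a synthetic two-library small RNA study
#'
#' Bundles every knob of the synthetic study generator: a genome with
#' annotated non-miRNA features, a catalog of known miRNAs with designed
#' tissue fold changes, spiked novel hairpins, and two read libraries
#' ("AF" and "AM") of 18-30 nt inserts with a dominant 22 nt mode, a 3'
#' adapter, and isomiR length jitter. A fixed `seed` makes every derived
#' artifact byte-identical across runs.
#'
#' @param seed integer seed controlling all randomness.
#' @param genome_length genome size in bases (>= 10 kb).
#' @param gc_content genome GC fraction in (0, 1).
#' @param n_known_mirnas number of catalog (known) miRNAs.
#' @param n_novel_hairpins number of spiked novel hairpin loci.
#' @param depth_per_library reads simulated per library (>= 0).
#' @param adapter 3' adapter appended to every insert (>= 6 nt).
#' @param fold_change_spec named numeric: designed linear AF/AM abundance
#'   ratio per known miRNA id. `NULL` assigns the default design: 15% of
#'   miRNAs up 8-fold, 15% down 8-fold, the rest unchanged.
#' @param isomir_jitter maximum nt trimmed or extended at the mature 3' end.
#' @param background_fraction fraction of reads drawn from annotated
#'   ncRNA/repeat/exon intervals and intergenic positions.
#' @param novel_fraction fraction of reads drawn from spiked novel hairpins.
#' @param libraries two library identifiers.
#' @return a validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1, depth_per_library = 1e4)
synthetic_config <- function(seed = 1L,
                             genome_length = 50000L,
                             gc_content = 0.42,
                             n_known_mirnas = 30L,
                             n_novel_hairpins = 8L,
                             depth_per_library = 1e5,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             fold_change_spec = NULL,
                             isomir_jitter = 2L,
                             background_fraction = 0.25,
                             novel_fraction = 0.05,
                             libraries = c("AF", "AM")) {
  stopifnot(seed %% 1 == 0, genome_length >= 10000,
            gc_content > 0, gc_content < 1,
            n_known_mirnas >= 1, n_novel_hairpins >= 0,
            depth_per_library >= 0, nchar(adapter) >= 6,
            isomir_jitter >= 0,
            background_fraction >= 0, background_fraction <= 1,
            novel_fraction >= 0,
            background_fraction + novel_fraction < 1,
            length(libraries) == 2)
  ids <- sprintf("mir-%03d", seq_len(n_known_mirnas))
  if (is.null(fold_change_spec)) {
    k <- ceiling(0.15 * n_known_mirnas)
    fc <- setNames(rep(1, n_known_mirnas), ids)
    fc[seq_len(k)] <- 8
    if (n_known_mirnas >= 2 * k) fc[k + seq_len(k)] <- 1 / 8
    fold_change_spec <- fc
  } else {
    if (!all(names(fold_change_spec) %in% ids))
      abort("fold_change_spec names must be known miRNA ids (mir-XXX)")
    fc <- setNames(rep(1, n_known_mirnas), ids)
    fc[names(fold_change_spec)] <- fold_change_spec
    fold_change_spec <- fc
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, n_known_mirnas = as.integer(n_known_mirnas),
         n_novel_hairpins = as.integer(n_novel_hairpins),
         depth_per_library = depth_per_library, adapter = toupper(adapter),
         fold_change_spec = fold_change_spec,
         isomir_jitter = as.integer(isomir_jitter),
         background_fraction = background_fraction,
         novel_fraction = novel_fraction,
         libraries = libraries),
    class = "synthetic_config"
  )
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# stem-loop precursor: mature on the 5' arm, short loop, perfect-complement
# star on the 3' arm
design_hairpin <- function(mature, loop_len) {
  loop <- random_dna(loop_len, 0.2)   # AU-rich loop folds nowhere else
  paste0(mature, loop, revcomp(mature))
}

#' Generate the synthetic miRNA catalog
#'
#' Designs `n_known_mirnas` known miRNAs and `n_novel_hairpins` novel
#' hairpins: each entry is a mature sequence (20-23 nt, mode 22 nt for known;
#' 20-22 nt for novel) sitting on the 5' arm of a designed stem-loop
#' precursor (mature + AU-rich loop + perfect-complement star). The mature is
#' always an exact substring of its precursor and every precursor folds to a
#' strongly negative MFE.
#'
#' @param cfg a [synthetic_config()].
#' @return a tibble with columns `id`, `type` ("known"/"novel"), `mature`,
#'   `precursor`, `mature_start`, `mature_end` (1-based within precursor).
#' @export
generate_mirna_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 202L)
  n_k <- cfg$n_known_mirnas; n_n <- cfg$n_novel_hairpins
  lens_known <- sample(c(21L, 22L, 22L, 22L, 23L), n_k, replace = TRUE)
  lens_novel <- if (n_n > 0) sample(c(20L, 21L, 21L, 22L), n_n, replace = TRUE)
                else integer()
  tibble(
    id = c(sprintf("mir-%03d", seq_len(n_k)),
           if (n_n > 0) sprintf("novel-%03d", seq_len(n_n))),
    type = c(rep("known", n_k), rep("novel", n_n)),
    mature_len = c(lens_known, lens_novel)
  ) |>
    mutate(
      mature = vapply(.data$mature_len, function(l) random_dna(l, 0.5),
                      character(1)),
      loop_len = sample(8:12, n_k + n_n, replace = TRUE),
      precursor = mapply(design_hairpin, .data$mature, .data$loop_len),
      mature_start = 1L,
      mature_end = .data$mature_len
    ) |>
    select("id", "type", "mature", "precursor", "mature_start", "mature_end")
}

#' Generate the synthetic genome and annotation intervals
#'
#' Builds a random genome of the configured length and GC content, embeds
#' every catalog precursor (known and novel; about a third on the minus
#' strand), and lays down non-overlapping annotation intervals for rRNA,
#' tRNA, snRNA, snoRNA, repeat and exon classes plus an intergenic pool.
#' Repeat intervals share one monomer sequence so repeat-derived tags hit
#' multiple loci. Coordinates are 0-based half-open throughout.
#'
#' @param cfg a [synthetic_config()].
#' @param catalog optional catalog from [generate_mirna_catalog()]; generated
#'   from `cfg` when omitted.
#' @return a list of class `synthetic_genome`: `genome` (named character,
#'   single chromosome "chr1"), `annotations` (tibble: chrom, start, end,
#'   class, name, strand), `mirna_loci` (tibble: id, type, chrom, start, end,
#'   strand).
#' @export
generate_genome <- function(cfg, catalog = generate_mirna_catalog(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 101L)
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "exon")
  n_per_class <- 4L
  n_feat <- nrow(catalog) + length(classes) * n_per_class
  slot <- floor(cfg$genome_length / n_feat)
  need <- 400L   # precursor/interval plus 150 nt flanks on both sides
  if (slot < need)
    abort(sprintf(paste0(
      "genome too short: %d features need ~%d bases each but only %d are ",
      "available per feature; increase genome_length by at least %d bases"),
      n_feat, need, slot, (need - slot) * n_feat))
  genome <- random_dna(cfg$genome_length, cfg$gc_content)

  slots <- sample(seq_len(n_feat))   # shuffle feature order across the genome
  slot_start <- (slots - 1L) * slot + 160L   # leave flank room at both ends

  # embed precursors
  n_cat <- nrow(catalog)
  strands <- rep(c("+", "+", "-"), length.out = n_cat)
  loci <- vector("list", n_cat)
  for (i in seq_len(n_cat)) {
    pre <- catalog$precursor[i]
    emb <- if (strands[i] == "+") pre else revcomp(pre)
    s0 <- slot_start[i]
    substr(genome, s0 + 1L, s0 + nchar(pre)) <- emb
    loci[[i]] <- tibble(id = catalog$id[i], type = catalog$type[i],
                        chrom = "chr1", start = s0, end = s0 + nchar(pre),
                        strand = strands[i])
  }
  mirna_loci <- bind_rows(loci)

  # annotation intervals; repeat intervals share one monomer
  rep_monomer <- random_dna(180L, cfg$gc_content)
  ann <- vector("list", length(classes) * n_per_class)
  k <- 0L
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      k <- k + 1L
      s0 <- slot_start[n_cat + k]
      len <- sample(80:220, 1)
      if (classes[ci] == "repeat") {
        len <- 180L
        substr(genome, s0 + 1L, s0 + len) <- rep_monomer
      }
      ann[[k]] <- tibble(chrom = "chr1", start = s0, end = s0 + len,
                         class = classes[ci],
                         name = sprintf("%s_%d", classes[ci], r),
                         strand = "+")
    }
  }
  structure(
    list(genome = c(chr1 = genome),
         annotations = bind_rows(ann) |> arrange(.data$start),
         mirna_loci = mirna_loci),
    class = "synthetic_genome"
  )
}

# probabilities of the 3' isomiR variants: offset 0 has weight 1/(j+1),
# each of +/-k (k = 1..j) has weight 1/(2(j+1))
isomir_offsets <- function(j) {
  if (j == 0) return(tibble(offset = 0L, prob = 1))
  tibble(offset = c(0L, -(1:j), 1:j),
         prob = c(1 / (j + 1), rep(1 / (2 * (j + 1)), 2 * j)))
}

# variant sequences for a mature at the 5' end of its precursor; extension
# templates from the precursor, lengths clamped to what the precursor allows
isomir_variants <- function(mature, precursor, j) {
  isomir_offsets(j) |>
    mutate(len = nchar(mature) + .data$offset) |>
    filter(.data$len >= 18, .data$len <= 30, .data$len <= nchar(precursor)) |>
    mutate(sequence = substring(precursor, 1L, .data$len)) |>
    group_by(.data$sequence) |>
    summarise(prob = sum(.data$prob), .groups = "drop") |>
    mutate(prob = .data$prob / sum(.data$prob))
}

#' Simulate the two read libraries with a known truth table
#'
#' Draws `depth_per_library` reads per library from a designed proportion
#' vector: known miRNAs get log-normal base abundances with the configured
#' AF/AM fold changes applied to the AF proportions, novel hairpins a fixed
#' share split evenly, and the background share is drawn from a small pool of
#' distinct tags taken from annotated ncRNA/repeat/exon intervals and
#' intergenic positions. miRNA-derived reads receive uniform 3' isomiR
#' jitter (5' end fixed); every read then gets the 3' adapter appended.
#' Counts are multinomial, so empirical AF/AM ratios recover the designed
#' ones within sampling error.
#'
#' @param cfg a [synthetic_config()].
#' @param catalog catalog from [generate_mirna_catalog()].
#' @param genome a `synthetic_genome` from [generate_genome()].
#' @return a list of class `synthetic_reads`: `reads` (tibble: library,
#'   read_id, sequence, quality), `truth` (tibble per origin x library:
#'   origin_id, class, designed proportion, expected and drawn counts),
#'   `draws` (tibble per emitted tag variant: library, origin_id, sequence,
#'   count).
#' @export
simulate_libraries <- function(cfg, catalog = generate_mirna_catalog(cfg),
                               genome = generate_genome(cfg, catalog)) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(genome, "synthetic_genome"))
  set.seed(cfg$seed + 303L)
  libs <- cfg$libraries
  known <- catalog |> filter(.data$type == "known")
  novel <- catalog |> filter(.data$type == "novel")

  # designed proportions ------------------------------------------------
  # AM carries log-normal base abundances; AF applies the designed ratios to
  # the same bases. The background share absorbs the per-library
  # normalization (scaled jointly when the ratios inflate the miRNA share),
  # so every designed AF/AM proportion ratio equals fold_change_spec exactly.
  base <- rlnorm(nrow(known), meanlog = 0, sdlog = 1.2)
  novel_tot <- if (nrow(novel) > 0) cfg$novel_fraction else 0
  known_share <- 1 - cfg$background_fraction - novel_tot
  prop_am_known <- base / sum(base) * known_share
  fc <- unname(cfg$fold_change_spec[known$id])
  prop_af_known <- prop_am_known * fc
  if (cfg$background_fraction > 0) {
    min_bg <- min(0.02, cfg$background_fraction / 2)
    cap <- 1 - novel_tot - min_bg
    over <- max(sum(prop_af_known), sum(prop_am_known))
    if (over > cap) {
      s <- cap / over
      prop_af_known <- prop_af_known * s
      prop_am_known <- prop_am_known * s
    }
  } else {
    # no background to absorb the normalization: renormalize each library
    # (designed ratios then hold only up to the common factor)
    prop_af_known <- prop_af_known / sum(prop_af_known) * known_share
    prop_am_known <- prop_am_known / sum(prop_am_known) * known_share
  }

  novel_prop <- if (nrow(novel) > 0)
    rep(cfg$novel_fraction / nrow(novel), nrow(novel)) else numeric()

  # background pool: 5 distinct tags per annotated class + intergenic ----
  bg <- local({
    gseq <- genome$genome[["chr1"]]
    pick <- function(cls_tbl, cls, n_tags = 5L) {
      rows <- cls_tbl[sample.int(nrow(cls_tbl), n_tags, replace = TRUE), ]
      len <- sample(c(19:21, rep(22L, 3), 23:26), n_tags, replace = TRUE)
      off <- vapply(seq_len(n_tags), function(i)
        sample.int(max(1L, rows$end[i] - rows$start[i] - len[i]), 1L),
        integer(1))
      tibble(class = cls,
             sequence = substr(rep(gseq, n_tags),
                               rows$start + off + 1L,
                               rows$start + off + len))
    }
    ann <- genome$annotations
    pools <- lapply(split(ann, ann$class), function(tb)
      pick(tb, tb$class[1]))
    # intergenic: positions clear of every feature and its flanks
    feat <- bind_rows(ann |> select("start", "end"),
                      genome$mirna_loci |> select("start", "end"))
    inter <- NULL
    tries <- 0L
    while ((is.null(inter) || nrow(inter) < 5L) && tries < 200L) {
      tries <- tries + 1L
      len <- sample(c(20L, 22L, 24L), 1)
      s0 <- sample.int(cfg$genome_length - len, 1L)
      if (any(s0 < feat$end + 160 & s0 + len > feat$start - 160)) next
      inter <- bind_rows(inter, tibble(class = "intergenic",
                                       sequence = substr(gseq, s0 + 1, s0 + len)))
    }
    bind_rows(c(pools, list(inter))) |>
      distinct(.data$sequence, .keep_all = TRUE)
  })
  bg_af_tot <- max(0, 1 - novel_tot - sum(prop_af_known))
  bg_am_tot <- max(0, 1 - novel_tot - sum(prop_am_known))

  origins <- tibble(
    origin_id = c(known$id, novel$id,
                  sprintf("bg-%s-%02d", bg$class, seq_len(nrow(bg)))),
    class = c(rep("known_miRNA", nrow(known)), rep("novel", nrow(novel)),
              bg$class),
    prop_AF = c(prop_af_known, novel_prop,
                rep(bg_af_tot / nrow(bg), nrow(bg))),
    prop_AM = c(prop_am_known, novel_prop,
                rep(bg_am_tot / nrow(bg), nrow(bg)))
  )
  names(origins)[3:4] <- paste0("prop_", libs)

  depth <- cfg$depth_per_library
  draw <- function(p) {
    if (depth == 0) return(integer(length(p)))
    as.integer(rmultinom(1, depth, p))
  }
  counts <- lapply(setNames(libs, libs),
                   function(l) draw(origins[[paste0("prop_", l)]]))

  # expand origins into tag variants (isomiR jitter for miRNA origins) ---
  all_draws <- list()
  for (l in libs) {
    cnt <- counts[[l]]
    rows <- which(cnt > 0)
    pieces <- lapply(rows, function(i) {
      oid <- origins$origin_id[i]
      ci <- match(oid, catalog$id)
      if (!is.na(ci) && cfg$isomir_jitter > 0) {
        v <- isomir_variants(catalog$mature[ci], catalog$precursor[ci],
                             cfg$isomir_jitter)
        k <- as.integer(rmultinom(1, cnt[i], v$prob))
        tibble(library = l, origin_id = oid, sequence = v$sequence, count = k) |>
          filter(.data$count > 0)
      } else {
        seqi <- if (!is.na(ci)) catalog$mature[ci]
                else bg$sequence[match(oid, sprintf("bg-%s-%02d", bg$class,
                                                    seq_len(nrow(bg))))]
        tibble(library = l, origin_id = oid, sequence = seqi, count = cnt[i])
      }
    })
    all_draws[[l]] <- bind_rows(pieces)
  }
  draws <- bind_rows(all_draws)

  # raw reads: insert + full 3' adapter, dummy qualities
  reads <- if (nrow(draws) == 0) {
    tibble(library = character(), read_id = character(),
           sequence = character(), quality = character())
  } else {
    idx <- rep(seq_len(nrow(draws)), draws$count)
    tibble(library = draws$library[idx],
           sequence = paste0(draws$sequence[idx], cfg$adapter)) |>
      group_by(.data$library) |>
      mutate(read_id = sprintf("%s_read_%06d", .data$library, row_number())) |>
      ungroup() |>
      mutate(quality = strrep("I", nchar(.data$sequence))) |>
      select("library", "read_id", "sequence", "quality")
  }

  truth <- origins
  for (l in libs) {
    truth[[paste0("expected_", l)]] <- origins[[paste0("prop_", l)]] * depth
    truth[[paste0("count_", l)]] <- counts[[l]]
  }
  truth$designed_ratio <- NA_real_
  ki <- match(known$id, truth$origin_id)
  truth$designed_ratio[ki] <-
    (origins[[paste0("prop_", libs[1])]][ki] /
       origins[[paste0("prop_", libs[2])]][ki])

  structure(list(reads = reads, truth = truth, draws = draws),
            class = "synthetic_reads")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_mirna_catalog()],
#' [generate_genome()] and [simulate_libraries()] under one configuration.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `synthetic_study` with elements `config`, `catalog`,
#'   `genome`, `reads` (a `synthetic_reads`).
#' @export
#' @examples
#' study <- synthetic_study(synthetic_config(seed = 1, depth_per_library = 2e3))
#' nrow(study$reads$reads)
synthetic_study <- function(cfg = synthetic_config()) {
  catalog <- generate_mirna_catalog(cfg)
  genome <- generate_genome(cfg, catalog)
  reads <- simulate_libraries(cfg, catalog, genome)
  structure(list(config = cfg, catalog = catalog, genome = genome,
                 reads = reads),
            class = "synthetic_study")
}

#' Simulate 3'UTR sequences with planted miRNA target sites
#'
#' Builds random UTR sequences and plants perfect-complement sites for a
#' subset of catalog matures, providing a truth table for target scanning.
#' A synthetic stand-in for real annotated 3'UTRs.
#'
#' @param catalog catalog from [generate_mirna_catalog()].
#' @param n_utrs number of UTR sequences.
#' @param utr_length UTR length in nt.
#' @param mirna_ids matures to plant (default: every catalog id).
#' @param seed integer seed.
#' @return list: `utrs` (tibble: id, sequence), `truth` (tibble: utr id,
#'   mirna id, 0-based half-open site interval).
#' @export
simulate_utrs <- function(catalog, n_utrs = 10L, utr_length = 400L,
                          mirna_ids = catalog$id, seed = 1L) {
  set.seed(seed + 404L)
  utrs <- tibble(id = sprintf("utr-%03d", seq_len(n_utrs)),
                 sequence = vapply(rep(utr_length, n_utrs), random_dna,
                                   character(1), gc = 0.4))
  planted <- list()
  for (k in seq_along(mirna_ids)) {
    ui <- (k - 1L) %% n_utrs + 1L
    m <- catalog$mature[match(mirna_ids[k], catalog$id)]
    site <- revcomp(m)
    s0 <- 30L + ((k - 1L) %/% n_utrs) * 60L
    if (s0 + nchar(site) > utr_length - 10L) next
    seqs <- utrs$sequence[ui]
    substr(seqs, s0 + 1L, s0 + nchar(site)) <- site
    utrs$sequence[ui] <- seqs
    planted[[length(planted) + 1L]] <-
      tibble(utr = utrs$id[ui], mirna = mirna_ids[k],
             start = s0, end = s0 + nchar(site))
  }
  list(utrs = utrs, truth = bind_rows(planted))
}
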