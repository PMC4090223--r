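test_that("candidate selection applies the hit-count and class filters", {
  cls <- tibble::tibble(
    sequence = c("a", "b", "c", "d", "e"),
    class = c("unannotated", "unannotated", "unannotated", "tRNA",
              "known_miRNA"),
    feature_id = NA_character_,
    n_hits = c(1L, 11L, 0L, 1L, 1L),
    over_threshold = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  kept <- select_candidate_tags(cls, max_hits = 10)
  expect_equal(kept$sequence, "a")
  # boundary: exactly 10 hits is retained, 11 is not
  cls$n_hits[2] <- 10L
  expect_equal(select_candidate_tags(cls)$sequence, c("a", "b"))
})

test_that("flank extraction clips at chromosome ends and handles strand", {
  tag <- "GATTACAGGCATTGCAATCCGA"
  genome <- c(chr1 = paste0(tag, strrep("A", 400), revcomp(tag),
                            strrep("C", 400)))
  idx <- build_genome_index(genome)
  tags <- tibble::tibble(sequence = tag, count_AF = 1L, count_AM = 0L)
  map <- map_tags(tags, idx)
  cand <- tibble::tibble(sequence = tag)
  # first hit in coordinate order is the plus-strand copy at position 0:
  # no upstream flank available
  w <- extract_flanks(cand, map, genome, flank = 150)
  expect_equal(w$window_start, 0L)
  expect_equal(nchar(w$window), nchar(tag) + 150L)
  expect_equal(w$tag_offset, 0L)
  expect_equal(substr(w$window, 1, nchar(tag)), tag)
  # a minus-strand-only tag appears verbatim in its window
  tag2 <- revcomp(tag)   # occurs at the minus copy only... both strands map;
  # instead plant a distinct minus-strand tag mid-chromosome
  tagm <- "TTGGCCAATTCCGGAATTGGCA"
  genome2 <- c(chr1 = paste0(strrep("G", 300), revcomp(tagm),
                             strrep("T", 300)))
  map2 <- map_tags(tibble::tibble(sequence = tagm, count_AF = 1L,
                                  count_AM = 0L),
                   build_genome_index(genome2))
  expect_equal(map2$hits$strand, "-")
  w2 <- extract_flanks(tibble::tibble(sequence = tagm), map2, genome2)
  expect_equal(nchar(w2$window), nchar(tagm) + 300L)
  expect_true(grepl(tagm, w2$window, fixed = TRUE))
  expect_equal(substr(w2$window, w2$tag_offset + 1,
                      w2$tag_offset + nchar(tagm)), tagm)
})

test_that("hairpin evaluation applies the stem, length and MFE criteria", {
  # designed strong hairpin: 22 nt tag on the 5' arm of a perfect stem
  tag <- "GCGGATCCATTGCAACGGTATC"
  window <- paste0(strrep("A", 40), tag, "TTAATTTT", revcomp(tag),
                   strrep("A", 40))
  off <- 40L
  ev <- evaluate_hairpin(window, tag, off)
  expect_true(ev$in_stem)
  expect_true(ev$length_ok)
  expect_true(ev$mfe_ok)
  expect_true(ev$verdict)
  # 19 nt tag, otherwise perfect -> length gate fails, verdict false
  tag19 <- substr(tag, 1, 19)
  window19 <- paste0(strrep("A", 40), tag19, "TTAATTTT", revcomp(tag19),
                     strrep("A", 40))
  ev19 <- evaluate_hairpin(window19, tag19, 40L)
  expect_false(ev19$length_ok)
  expect_false(ev19$verdict)
  # a weakly folding window fails the -20 kcal/mol gate
  weak_tag <- "ACCGGAAAAAAAAAAAAAAGGA"   # mostly unpairable against poly-A
  weak <- paste0(strrep("A", 30), weak_tag, strrep("A", 30))
  evw <- evaluate_hairpin(weak, weak_tag, 30L)
  expect_gt(evw$mfe, -20)
  expect_false(evw$mfe_ok)
  expect_false(evw$verdict)
  # offset mismatch is an error
  expect_error(evaluate_hairpin(window, tag, 10L), "tag_offset")
})

test_that("the MFEI flag is reported separately unless strict mode is on", {
  tag <- "GCGGATCCATTGCAACGGTATC"
  window <- paste0(strrep("A", 40), tag, "TTAATTTT", revcomp(tag),
                   strrep("A", 40))
  ev <- evaluate_hairpin(window, tag, 40L)
  ev_strict <- evaluate_hairpin(window, tag, 40L, strict_mfei = TRUE)
  expect_equal(ev$mfei, ev_strict$mfei)
  expect_equal(ev_strict$verdict, ev_strict$verdict && ev_strict$mfei_ok)
})

test_that("the discovery pipeline recovers spiked hairpins and only them from the catalog side", {
  fix <- tiny_classified()
  study <- fix$study
  novel <- novel_candidates(fix$classified, fix$tags, fix$map, study$genome)
  # every spiked hairpin is recovered by at least one passing tag
  spiked <- study$reads$draws |>
    dplyr::filter(grepl("^novel", origin_id)) |>
    dplyr::distinct(origin_id, sequence)
  rec <- spiked |>
    dplyr::left_join(novel, by = "sequence") |>
    dplyr::group_by(origin_id) |>
    dplyr::summarise(hit = any(verdict, na.rm = TRUE))
  expect_true(all(rec$hit))
  # disjointness with the known catalog
  known_tags <- fix$classified$sequence[fix$classified$class == "known_miRNA"]
  expect_equal(length(intersect(novel$sequence, known_tags)), 0L)
  # table is coordinate-sorted and carries counts
  expect_true(!is.unsorted(novel$start[novel$chrom == "chr1"]))
  expect_true(all(c("count_AF", "count_AM") %in% names(novel)))
})

test_that("no unannotated tags yields an empty candidate table", {
  cls <- tibble::tibble(sequence = character(), class = character(),
                        feature_id = character(), n_hits = integer(),
                        over_threshold = logical())
  tags <- tibble::tibble(sequence = character(), count_AF = integer(),
                         count_AM = integer())
  map <- structure(list(hits = tibble::tibble(
    sequence = character(), chrom = character(), start = integer(),
    end = integer(), strand = character()),
    tag_hits = tibble::tibble(sequence = character(), n_hits = integer(),
                              over_threshold = logical()),
    max_hits = 10L), class = "mir_map")
  out <- novel_candidates(cls, tags, map, c(chr1 = strrep("ACGT", 100)))
  expect_equal(nrow(out), 0)
})
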