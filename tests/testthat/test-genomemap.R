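test_that("index construction validates the alphabet", {
  expect_error(build_genome_index(c(chr1 = "ACGTNNACGT")), "non-ACGT")
  idx <- build_genome_index(c(chr1 = strrep("ACGT", 100)))
  expect_s3_class(idx, "genome_index")
})

test_that("exact mapping finds planted tags on both strands", {
  set.seed(8)
  backbone <- random_rna(600, c("A", "C", "G", "T"))
  tag <- "ATCGGATTACAGGCATTGCAAT"
  genome <- c(chr1 = paste0(substr(backbone, 1, 200), tag,
                            substr(backbone, 201, 400), revcomp(tag),
                            substr(backbone, 401, 600)))
  idx <- build_genome_index(genome)
  map <- map_tags(tag, idx)
  expect_equal(nrow(map$hits), 2)
  plus <- map$hits[map$hits$strand == "+", ]
  expect_equal(plus$start, 200)
  expect_equal(plus$end, 200 + nchar(tag))
  minus <- map$hits[map$hits$strand == "-", ]
  expect_equal(minus$start, 200 + nchar(tag) + 200)
  # an absent random 30-mer maps nowhere (absence confirmed by brute scan)
  probe <- strrep("ACTG", 8)
  stopifnot(!grepl(probe, genome), !grepl(revcomp(probe), genome))
  expect_equal(map_tags(probe, idx)$tag_hits$n_hits, 0L)
})

test_that("repeat-embedded tags are counted fully and flagged over threshold", {
  tag <- "GGATCCATTGCAACGGTATCGA"
  spacer <- strrep("T", 30)
  genome <- c(chr1 = paste0(paste(rep(paste0(tag, spacer), 12), collapse = ""),
                            strrep("C", 50)))
  idx <- build_genome_index(genome)
  map <- map_tags(tag, idx, max_hits = 10)
  # brute-force occurrence count agrees
  brute <- length(gregexpr(tag, genome, fixed = TRUE)[[1]])
  expect_equal(map$tag_hits$n_hits, brute)
  expect_equal(map$tag_hits$n_hits, 12L)
  expect_true(map$tag_hits$over_threshold)
})

test_that("the annotation cascade assigns exactly one class in priority order", {
  study <- tiny_study()
  fix <- tiny_classified()
  cls <- fix$classified
  expect_equal(nrow(cls), nrow(fix$tags))
  expect_true(all(table(cls$sequence) == 1))
  # catalog matures classify as known_miRNA (perfect-match rule)
  known <- study$catalog[study$catalog$type == "known", ]
  in_tags <- intersect(known$mature, cls$sequence)
  expect_gt(length(in_tags), 0)
  expect_true(all(cls$class[cls$sequence %in% in_tags] == "known_miRNA"))
  # truth background tags land in their own class
  truth <- study$reads$draws |>
    dplyr::distinct(origin_id, sequence) |>
    dplyr::filter(grepl("^bg-rRNA", origin_id))
  got <- cls$class[cls$sequence %in% truth$sequence]
  expect_true(all(got == "rRNA"))
  # input order invariance
  perm <- sample(nrow(fix$tags))
  cls2 <- classify_tags(fix$tags[perm, ], fix$map,
                        study$genome$annotations, study$catalog)
  expect_equal(dplyr::arrange(cls2, sequence), dplyr::arrange(cls, sequence))
})

test_that("overlapping repeat and exon intervals resolve to repeat", {
  tag <- "CAGTTACGGATCTTAGCCAATG"
  genome <- c(chr1 = paste0(strrep("A", 100), tag, strrep("A", 100)))
  idx <- build_genome_index(genome)
  tags <- tibble::tibble(sequence = tag, count_AF = 1L, count_AM = 0L)
  map <- map_tags(tags, idx)
  ann <- tibble::tibble(chrom = "chr1", start = c(95L, 105L),
                        end = c(130L, 140L), class = c("exon", "repeat"),
                        name = c("e1", "r1"), strand = "+")
  cls <- classify_tags(tags, map, ann, tibble::tibble(id = character(),
                                                      mature = character(),
                                                      precursor = character(),
                                                      mature_start = integer(),
                                                      mature_end = integer()))
  expect_equal(cls$class, "repeat")
  # with no annotations at all the tag is unannotated
  cls2 <- classify_tags(tags, map, ann[0, ], tibble::tibble(
    id = character(), mature = character(), precursor = character(),
    mature_start = integer(), mature_end = integer()))
  expect_equal(cls2$class, "unannotated")
})

test_that("class totals partition the tag table on both bases", {
  fix <- tiny_classified()
  dist <- class_distribution(fix$classified, fix$tags)
  expect_equal(sum(dist$unique_tags), nrow(fix$tags))
  cols <- grep("^count_", names(fix$tags), value = TRUE)
  expect_equal(sum(dist$total_reads),
               sum(sapply(fix$tags[cols], sum)))
  expect_equal(sum(dist$unique_pct), 100, tolerance = 1e-9)
  expect_equal(sum(dist$total_pct), 100, tolerance = 1e-9)
})

test_that("isomiR tags sum onto their miRNA and zero-count entries persist", {
  catalog <- tibble::tibble(
    id = c("mir-x", "mir-y"), type = "known",
    mature = c("ACGGATTCAGGCAATCGGATCA", "TTGACCGGTATTCCGGAACCAT"),
    precursor = c(paste0("ACGGATTCAGGCAATCGGATCA", "TTTTTTTT",
                         revcomp("ACGGATTCAGGCAATCGGATCA")),
                  paste0("TTGACCGGTATTCCGGAACCAT", "TTTTTTTT",
                         revcomp("TTGACCGGTATTCCGGAACCAT"))),
    mature_start = 1L, mature_end = 22L)
  tags <- tibble::tibble(
    sequence = c(catalog$mature[1], substr(catalog$mature[1], 1, 21)),
    count_AF = c(30L, 12L), count_AM = c(0L, 1L))
  genome <- c(chr1 = paste0(strrep("A", 50), catalog$precursor[1],
                            strrep("A", 50)))
  map <- map_tags(tags, build_genome_index(genome))
  cls <- classify_tags(tags, map, tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    class = character(), name = character(), strand = character()), catalog)
  q <- quantify_known_mirnas(cls, tags, catalog)
  expect_equal(q$count_AF[q$id == "mir-x"], 42L)
  expect_equal(q$count_AM[q$id == "mir-x"], 1L)
  expect_equal(q$count_AF[q$id == "mir-y"], 0L)
  expect_equal(nrow(q), 2)
})
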