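test_that("adapter trimming removes the longest adapter prefix", {
  out <- trim_adapter("ACGTACGTACGTACGTACGTTGGAATTC", "TGGAATTCTCGG")
  expect_equal(out$status, "trimmed")
  expect_equal(out$insert, "ACGTACGTACGTACGTACGT")
  # read consisting of adapter prefix only -> empty insert, rejected
  out2 <- trim_adapter("TGGAATTCTC", "TGGAATTCTCGG")
  expect_equal(out2$status, "empty_insert")
  expect_true(is.na(out2$insert))
  # no overlap at all
  out3 <- trim_adapter("ACGTACGTACGTACGT", "TGGAATTCTCGG")
  expect_equal(out3$status, "no_adapter")
  expect_equal(trim_adapter("", "TGGAATTCTCGG")$status, "empty_read")
})

test_that("one mismatch is tolerated within the adapter overlap", {
  insert <- "ACGTACGTACGTACGTACGT"
  adapter <- "TGGAATTCTCGG"
  # 8 nt overlap with one mismatch (G -> C at overlap position 3)
  read <- paste0(insert, "TGCAATTC")
  out <- trim_adapter(read, adapter)
  expect_equal(out$status, "trimmed")
  expect_equal(out$insert, insert)
  # enumerate overlaps by hand: the longest overlap within 1 mismatch is 8
  a <- strsplit(adapter, "")[[1]]; r <- strsplit(read, "")[[1]]
  best <- max(Filter(function(o)
    sum(r[(length(r) - o + 1):length(r)] != a[1:o]) <= 1,
    6:min(nchar(adapter), nchar(read))))
  expect_equal(best, 8)
  # two mismatches are too many
  out2 <- trim_adapter(paste0(insert, "TCCAATTC"), adapter)
  expect_equal(out2$status, "no_adapter")
})

test_that("cleaning filters by insert length and N content and conserves reads", {
  adapter <- "TGGAATTCTCGG"
  mk <- function(ins) paste0(ins, adapter)
  reads <- tibble::tibble(
    library = "AF",
    sequence = c(replicate(90, mk(random_rna(22, c("A", "C", "G", "T")))),
                 replicate(10, mk(random_rna(10, c("A", "C", "G", "T")))),
                 mk(strrep("A", 31)),
                 mk(paste0("ACGTNACGTACGTACGTACGT"))))
  cl <- clean_reads(reads, adapter)
  expect_equal(cl$stats$raw_reads, 102)
  expect_equal(cl$stats$clean_reads, 90)
  expect_equal(sum(cl$rejects$n[cl$rejects$reason == "too_short"]), 10)
  expect_equal(sum(cl$rejects$n[cl$rejects$reason == "too_long"]), 1)
  expect_equal(sum(cl$rejects$n[cl$rejects$reason == "contains_N"]), 1)
  # conservation: raw = clean + rejected
  expect_equal(cl$stats$raw_reads,
               cl$stats$clean_reads + sum(cl$rejects$n))
})

test_that("low-quality reads are dropped when qualities exist", {
  adapter <- "TGGAATTCTCGG"
  ins <- strrep("ACGT", 5)
  reads <- tibble::tibble(
    library = "AF",
    sequence = rep(paste0(ins, adapter), 2),
    quality = c(strrep("I", 32),
                paste0(strrep("#", 10), strrep("I", 22))))  # '#' = Phred 2
  cl <- clean_reads(reads, adapter)
  expect_equal(cl$stats$clean_reads, 1)
  expect_equal(cl$rejects$reason, "low_quality")
})

test_that("tag collapsing conserves counts and round-trips", {
  reads <- tibble::tibble(
    library = c(rep("AF", 5), rep("AM", 4)),
    sequence = c(rep(strrep("AC", 11), 3), rep(strrep("GT", 10), 2),
                 rep(strrep("AC", 11), 2), rep(strrep("TG", 10), 2)))
  tags <- collapse_tags(reads)
  expect_equal(nrow(tags), 3)
  expect_equal(sum(tags$count_AF), 5)
  expect_equal(sum(tags$count_AM), 4)
  shared <- tags[tags$sequence == strrep("AC", 11), ]
  expect_equal(shared$count_AF, 3); expect_equal(shared$count_AM, 2)
  # expand back to a read multiset and re-collapse: identity
  expanded <- tibble::tibble(
    library = c(rep("AF", sum(tags$count_AF)), rep("AM", sum(tags$count_AM))),
    sequence = c(rep(tags$sequence, tags$count_AF),
                 rep(tags$sequence, tags$count_AM)))
  expect_equal(collapse_tags(expanded), tags)
  # identical libraries -> equal counts everywhere
  same <- tibble::tibble(library = rep(c("AF", "AM"), each = 3),
                         sequence = rep(c(strrep("A", 20), strrep("C", 20),
                                          strrep("G", 20)), 2))
  t2 <- collapse_tags(same)
  expect_true(all(t2$count_AF == t2$count_AM))
})

test_that("overlap percentages partition on both bases", {
  tags <- tibble::tibble(sequence = c("s1", "s2", "s3"),
                         count_AF = c(4L, 6L, 0L),
                         count_AM = c(1L, 0L, 9L))
  ov <- overlap_stats(tags)
  expect_equal(ov$common_pct + ov$AF_specific_pct + ov$AM_specific_pct,
               c(100, 100))
  # hand counts: 1 of 3 unique shared; 5 of 20 reads in the shared tag
  expect_equal(ov$common_pct, c(100 / 3, 25))
  expect_equal(ov$AF_specific_pct, c(100 / 3, 30))
  # identical libraries
  ident <- tibble::tibble(sequence = "s", count_AF = 3L, count_AM = 3L)
  expect_equal(overlap_stats(ident)$common_pct, c(100, 100))
  # disjoint libraries
  disj <- tibble::tibble(sequence = c("a", "b"),
                         count_AF = c(2L, 0L), count_AM = c(0L, 5L))
  expect_equal(overlap_stats(disj)$common_pct, c(0, 0))
})

test_that("length distribution percentages sum to 100 per library", {
  tags <- tibble::tibble(sequence = c(strrep("A", 22), strrep("C", 22),
                                      strrep("G", 24)),
                         count_AF = c(7L, 3L, 0L), count_AM = c(0L, 0L, 5L))
  ld <- length_distribution(tags)
  sums <- tapply(ld$pct, ld$library, sum)
  expect_equal(as.numeric(sums), c(100, 100))
  expect_equal(ld$pct[ld$library == "AF" & ld$length == 22], 100)
  # empty input does not crash
  expect_equal(nrow(length_distribution(tags[0, ])), 0)
})
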