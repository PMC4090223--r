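test_that("a fixed seed reproduces the study byte-for-byte", {
  cfg <- synthetic_config(seed = 7, genome_length = 15000, n_known_mirnas = 6,
                          n_novel_hairpins = 2, depth_per_library = 500)
  s1 <- synthetic_study(cfg)
  s2 <- synthetic_study(cfg)
  expect_identical(s1$genome$genome, s2$genome$genome)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$reads$reads, s2$reads$reads)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_study(s1, d1)
  write_synthetic_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})

test_that("requested feature counts are honoured and classes stay disjoint", {
  cfg <- synthetic_config(seed = 3, genome_length = 20000,
                          n_known_mirnas = 10, n_novel_hairpins = 0,
                          depth_per_library = 0)
  g <- generate_genome(cfg)
  expect_equal(sum(g$mirna_loci$type == "known"), 10)
  # no annotation interval overlaps a miRNA locus
  for (i in seq_len(nrow(g$mirna_loci))) {
    ov <- g$annotations$start < g$mirna_loci$end[i] &
      g$annotations$end > g$mirna_loci$start[i]
    expect_false(any(ov))
  }
  # all intervals within genome bounds, half-open and non-empty
  expect_true(all(g$annotations$start >= 0))
  expect_true(all(g$annotations$end <= cfg$genome_length))
  expect_true(all(g$annotations$end > g$annotations$start))
})

test_that("genome GC content tracks the configured fraction", {
  cfg <- synthetic_config(seed = 5, genome_length = 100000, gc_content = 0.5)
  g <- generate_genome(cfg)
  gc <- gc_fraction(g$genome[["chr1"]])
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
})

test_that("a genome too short for the requested features names the deficit", {
  cfg <- synthetic_config(seed = 1, genome_length = 10000,
                          n_known_mirnas = 40, n_novel_hairpins = 10)
  expect_error(generate_genome(cfg), "genome too short")
})

test_that("catalog precursors are foldable stem-loops containing the mature", {
  cat <- generate_mirna_catalog(tiny_config())
  expect_true(all(mapply(grepl, cat$mature, cat$precursor, fixed = TRUE)))
  expect_true(all(nchar(cat$mature) >= 20 & nchar(cat$mature) <= 23))
  expect_true(all(nchar(cat$precursor) >= 48 & nchar(cat$precursor) <= 90))
  for (i in seq_len(nrow(cat))) {
    expect_lt(fold_hairpin(cat$precursor[i])$mfe, 0)
  }
})

test_that("designed fold changes are recovered within sampling error", {
  cfg <- synthetic_config(seed = 11, fold_change_spec = c("mir-001" = 32),
                          depth_per_library = 1e5, isomir_jitter = 0)
  sim <- simulate_libraries(cfg)
  tr <- sim$truth
  row <- tr[tr$origin_id == "mir-001", ]
  expect_equal(row$prop_AF / row$prop_AM, 32, tolerance = 1e-9)
  # empirical count ratio within 3 SE of the design (delta method on log)
  se_log <- sqrt(1 / row$expected_AF + 1 / row$expected_AM)
  expect_lt(abs(log(row$count_AF / row$count_AM) - log(32)), 3 * se_log)
})

test_that("background_fraction zero with no novels leaves only catalog reads", {
  cfg <- synthetic_config(seed = 2, background_fraction = 0,
                          n_novel_hairpins = 0, novel_fraction = 0,
                          depth_per_library = 2000)
  sim <- simulate_libraries(cfg)
  expect_true(all(sim$truth$class[sim$truth$count_AF +
                                    sim$truth$count_AM > 0] == "known_miRNA"))
})

test_that("zero depth yields empty libraries with a valid empty truth", {
  cfg <- synthetic_config(seed = 2, depth_per_library = 0)
  sim <- simulate_libraries(cfg)
  expect_equal(nrow(sim$reads), 0)
  expect_true(all(sim$truth$count_AF == 0 & sim$truth$count_AM == 0))
})

test_that("truth counts conserve the simulated depth", {
  sim <- tiny_study()$reads
  depth <- tiny_config()$depth_per_library
  expect_equal(sum(sim$truth$count_AF), depth)
  expect_equal(sum(sim$truth$count_AM), depth)
  # per-variant draws aggregate back to the origin counts
  agg <- dplyr::count(sim$draws, library, origin_id, wt = count)
  expect_equal(sum(agg$n), 2 * depth)
})

test_that("simulated read lengths concentrate at the 22 nt mode", {
  study <- tiny_study()
  clean <- clean_reads(study$reads$reads, study$config$adapter)
  tags <- collapse_tags(clean)
  ld <- length_distribution(tags)
  for (l in unique(ld$library)) {
    sub <- ld[ld$library == l, ]
    expect_equal(sub$length[which.max(sub$count)], 22)
  }
})

test_that("planted UTR sites contain the exact complement of the mature", {
  cat <- generate_mirna_catalog(tiny_config())
  u <- simulate_utrs(cat[cat$type == "known", ], n_utrs = 4, seed = 9)
  expect_gt(nrow(u$truth), 0)
  for (i in seq_len(nrow(u$truth))) {
    tr <- u$truth[i, ]
    site <- substr(u$utrs$sequence[u$utrs$id == tr$utr],
                   tr$start + 1, tr$end)
    m <- cat$mature[cat$id == tr$mirna]
    expect_equal(site, revcomp(m))
  }
})
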