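# lazily-built shared fixtures; each is computed once per test run
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# small study: 12 known miRNAs, 4 spiked hairpins, 2000 reads per library
tiny_config <- function() {
  synthetic_config(seed = 42, genome_length = 20000, n_known_mirnas = 12,
                   n_novel_hairpins = 4, depth_per_library = 2000)
}

tiny_study <- function() memo("tiny_study", function() {
  synthetic_study(tiny_config())
})

# tiny study pushed through the mapping/classification stages
tiny_classified <- function() memo("tiny_classified", function() {
  study <- tiny_study()
  clean <- clean_reads(study$reads$reads, study$config$adapter)
  tags <- collapse_tags(clean)
  index <- build_genome_index(study$genome)
  map <- map_tags(tags, index)
  list(study = study, clean = clean, tags = tags, map = map,
       classified = classify_tags(tags, map, study$genome$annotations,
                                  study$catalog))
})

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# pair-state vector of given length with opens/GUs at chosen positions
make_states <- function(L, open = integer(), gu = integer()) {
  s <- rep("WC", L)
  s[open] <- "open"
  s[gu] <- "GU"
  s
}
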