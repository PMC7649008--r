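# Shared fixture builders, cached per test run.  All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

rnd_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else scafmend:::with_seed(seed, draw())
}

# zero-noise fixture on the non-palindromic BspQI channel, mixed contig
# orientations; every overlap resolvable (no tiny class)
exact_fixture <- function() {
  cached("exact", {
    spec <- fixture_spec(
      genome_length = 3e6, seed = 11, n_gap_junctions = 4,
      n_overlap_junctions = 4,
      overlap_classes = c(labelled = 0.5, alignable = 0.5, tiny = 0),
      n_contained = 2, motifs = "GCTCTTC", label_noise_sd = 0,
      label_fn_rate = 0, label_fp_rate = 0, reverse_fraction = 0.4)
    fx <- simulate_fixture(spec)
    res <- build_scaffolds(fx$contigs, fx$key, fx$contig_maps,
                           fx$anchor_maps, fx$alignments)
    list(fx = fx, res = res, out = render_scaffolds(res))
  })
}

# two-channel fixture with the default motifs, mild noise, all junction
# classes represented
default_fixture <- function() {
  cached("default", {
    spec <- fixture_spec(genome_length = 4e6, seed = 5,
                         n_gap_junctions = 5, n_overlap_junctions = 5,
                         n_contained = 2, label_fn_rate = 0,
                         label_fp_rate = 0)
    fx <- simulate_fixture(spec)
    res <- build_scaffolds(fx$contigs, fx$key, fx$contig_maps,
                           fx$anchor_maps, fx$alignments)
    list(fx = fx, res = res, out = render_scaffolds(res))
  })
}

# expected scaffold sequence for a fixture whose gap estimates are exact:
# the genome span with every true gap N-masked
masked_genome_expectation <- function(fx) {
  tr <- fx$truth
  cd <- tr$contigs[tr$contigs$role == "linear", ]
  gstart <- cd$genome_start[1L]
  expect <- substr(fx$genome, gstart, cd$genome_end[nrow(cd)])
  for (i in seq_len(nrow(tr$junctions))) {
    if (tr$junctions$type[i] != "gap") next
    li <- match(tr$junctions$left[i], cd$name)
    a <- cd$genome_end[li] + 1L - gstart + 1L
    b <- cd$genome_start[li + 1L] - 1L - gstart + 1L
    substr(expect, a, b) <- strrep("N", b - a + 1L)
  }
  expect
}

# junction report row for a truth junction
report_row <- function(report, left, right) {
  report[report$left == left & report$right == right, , drop = FALSE]
}

# independent Smith-Waterman oracle under the package's unit scheme
# (match +1 / mismatch -1 / gap open 1 + 1 per base), via Biostrings
sw_oracle_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = 1, gapExtension = 1)))
}
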