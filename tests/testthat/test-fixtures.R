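test_that("genome generation is seeded, validated, and near-uniform", {
  g1 <- generate_genome(100, seed = 1)
  g2 <- generate_genome(100, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(100, seed = 2)))
  expect_error(generate_genome(0), "> 0")

  g <- generate_genome(1e6, seed = 3)
  freq <- table(strsplit(g, "")[[1L]]) / 1e6
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("digestion matches a brute-force scan and handles palindromes", {
  expect_equal(digest_sequence("AACTTAAGTT", "CTTAAG"), 3L)
  expect_length(digest_sequence("AAAAAA", "CTTAAG"), 0L)
  expect_error(digest_sequence("ACGT", ""), "non-empty")

  # brute-force oracle: sliding window over both strands with the same
  # strand-aware site convention
  brute <- function(s, motif) {
    m <- nchar(motif); n <- nchar(s)
    rc <- scafmend:::revcomp(motif)
    pos <- integer(0)
    for (i in seq_len(n - m + 1L)) {
      w <- substr(s, i, i + m - 1L)
      if (w == motif) pos <- c(pos, i)
      if (rc != motif && w == rc) pos <- c(pos, i + m - 1L)
    }
    sort(unique(pos))
  }
  set.seed(12)
  for (motif in c("CTTAAG", "GCTCTTC", "GAATGC")) {
    for (i in 1:5) {
      s <- rnd_dna(10000)
      expect_identical(digest_sequence(s, motif), brute(s, motif))
    }
  }
})

test_that("fragmentation plants the requested junctions consistently", {
  spec <- fixture_spec(genome_length = 2e6, seed = 3, n_gap_junctions = 2,
                       gap_size_range = c(1000, 1000),
                       n_overlap_junctions = 0, n_contained = 0)
  genome <- generate_genome(2e6, 3)
  fr <- fragment_genome(genome, spec)
  expect_equal(nrow(fr$truth$contigs), 3L)
  expect_equal(fr$truth$junctions$true_size, c(1000, 1000))
  cd <- fr$truth$contigs
  holes <- cd$genome_start[-1L] - cd$genome_end[-nrow(cd)] - 1L
  expect_equal(holes, c(1000, 1000))

  # conservation: contig lengths - overlaps + gaps span the genome
  spec2 <- fixture_spec(genome_length = 4e6, seed = 5, n_gap_junctions = 4,
                        n_overlap_junctions = 4, n_contained = 0)
  fr2 <- fragment_genome(generate_genome(4e6, 5), spec2)
  tr <- fr2$truth
  lens <- tr$contigs$genome_end - tr$contigs$genome_start + 1
  gaps <- sum(tr$junctions$true_size[tr$junctions$type == "gap"])
  ovs <- sum(tr$junctions$true_size[tr$junctions$type == "overlap"])
  expect_equal(sum(lens) - ovs + gaps,
               tr$contigs$genome_end[nrow(tr$contigs)] -
                 tr$contigs$genome_start[1L] + 1)

  # contigs are exact (oriented) genome subsequences
  fx <- simulate_fixture(spec2)
  for (i in seq_len(nrow(tr$contigs))) {
    cdi <- tr$contigs[i, ]
    want <- substr(fx$genome, cdi$genome_start, cdi$genome_end)
    if (cdi$strand == "-") want <- scafmend:::revcomp(want)
    expect_identical(unname(fx$contigs[[cdi$name]]), want)
  }

  expect_error(fragment_genome(generate_genome(5e4, 1),
                               fixture_spec(genome_length = 5e4, seed = 1)),
               "infeasible")
})

test_that("the anchor bundle is noiseless-consistent and parser-clean", {
  spec <- fixture_spec(genome_length = 2e6, seed = 9, n_gap_junctions = 2,
                       n_overlap_junctions = 2,
                       overlap_classes = c(labelled = 1, alignable = 0,
                                           tiny = 0),
                       n_contained = 0, motifs = "GCTCTTC",
                       label_noise_sd = 0, label_fn_rate = 0,
                       label_fp_rate = 0, reverse_fraction = 0)
  fx <- simulate_fixture(spec)
  anchor <- fx$anchor_maps[["1"]][["1"]]
  apos <- scafmend:::map_positions(anchor, 1L)
  # zero noise, forward contigs: every pair's anchor position equals the
  # contig position plus the contig's genome offset
  for (al in fx$alignments) {
    nm <- fx$key$component_name[match(al$query_map_id,
                                      fx$key$component_id)]
    cdi <- fx$truth$contigs[fx$truth$contigs$name == nm, ]
    cmap <- fx$contig_maps[["1"]][[as.character(al$query_map_id)]]
    qpos <- scafmend:::map_positions(cmap, 1L)
    for (r in seq_len(nrow(al$pairs))) {
      a_p <- apos[[as.character(al$pairs[r, 1L])]]
      q_p <- qpos[[as.character(al$pairs[r, 2L])]]
      expect_equal(a_p, q_p + cdi$genome_start - 1)
    }
  }

  # a full write/parse round trip preserves the bundle
  dir <- tempfile("bundle"); paths <- write_fixture_bundle(fx, dir)
  key2 <- parse_key(paths$key)
  expect_equal(key2$component_name, fx$key$component_name)
  cm2 <- parse_cmap(paths$contig_cmap_1)
  expect_equal(length(cm2), length(fx$contig_maps[["1"]]))
  for (id in names(fx$contig_maps[["1"]])) {
    expect_equal(cm2[[id]]$sites$position_bp,
                 fx$contig_maps[["1"]][[id]]$sites$position_bp)
  }
  x2 <- parse_xmap(paths$xmap_1, channel = 1L)
  expect_equal(length(x2), length(fx$alignments))
  for (i in seq_along(x2)) {
    expect_equal(x2[[i]]$pairs, fx$alignments[[i]]$pairs)
    expect_equal(x2[[i]]$orientation, fx$alignments[[i]]$orientation)
  }
})

test_that("dropping every anchor label leaves all contigs unaligned", {
  spec <- fixture_spec(genome_length = 2e6, seed = 13, n_gap_junctions = 2,
                       n_overlap_junctions = 0, n_contained = 0,
                       motifs = "CTTAAG", label_fn_rate = 1)
  fx <- simulate_fixture(spec)
  expect_length(fx$alignments, 0L)
  res <- build_scaffolds(fx$contigs, fx$key, fx$contig_maps,
                         fx$anchor_maps, fx$alignments)
  expect_length(res$plans, 0L)
  expect_setequal(res$singletons, fx$truth$contigs$name)
})

test_that("simulation is deterministic in the seed", {
  spec <- fixture_spec(genome_length = 1e6, seed = 21, n_gap_junctions = 1,
                       n_overlap_junctions = 1, n_contained = 0)
  fx1 <- simulate_fixture(spec)
  fx2 <- simulate_fixture(spec)
  expect_identical(fx1$contigs, fx2$contigs)
  expect_identical(fx1$truth$junctions, fx2$truth$junctions)
  expect_identical(
    lapply(fx1$alignments, unclass),
    lapply(fx2$alignments, unclass))
})

test_that("subseq components slice back to the planted contigs", {
  spec <- fixture_spec(genome_length = 2e6, seed = 17, n_gap_junctions = 2,
                       n_overlap_junctions = 0, n_contained = 0,
                       n_subseq = 1L, label_noise_sd = 0,
                       label_fn_rate = 0, label_fp_rate = 0)
  fx <- simulate_fixture(spec)
  sub <- grep("_subseq_", fx$key$component_name, value = TRUE)
  expect_length(sub, 1L)
  rc <- resolve_components(fx$contigs, fx$key)
  src <- sub("_subseq_.*$", "", sub)
  # the sliced component equals the contig the truth describes
  cdi <- fx$truth$contigs[fx$truth$contigs$name == src, ]
  want <- substr(fx$genome, cdi$genome_start, cdi$genome_end)
  if (cdi$strand == "-") want <- scafmend:::revcomp(want)
  expect_identical(unname(rc$seqs[[sub]]), want)
  # and the pipeline still reconstructs scaffolds from the padded FASTA
  res <- build_scaffolds(fx$contigs, fx$key, fx$contig_maps,
                         fx$anchor_maps, fx$alignments)
  out <- render_scaffolds(res)
  expect_gt(length(res$plans), 0L)
})
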