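test_that("length statistics match direct formulas on small cases", {
  s <- length_stats(c(10, 10))
  expect_equal(s$n50, 10); expect_equal(s$l50, 1L); expect_equal(s$aun, 10)

  s <- length_stats(c(30, 10))
  expect_equal(s$n50, 30); expect_equal(s$l50, 1L)
  expect_equal(s$aun, (900 + 100) / 40)

  s <- length_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$n50, 4); expect_equal(s$l50, 2L)
  expect_equal(s$n90, 2); expect_equal(s$l90, 4L)

  expect_error(length_stats(numeric(0)), "empty")
  expect_error(length_stats(c(5, 0)), "non-positive")
})

test_that("length statistics equal a brute-force cumulative-sum oracle", {
  brute <- function(lengths, x) {
    s <- sort(lengths, decreasing = TRUE)
    total <- sum(s); acc <- 0
    for (i in seq_along(s)) {
      acc <- acc + s[i]
      if (acc >= x / 100 * total) return(c(n = s[i], l = i))
    }
  }
  set.seed(31)
  for (i in 1:1000) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    st <- length_stats(lens)
    b50 <- brute(lens, 50); b90 <- brute(lens, 90)
    expect_equal(st$n50, unname(b50["n"]))
    expect_equal(st$l50, as.integer(b50["l"]))
    expect_equal(st$n90, unname(b90["n"]))
    expect_equal(st$l90, as.integer(b90["l"]))
    expect_equal(st$aun, sum(as.numeric(lens)^2) / sum(lens))
    expect_lte(st$l50, st$l90)
    expect_gte(st$n50, st$n90)
  }
})

test_that("scaffolds split into contigs at N runs with conserved bases", {
  expect_equal(scaffolds_to_contigs(c(s = "ACGTNNNACG")), c(4L, 3L))
  expect_length(scaffolds_to_contigs(c(s = "NNNN")), 0L)
  set.seed(33)
  for (i in 1:20) {
    parts <- replicate(sample(1:5, 1), rnd_dna(sample(1:50, 1)))
    gaps <- replicate(length(parts), strrep("N", sample(0:10, 1)))
    sc <- paste0(paste0(parts, gaps, collapse = ""))
    lens <- scaffolds_to_contigs(c(x = sc))
    expect_equal(sum(lens) + sum(nchar(gaps)), nchar(sc))
  }
})

test_that("the junction census aggregates decision reports", {
  rep <- data.frame(
    kind = c("fuse_at_label", "fuse_at_label", "fuse_at_label",
             "sized_gap"),
    removed_bases = c(100, 250, 50, 0))
  cen <- junction_census(rep)
  expect_equal(unname(cen$counts["fuse_at_label"]), 3L)
  expect_equal(unname(cen$counts["sized_gap"]), 1L)
  expect_equal(cen$removed_bases, 400)
  expect_equal(cen$overlap_sizes, c(100, 250, 50))

  empty <- data.frame(kind = character(), removed_bases = numeric())
  cen0 <- junction_census(empty)
  expect_true(all(cen0$counts == 0L))
  expect_equal(cen0$removed_bases, 0)
})

test_that("removed duplicated bases equal the planted overlap sizes", {
  ex <- exact_fixture()
  tr <- ex$fx$truth$junctions
  rep <- ex$res$report
  for (i in which(tr$type == "overlap")) {
    row <- report_row(rep, tr$left[i], tr$right[i])
    if (row$kind %in% c("fuse_at_label", "fuse_by_alignment")) {
      expect_equal(row$removed_bases, tr$true_size[i],
                   label = paste("overlap", tr$left[i], tr$right[i]))
    }
  }
})

test_that("junction resolution does not reduce contig-level contiguity", {
  ex <- exact_fixture()
  input_contigs <- nchar(ex$fx$contigs)
  out_contigs <- scaffolds_to_contigs(ex$out$fasta)
  expect_gte(length_stats(out_contigs)$n50,
             length_stats(input_contigs)$n50)
  # cumulative contig size decreases by exactly the removed duplicates
  expect_equal(sum(out_contigs),
               sum(input_contigs) - sum(ex$res$report$removed_bases))
})
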