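test_that("identity windows align end to end with score equal to length", {
  w <- rnd_dna(6000, 1)
  al <- local_align(w, w)
  expect_equal(al$score, 6000)
  expect_equal(c(al$a_start, al$a_end, al$b_start, al$b_end),
               c(1, 6000, 1, 6000))
  expect_equal(al$mismatches, 0)
  expect_equal(al$gap_opens, 0)
})

test_that("reverse-complement windows with no shared forward k-mers yield no alignment", {
  # construct a pair with zero shared forward 11-mers, verified directly
  set.seed(2)
  repeat {
    a <- rnd_dna(5000)
    b <- scafmend:::revcomp(a)
    kmers <- function(s, k = 11) {
      n <- nchar(s)
      unique(substring(s, 1:(n - k + 1), k:n))
    }
    if (length(intersect(kmers(a), kmers(b))) == 0L) break
  }
  expect_null(local_align(a, b))
})

test_that("a planted mismatch costs exactly two relative to identity", {
  a <- rnd_dna(150, 3)
  b <- a
  orig <- substr(a, 75, 75)
  substr(b, 75, 75) <- setdiff(c("A", "C", "G", "T"), orig)[1L]
  al <- local_align(a, b)
  expect_equal(al$score, 148)
  expect_equal(al$matches, 149)
  expect_equal(al$mismatches, 1)
  expect_equal(al$score, sw_oracle_score(a, b))
})

test_that("seed-and-extend equals full Smith-Waterman on short random pairs", {
  set.seed(4)
  for (i in 1:150) {
    a <- rnd_dna(sample(20:200, 1))
    b <- rnd_dna(sample(20:200, 1))
    mine <- local_align(a, b)
    mine <- if (is.null(mine)) 0 else mine$score
    expect_equal(as.numeric(mine), sw_oracle_score(a, b))
  }
})

test_that("alignment score is symmetric and monotone in planted overlap length", {
  set.seed(5)
  a <- rnd_dna(3000); b <- rnd_dna(3000)
  sa <- local_align(a, b); sb <- local_align(b, a)
  expect_equal(sa$score %||% 0, sb$score %||% 0)

  flank_a <- rnd_dna(10000); flank_b <- rnd_dna(10000)
  core <- rnd_dna(9000)
  prev <- -1
  for (len in c(1000, 3000, 6000, 9000)) {
    ov <- substr(core, 1, len)
    al <- local_align(paste0(flank_a, ov), paste0(ov, flank_b))
    expect_gte(al$score, prev)
    expect_gte(al$score, len - 5)  # essentially the full overlap
    prev <- al$score
  }
})

test_that("unrelated large windows stay far below the merge threshold", {
  set.seed(6)
  scores <- replicate(5, {
    al <- local_align(rnd_dna(30000), rnd_dna(30000))
    if (is.null(al)) 0 else al$score
  })
  expect_true(all(scores < 100))
})

test_that("window cap guards against oversized input", {
  p <- align_params(window_cap = 1000)
  expect_error(local_align(rnd_dna(1500), "ACGT", p), "cap")
})

test_that("PSL parsing returns the best hit with the BLAT score", {
  psl <- c(
    paste(c(5900, 60, 0, 0, 1, 40, 1, 30, "+", "b", 6000, 0, 6000,
            "a", 6000, 0, 5990), collapse = "\t"),
    paste(c(120, 5, 0, 0, 0, 0, 0, 0, "+", "b", 6000, 10, 135,
            "a", 6000, 20, 145), collapse = "\t"))
  best <- parse_psl_best(psl)
  expect_equal(best$score, 5900 + 0 - 60 - 1 - 1)  # one q and one t gap open
  expect_equal(best$a_start, 1)
  expect_equal(best$b_end, 6000)
  expect_null(parse_psl_best(character(0)))
})

test_that("the external BLAT adapter reports a configuration error when absent", {
  expect_error(external_blat_adapter("ACGT", "ACGT",
                                     blat_path = "/no/such/blat"),
               "builtin")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
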