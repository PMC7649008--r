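#' Local sequence alignment with a BLAT-comparable score
#'
#' Finds the best local alignment between two DNA windows under unit
#' scoring: match +1, mismatch -1, gap open -1 and -1 per gapped base, so
#' a gap of length L costs 1 + L and
#' `score = matches - mismatches - gap_opens - gap_bases`.  Under this
#' scheme an exact overlap of L bases scores exactly L, so the classical
#' score-5000 merge threshold used for junction rescue transfers
#' directly, while optimal local scores between unrelated windows stay in
#' the logarithmic regime (tens, not thousands, even for 30 kb windows).
#'
#' For short inputs (both sequences at most `exact_max` bases) the full
#' Smith-Waterman dynamic program is run, so results are provably optimal.
#' For longer windows a seed-and-extend strategy is used: exact shared
#' k-mers (default k = 11) vote for diagonals, the densest run of diagonals
#' is selected, and a banded Smith-Waterman restricted to those diagonals
#' (plus `band_pad` on each side) is run.  If the two windows share no
#' k-mer, no alignment is reported.
#'
#' Ambiguity characters never match: N aligned to N counts as a mismatch.
#'
#' @param window_a,window_b Character scalars, uppercase DNA (Ns allowed).
#' @param params Alignment parameters from [align_params()].
#' @return A `local_alignment` object (list with `score`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `matches`, `mismatches`, `gap_opens`,
#'   `gap_bases`), or `NULL` when no positive-scoring alignment is found.
#' @examples
#' local_align("ACGTACGTAC", "ACGTACGTAC")$score  # 10
#' @export
local_align <- function(window_a, window_b, params = align_params()) {
  stopifnot(is.character(window_a), length(window_a) == 1L,
            is.character(window_b), length(window_b) == 1L)
  n <- nchar(window_a); m <- nchar(window_b)
  if (n < 1L || m < 1L) stop("alignment windows must have length >= 1")
  cap <- params$window_cap
  if (n > cap || m > cap) {
    stop("alignment window longer than the configured cap (", cap, " bp)")
  }
  if (max(n, m) <= params$exact_max) {
    res <- sw_banded_cpp(window_a, window_b, -n, m)
  } else {
    diags <- seed_diagonals_cpp(window_a, window_b, params$seed_k)
    if (length(diags) == 0L) return(NULL)
    band <- densest_diagonal_band(diags, params$band_max)
    res <- sw_banded_cpp(window_a, window_b,
                         band[1L] - params$band_pad,
                         band[2L] + params$band_pad)
  }
  if (res$score <= 0L) return(NULL)
  structure(res, class = "local_alignment")
}

#' Alignment parameters
#'
#' @param seed_k Exact seed length for the seed-and-extend stage.
#' @param band_pad Diagonals added on each side of the seed band.
#' @param band_max Maximal width (in diagonals) of the seed cluster
#'   considered for banded extension.
#' @param exact_max Inputs up to this length are aligned with the full
#'   (unbanded) dynamic program.
#' @param window_cap Hard cap on accepted window length; a guard against
#'   accidentally feeding whole chromosomes to the aligner (default 10x the
#'   usual 30 kb junction window).
#' @return A named list of parameters.
#' @export
align_params <- function(seed_k = 11L, band_pad = 64L, band_max = 2048L,
                         exact_max = 2048L, window_cap = 300000L) {
  stopifnot(seed_k >= 4L, seed_k <= 15L, band_pad >= 0L, band_max >= 1L)
  list(seed_k = as.integer(seed_k), band_pad = as.integer(band_pad),
       band_max = as.integer(band_max), exact_max = as.integer(exact_max),
       window_cap = as.integer(window_cap))
}

# Densest window of seed diagonals no wider than band_max; returns c(lo, hi).
densest_diagonal_band <- function(diags, band_max) {
  d <- sort(diags)
  if (length(d) == 1L) return(c(d, d))
  lo <- 1L; best <- c(d[1L], d[1L]); best_n <- 1L
  for (hi in seq_along(d)) {
    while (d[hi] - d[lo] > band_max) lo <- lo + 1L
    if (hi - lo + 1L > best_n) {
      best_n <- hi - lo + 1L
      best <- c(d[lo], d[hi])
    }
  }
  best
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local alignment: score %d, a[%d..%d] ~ b[%d..%d] (%d match, %d mismatch, %d gaps)\n",
    x$score, x$a_start, x$a_end, x$b_start, x$b_end,
    x$matches, x$mismatches, x$gap_opens))
  invisible(x)
}

#' Local alignment through an external BLAT executable
#'
#' Runs `blat` on the two windows and converts the best PSL hit to the same
#' `local_alignment` contract as [local_align()], with score computed as
#' matches - mismatches - query gap opens - target gap opens.  Intended for
#' users who want junction rescue decisions taken by BLAT itself rather
#' than the builtin aligner.
#'
#' @param window_a,window_b Character scalars, uppercase DNA.
#' @param blat_path Path to the `blat` executable.
#' @return A `local_alignment` or `NULL` when BLAT reports no hit.
#' @export
external_blat_adapter <- function(window_a, window_b, blat_path = "blat") {
  if (Sys.which(blat_path) == "" && !file.exists(blat_path)) {
    stop("BLAT executable not found at '", blat_path,
         "'; use the builtin aligner (local_align) instead")
  }
  td <- tempfile("blat"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fa_a <- file.path(td, "a.fa"); fa_b <- file.path(td, "b.fa")
  psl <- file.path(td, "out.psl")
  writeLines(c(">a", window_a), fa_a)
  writeLines(c(">b", window_b), fa_b)
  status <- system2(blat_path, c(fa_a, fa_b, "-noHead", psl),
                    stdout = FALSE, stderr = FALSE)
  if (!file.exists(psl)) return(NULL)
  parse_psl_best(readLines(psl))
}

#' Parse PSL alignment lines into the best `local_alignment`
#'
#' @param lines Character vector of PSL rows (no header, or header lines
#'   which are skipped).
#' @return Best-scoring `local_alignment`, or `NULL` for an empty PSL.
#' @export
parse_psl_best <- function(lines) {
  lines <- lines[!grepl("^(psLayout|match|-|\\s*$)", lines)]
  if (length(lines) == 0L) return(NULL)
  best <- NULL
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 17L) next
    matches <- as.integer(f[1L]); mism <- as.integer(f[2L])
    rep_m <- as.integer(f[3L])
    qgap <- as.integer(f[5L]); tgap <- as.integer(f[7L])
    score <- matches + rep_m - mism - qgap - tgap
    al <- structure(list(
      score = score,
      # PSL coords are 0-based half-open; query is the second input here
      b_start = as.integer(f[12L]) + 1L, b_end = as.integer(f[13L]),
      a_start = as.integer(f[16L]) + 1L, a_end = as.integer(f[17L]),
      matches = matches + rep_m, mismatches = mism,
      gap_opens = qgap + tgap), class = "local_alignment")
    if (is.null(best) || al$score > best$score) best <- al
  }
  best
}
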