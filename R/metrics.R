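# Assembly contiguity statistics and the junction census used to report
# the improvement brought by junction resolution.

#' Contiguity statistics from a length multiset
#'
#' NX is the length of the sequence at which the cumulative
#' sorted-descending length first reaches X% of the total; LX is its
#' 1-based rank; auN is the area under the Nx curve,
#' `sum(L_i^2) / sum(L_i)`.
#'
#' @param lengths Non-empty vector of positive sequence lengths.
#' @return List with `total`, `count`, `n50`, `l50`, `n90`, `l90`, `aun`.
#' @export
length_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("length_stats: empty length set")
  if (any(lengths <= 0)) stop("length_stats: non-positive length")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(s)
  cum <- cumsum(s)
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[1L]
    c(n = s[i], l = i)
  }
  v50 <- nx(50); v90 <- nx(90)
  list(total = total, count = length(s),
       n50 = unname(v50["n"]), l50 = as.integer(v50["l"]),
       n90 = unname(v90["n"]), l90 = as.integer(v90["l"]),
       aun = sum(s^2) / total)
}

#' Split scaffolds into contig lengths at N runs
#'
#' Each scaffold is split at every position with at least one N; the
#' lengths of the maximal N-free runs are returned (empty runs dropped).
#'
#' @param fasta Named character vector of scaffold sequences, or a path to
#'   a FASTA file.
#' @return Integer vector of contig lengths.
#' @export
scaffolds_to_contigs <- function(fasta) {
  if (length(fasta) == 1L && !grepl("[ACGTN]{20}", fasta[[1L]]) &&
      file.exists(fasta)) {
    fasta <- read_fasta(fasta)
  }
  unlist(lapply(fasta, function(s) {
    runs <- strsplit(toupper(s), "N+")[[1L]]
    w <- nchar(runs)
    w[w > 0L]
  }), use.names = FALSE)
}

#' Census of junction decisions
#'
#' @param report Decision report from [build_scaffolds()].
#' @return List with per-kind `counts`, `overlap_sizes` (bases removed at
#'   each fused junction), and `removed_bases` (total duplicated sequence
#'   removed).
#' @export
junction_census <- function(report) {
  kinds <- c("fuse_at_label", "fuse_by_alignment", "sized_gap",
             "containment_insert", "containment_singleton")
  counts <- vapply(kinds, function(k) sum(report$kind == k), 0L)
  fused <- report$kind %in% c("fuse_at_label", "fuse_by_alignment")
  list(counts = counts,
       overlap_sizes = report$removed_bases[fused],
       removed_bases = sum(report$removed_bases))
}

#' Assembly statistics of a scaffold FASTA
#'
#' Scaffold-level and contig-level (split at Ns) contiguity statistics.
#'
#' @param fasta Named character vector of sequences or FASTA path.
#' @return List with `scaffolds`, `contigs` ([length_stats()] lists) and
#'   `n_bases` (count of N characters).
#' @export
assembly_stats <- function(fasta) {
  if (length(fasta) == 1L && file.exists(fasta)) fasta <- read_fasta(fasta)
  scaff_lens <- nchar(fasta)
  contig_lens <- scaffolds_to_contigs(fasta)
  list(scaffolds = length_stats(scaff_lens),
       contigs = length_stats(contig_lens),
       n_bases = sum(scaff_lens) - sum(contig_lens))
}
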