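# High-level entry points behind the command-line script: scaffold a
# bundle from files on disk, simulate a fixture bundle, compute stats.

#' Run configuration for a scaffolding run
#'
#' @param fasta Draft assembly FASTA path.
#' @param key Key file path (or several, one per channel in the same
#'   order as the CMAP/XMAP files).
#' @param contig_cmaps,anchor_cmaps,xmaps Paths, one per label channel,
#'   in matched order (channel 1 first).
#' @param out_dir Output directory.
#' @param gap_merge_threshold,min_align_score,window,min_gap See
#'   [scaffold_params()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(fasta, key, contig_cmaps, anchor_cmaps, xmaps,
                       out_dir = ".", gap_merge_threshold = 1000,
                       min_align_score = 5000, window = 30000,
                       min_gap = 13) {
  cfg <- list(fasta = fasta, key = key, contig_cmaps = contig_cmaps,
              anchor_cmaps = anchor_cmaps, xmaps = xmaps,
              out_dir = out_dir,
              params = scaffold_params(gap_merge_threshold,
                                       min_align_score, window, min_gap))
  for (f in c(fasta, key, contig_cmaps, anchor_cmaps, xmaps)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  if (length(contig_cmaps) != length(anchor_cmaps) ||
      length(contig_cmaps) != length(xmaps)) {
    stop("contig CMAPs, anchor CMAPs and XMAPs must come in matched ",
         "per-channel sets")
  }
  structure(cfg, class = "run_config")
}

#' Run the scaffolding pipeline on files
#'
#' Reads the bundle, resolves every junction, and writes
#' `scaffolds.fasta`, `scaffolds.agp` and `decisions.tsv` into the output
#' directory.  A summary of decisions is reported via [message()].
#'
#' @param config A [run_config()].
#' @return Invisibly, the [build_scaffolds()] result with output paths
#'   attached.
#' @export
run_scaffold <- function(config) {
  assembly <- read_fasta(config$fasta)
  keys <- lapply(config$key, parse_key)
  names(keys) <- as.character(seq_along(keys))
  if (length(keys) == 1L) keys <- keys[[1L]]
  channels <- as.character(seq_along(config$xmaps))
  contig_maps <- setNames(lapply(config$contig_cmaps, parse_cmap), channels)
  anchor_maps <- setNames(lapply(config$anchor_cmaps, parse_cmap), channels)
  alignments <- do.call(c, lapply(seq_along(config$xmaps), function(i) {
    parse_xmap(config$xmaps[i], channel = i)
  }))
  res <- build_scaffolds(assembly, keys, contig_maps, anchor_maps,
                         alignments, config$params)
  out <- render_scaffolds(res)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(config$out_dir, "scaffolds.fasta"),
                agp = file.path(config$out_dir, "scaffolds.agp"),
                report = file.path(config$out_dir, "decisions.tsv"))
  write_fasta(out$fasta, paths$fasta)
  write_agp(out$plans, paths$agp, components = res$components)
  write.table(res$report, paths$report, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cen <- junction_census(res$report)
  message("junctions: ",
          paste(sprintf("%s=%d", names(cen$counts), cen$counts),
                collapse = " "),
          "; duplicated bases removed: ", cen$removed_bases)
  res$paths <- paths
  invisible(res)
}

#' Simulate a fixture bundle onto disk
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(spec = fixture_spec(), out_dir = ".") {
  fx <- simulate_fixture(spec)
  paths <- write_fixture_bundle(fx, out_dir)
  message("truth manifest: ", paths$truth)
  invisible(paths)
}

#' Compute and write assembly statistics
#'
#' @param fasta Scaffold FASTA path.
#' @param report Optional decisions TSV from [run_scaffold()]; adds the
#'   junction census.
#' @param out Output TSV path (default: stdout via message).
#' @return Invisibly, the stats list.
#' @export
run_stats <- function(fasta, report = NULL, out = NULL) {
  st <- assembly_stats(fasta)
  lines <- c(
    sprintf("scaffolds\t%d", st$scaffolds$count),
    sprintf("scaffold_total_bp\t%.0f", st$scaffolds$total),
    sprintf("scaffold_N50\t%.0f", st$scaffolds$n50),
    sprintf("scaffold_L50\t%d", st$scaffolds$l50),
    sprintf("scaffold_N90\t%.0f", st$scaffolds$n90),
    sprintf("scaffold_L90\t%d", st$scaffolds$l90),
    sprintf("scaffold_auN\t%.1f", st$scaffolds$aun),
    sprintf("contigs\t%d", st$contigs$count),
    sprintf("contig_total_bp\t%.0f", st$contigs$total),
    sprintf("contig_N50\t%.0f", st$contigs$n50),
    sprintf("contig_auN\t%.1f", st$contigs$aun),
    sprintf("N_bases\t%.0f", st$n_bases))
  if (!is.null(report)) {
    rep_df <- read.delim(report)
    cen <- junction_census(rep_df)
    lines <- c(lines,
               sprintf("junctions_%s\t%d", names(cen$counts), cen$counts),
               sprintf("duplicated_bases_removed\t%.0f",
                       cen$removed_bases))
  }
  if (is.null(out)) message(paste(lines, collapse = "\n"))
  else writeLines(lines, out)
  invisible(st)
}
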