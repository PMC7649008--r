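# AGP v2.1 output describing how input contigs tile the new scaffolds,
# plus an independent reader/validator/reconstructor used to prove that
# the emitted FASTA and AGP agree.

agp_columns <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")

#' Write scaffold plans as an AGP v2.1 file
#'
#' Contig slices become W rows (1-based inclusive component coordinates);
#' gaps become N rows with gap type `scaffold`, linkage `yes` and evidence
#' `map`.  When a component table is supplied, component coordinates are
#' composed back onto the original input contig (relevant for Bionano
#' split components named `NAME_subseq_START:END`).
#'
#' @param plans List of [scaffold_plan()] objects.
#' @param path Output path.
#' @param components Optional component table from [resolve_components()];
#'   when given, W rows reference the source contig.
#' @return The path, invisibly.
#' @export
write_agp <- function(plans, path, components = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (plan in plans) {
    pos <- 0; partno <- 0L
    for (p in plan$parts) {
      w <- part_length(p)
      if (w < 1) stop("plan '", plan$name, "': zero-length part")
      partno <- partno + 1L
      beg <- pos + 1; end <- pos + w; pos <- end
      if (p$type == "slice") {
        nm <- p$contig; cs <- p$start; ce <- p$end
        if (!is.null(components)) {
          i <- match(nm, components$component_name)
          if (!is.na(i)) {
            cs <- components$src_start[i] + cs - 1
            ce <- components$src_start[i] + ce - 1
            nm <- components$source[i]
          }
        }
        writeLines(sprintf("%s\t%.0f\t%.0f\t%d\tW\t%s\t%.0f\t%.0f\t%s",
                           plan$name, beg, end, partno, nm, cs, ce,
                           p$strand), con)
      } else {
        writeLines(sprintf("%s\t%.0f\t%.0f\t%d\tN\t%.0f\tscaffold\tyes\tmap",
                           plan$name, beg, end, partno, p$length), con)
      }
    }
  }
  invisible(path)
}

#' Read an AGP file
#'
#' @param x Path, connection, or character vector of lines.
#' @return Data.frame with one row per AGP line; N rows carry
#'   `gap_length`, `gap_type`, `linkage`, `evidence` instead of component
#'   coordinates.
#' @export
read_agp <- function(x) {
  lines <- as_lines(x)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- split_tsv(lines)
  get <- function(i) vapply(rows, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  df <- data.frame(object = get(1L), object_beg = as.numeric(get(2L)),
                   object_end = as.numeric(get(3L)),
                   part_number = as.integer(get(4L)),
                   component_type = get(5L), stringsAsFactors = FALSE)
  num <- function(x) suppressWarnings(as.numeric(x))
  df$component_id <- ifelse(df$component_type == "W", get(6L), NA)
  df$component_beg <- ifelse(df$component_type == "W", num(get(7L)), NA)
  df$component_end <- ifelse(df$component_type == "W", num(get(8L)), NA)
  df$orientation <- ifelse(df$component_type == "W", get(9L), NA)
  df$gap_length <- ifelse(df$component_type == "N", num(get(6L)), NA)
  df$gap_type <- ifelse(df$component_type == "N", get(7L), NA)
  df$linkage <- ifelse(df$component_type == "N", get(8L), NA)
  df$evidence <- ifelse(df$component_type == "N", get(9L), NA)
  df
}

#' Validate AGP tiling
#'
#' Independent walk over every object: rows must tile `[1, object_length]`
#' with no holes or overlaps, W spans must match their component spans,
#' and N rows must have positive gap length.
#'
#' @param agp Data.frame from [read_agp()].
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_agp <- function(agp) {
  for (ob in unique(agp$object)) {
    rows <- agp[agp$object == ob, ]
    rows <- rows[order(rows$part_number), ]
    pos <- 0
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$object_beg != pos + 1) {
        stop("AGP object '", ob, "': hole or overlap at part ",
             r$part_number)
      }
      span <- r$object_end - r$object_beg + 1
      if (r$component_type == "W") {
        if (span != r$component_end - r$component_beg + 1) {
          stop("AGP object '", ob, "': W span mismatch at part ",
               r$part_number)
        }
      } else if (r$component_type == "N") {
        if (is.na(r$gap_length) || r$gap_length < 1 ||
            span != r$gap_length) {
          stop("AGP object '", ob, "': bad gap length at part ",
               r$part_number)
        }
      } else {
        stop("AGP object '", ob, "': unsupported component type '",
             r$component_type, "'")
      }
      pos <- r$object_end
    }
  }
  invisible(TRUE)
}

#' Reconstruct scaffold sequences from an AGP and the input contigs
#'
#' The reconstruction reads only the AGP semantics (W = oriented slice of
#' a component, N = run of Ns) and is therefore an independent check of
#' the emitted scaffold FASTA.
#'
#' @param agp Data.frame from [read_agp()].
#' @param seqs Named character vector of input contig sequences.
#' @return Named character vector of object sequences.
#' @export
reconstruct_from_agp <- function(agp, seqs) {
  out <- character(0)
  for (ob in unique(agp$object)) {
    rows <- agp[agp$object == ob, ]
    rows <- rows[order(rows$part_number), ]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      if (r$component_type == "N") {
        pieces[i] <- strrep("N", r$gap_length)
      } else {
        s <- seqs[[r$component_id]]
        if (is.null(s)) stop("AGP references unknown component ",
                             r$component_id)
        piece <- substr(s, r$component_beg, r$component_end)
        if (identical(r$orientation, "-")) piece <- revcomp(piece)
        pieces[i] <- piece
      }
    }
    out[[ob]] <- paste(pieces, collapse = "")
  }
  out
}
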