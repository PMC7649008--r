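# Readers and writers for the Bionano hybrid-scaffolding file bundle:
# the key file (map id <-> contig name), CMAP (label positions per map)
# and XMAP (query-to-anchor alignments with explicit site pairs).
#
# All parsers locate required columns by header name ('#h' line in the
# CMAP/XMAP dialects), ignore unknown columns, and are insensitive to
# comment content and trailing blank lines; coordinates are kept exactly
# as printed (1-based bp, possibly fractional).

as_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("[\t\n]", x)) {
    if (!file.exists(x)) stop("no such file: ", x)
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x) && length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  as.character(x)
}

split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

# '#h' header of the CMAP/XMAP dialects; returns column names or NULL.
dialect_header <- function(lines) {
  h <- grep("^#h[ \t]", lines, value = TRUE)
  if (length(h) == 0L) return(NULL)
  f <- strsplit(sub("^#h[ \t]+", "", h[1L]), "[ \t]+")[[1L]]
  f[nzchar(f)]
}

locate_columns <- function(header, required, what) {
  idx <- match(required, header)
  if (anyNA(idx)) {
    stop(what, ": missing required column(s): ",
         paste(required[is.na(idx)], collapse = ", "))
  }
  setNames(idx, required)
}

#' Parse a Bionano key file
#'
#' The key file maps numeric map identifiers to contig names and lengths.
#' Components named with the split-contig convention
#' `NAME_subseq_START:END` are recognized downstream (see
#' [resolve_components()]); this parser stores names verbatim.
#'
#' @param x Path, connection, or character vector of lines.
#' @return A data.frame with columns `component_id`, `component_name`,
#'   `component_length`, one row per data line, input order preserved.
#' @export
parse_key <- function(x) {
  lines <- as_lines(x)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  rows <- split_tsv(lines[keep])
  # a non-comment header row (e.g. "CompntId\tCompntName\tCompntLength"):
  # all-text fields, unlike a data row whose length column is numeric
  if (length(rows) > 0L &&
      is.na(suppressWarnings(as.numeric(rows[[1L]][1L]))) &&
      (length(rows[[1L]]) < 3L ||
         is.na(suppressWarnings(as.numeric(rows[[1L]][3L]))))) {
    rows <- rows[-1L]; lineno <- lineno[-1L]
  }
  if (length(rows) == 0L) {
    return(data.frame(component_id = integer(), component_name = character(),
                      component_length = numeric()))
  }
  bad_len <- vapply(rows, length, 1L) < 3L
  if (any(bad_len)) {
    stop("key file: expected 3 tab-separated fields at line ",
         lineno[which(bad_len)[1L]])
  }
  id <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 1L)))
  len <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3L)))
  if (anyNA(id) || any(id != floor(id))) {
    stop("key file: non-integer component id at line ",
         lineno[which(is.na(id) | id != floor(id))[1L]])
  }
  if (anyNA(len)) {
    stop("key file: non-numeric component length at line ",
         lineno[which(is.na(len))[1L]])
  }
  if (anyDuplicated(id)) {
    stop("key file: duplicate component id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(len <= 0)) stop("key file: non-positive component length")
  data.frame(component_id = as.integer(id),
             component_name = vapply(rows, `[`, "", 2L),
             component_length = len)
}

#' Write a key file
#' @param key Data.frame as returned by [parse_key()].
#' @param path Output path.
#' @export
write_key <- function(key, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("CompntId\tCompntName\tCompntLength", con)
  writeLines(sprintf("%d\t%s\t%d", key$component_id, key$component_name,
                     as.integer(key$component_length)), con)
  invisible(path)
}

#' Construct a label map
#'
#' One optical map: its id, length, and the ordered label sites per
#' channel.
#'
#' @param map_id Positive integer map identifier.
#' @param length_bp Map length in bp.
#' @param sites Data.frame with columns `channel`, `site_id`,
#'   `position_bp`.
#' @return A `label_map` object.
#' @export
label_map <- function(map_id, length_bp, sites) {
  sites <- sites[order(sites$channel, sites$site_id), , drop = FALSE]
  rownames(sites) <- NULL
  for (ch in unique(sites$channel)) {
    s <- sites[sites$channel == ch, ]
    if (anyDuplicated(s$site_id)) {
      stop("map ", map_id, ": duplicate site id in channel ", ch)
    }
    if (is.unsorted(s$position_bp)) {
      stop("map ", map_id, ": site positions not non-decreasing in site id")
    }
  }
  if (any(sites$position_bp > length_bp + 1e-6)) {
    stop("map ", map_id, ": label position beyond declared map length")
  }
  structure(list(map_id = as.integer(map_id), length_bp = as.numeric(length_bp),
                 sites = sites), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label map %d: %.0f bp, %d site(s) in %d channel(s)\n",
              x$map_id, x$length_bp, nrow(x$sites),
              length(unique(x$sites$channel))))
  invisible(x)
}

# positions of one channel of a label map, named by site id
map_positions <- function(lm, channel) {
  s <- lm$sites[lm$sites$channel == channel, ]
  setNames(s$position_bp, s$site_id)
}

#' Parse a CMAP file
#'
#' Rows are grouped by map id; the terminal row of each map (label channel
#' 0 in the dialect) marks the map end, sets the map length, and is not
#' stored as a site.
#'
#' @param x Path, connection, or character vector of lines.
#' @return Named list of [label_map()] objects (names are map ids).
#' @export
parse_cmap <- function(x) {
  lines <- as_lines(x)
  header <- dialect_header(lines)
  if (is.null(header)) {
    header <- c("CMapId", "ContigLength", "NumSites", "SiteID",
                "LabelChannel", "Position")
  }
  cols <- locate_columns(header, c("CMapId", "ContigLength", "SiteID",
                                   "LabelChannel", "Position"), "CMAP")
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(structure(list(), names = character()))
  rows <- split_tsv(lines[keep])
  get <- function(i) vapply(rows, `[`, "", cols[[i]])
  map_id <- as.integer(get("CMapId"))
  len <- as.numeric(get("ContigLength"))
  site_id <- as.integer(get("SiteID"))
  channel <- as.integer(get("LabelChannel"))
  pos <- as.numeric(get("Position"))
  if (anyNA(map_id) || anyNA(pos)) stop("CMAP: malformed numeric field")
  out <- list()
  for (id in unique(map_id)) {
    i <- map_id == id
    end_row <- i & channel == 0L
    declared <- len[i][1L]
    is_site <- i & channel != 0L
    if (any(pos[is_site] > declared + 1e-6)) {
      stop("CMAP: map ", id, " has a label position beyond its declared length")
    }
    length_bp <- if (any(end_row)) max(pos[end_row]) else declared
    out[[as.character(id)]] <- label_map(
      id, length_bp,
      data.frame(channel = channel[is_site], site_id = site_id[is_site],
                 position_bp = pos[is_site]))
  }
  out
}

#' Write a CMAP file
#' @param maps List of [label_map()] objects.
#' @param path Output path.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# CMAP File Version:\t0.1",
    "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition\tStdDev\tCoverage\tOccurrence",
    "#f int\tfloat\tint\tint\tint\tfloat\tfloat\tint\tint"), con)
  for (lm in maps) {
    s <- lm$sites[order(lm$sites$channel, lm$sites$site_id), ]
    n <- nrow(s)
    if (n > 0L) {
      writeLines(sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t1.0\t1\t1",
                         lm$map_id, lm$length_bp, n, s$site_id, s$channel,
                         s$position_bp), con)
    }
    # terminal row: channel 0 marks the end of the map
    writeLines(sprintf("%d\t%.1f\t%d\t%d\t%d\t%.1f\t0.0\t1\t1",
                       lm$map_id, lm$length_bp, n, n + 1L, 0L, lm$length_bp),
               con)
  }
  invisible(path)
}

#' Construct a map alignment
#'
#' One XMAP record: a contig (query) map aligned to an anchor, with
#' orientation and the explicit (anchor site, query site) pairs.  For
#' reverse-orientation records the raw format stores a descending query
#' span; here query coordinates are always normalized ascending and the
#' orientation kept as a separate flag.
#'
#' @param entry_id,query_map_id,anchor_id Integers.
#' @param query_start_bp,query_end_bp Alignment span on the query map
#'   (native coordinates; normalized so start <= end).
#' @param anchor_start_bp,anchor_end_bp Alignment span on the anchor.
#' @param orientation `"forward"` or `"reverse"`.
#' @param confidence Alignment score.
#' @param channel Label channel of the alignment.
#' @param pairs Two-column matrix `(anchor_site_id, query_site_id)` in file
#'   order.
#' @return A `map_alignment` object.
#' @export
map_alignment <- function(entry_id, query_map_id, anchor_id,
                          query_start_bp, query_end_bp,
                          anchor_start_bp, anchor_end_bp,
                          orientation, confidence, channel, pairs) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  if (anchor_start_bp > anchor_end_bp) {
    stop("XMAP entry ", entry_id, ": anchor span must be ascending")
  }
  if (query_start_bp > query_end_bp) {
    tmp <- query_start_bp; query_start_bp <- query_end_bp; query_end_bp <- tmp
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("anchor_site", "query_site")))
  if (nrow(pairs) == 0L) stop("XMAP entry ", entry_id, ": empty pair list")
  structure(list(entry_id = as.integer(entry_id),
                 query_map_id = as.integer(query_map_id),
                 anchor_id = as.integer(anchor_id),
                 query_start_bp = as.numeric(query_start_bp),
                 query_end_bp = as.numeric(query_end_bp),
                 anchor_start_bp = as.numeric(anchor_start_bp),
                 anchor_end_bp = as.numeric(anchor_end_bp),
                 orientation = orientation,
                 confidence = as.numeric(confidence),
                 channel = as.integer(channel),
                 pairs = pairs),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf(
    "alignment %d: query %d [%.0f..%.0f] -> anchor %d [%.0f..%.0f] (%s, conf %.1f, %d pairs)\n",
    x$entry_id, x$query_map_id, x$query_start_bp, x$query_end_bp,
    x$anchor_id, x$anchor_start_bp, x$anchor_end_bp, x$orientation,
    x$confidence, nrow(x$pairs)))
  invisible(x)
}

parse_pair_string <- function(s, entry_id) {
  toks <- regmatches(s, gregexpr("\\([^)]*\\)", s))[[1L]]
  clean <- sub("^\\(", "", sub("\\)$", "", toks))
  parts <- strsplit(clean, ",", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  flat <- suppressWarnings(as.integer(unlist(parts[ok])))
  if (!all(ok) || anyNA(flat) ||
      sum(nchar(toks)) != nchar(gsub("\\s", "", s))) {
    bad <- if (any(!ok)) toks[!ok][1L] else s
    stop("XMAP entry ", entry_id, ": malformed alignment pair token '",
         bad, "'")
  }
  matrix(flat, ncol = 2L, byrow = TRUE)
}

#' Parse an XMAP file
#'
#' @param x Path, connection, or character vector of lines.
#' @param channel Label channel tag for records without a `LabelChannel`
#'   column (one XMAP per enzyme is the common layout).
#' @return List of [map_alignment()] objects in file order.
#' @export
parse_xmap <- function(x, channel = 1L) {
  lines <- as_lines(x)
  header <- dialect_header(lines)
  if (is.null(header)) {
    header <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
                "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
                "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
                "Alignment")
  }
  cols <- locate_columns(header, c("XmapEntryID", "QryContigID",
                                   "RefContigID", "QryStartPos", "QryEndPos",
                                   "RefStartPos", "RefEndPos", "Orientation",
                                   "Confidence", "Alignment"), "XMAP")
  ch_col <- match("LabelChannel", header)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- split_tsv(lines[keep])
  lapply(rows, function(f) {
    ori_sym <- f[cols[["Orientation"]]]
    if (!ori_sym %in% c("+", "-")) {
      stop("XMAP: unknown orientation symbol '", ori_sym, "'")
    }
    entry_id <- as.integer(f[cols[["XmapEntryID"]]])
    ch <- if (!is.na(ch_col) && length(f) >= ch_col &&
              !is.na(suppressWarnings(as.integer(f[ch_col])))) {
      as.integer(f[ch_col])
    } else as.integer(channel)
    map_alignment(
      entry_id = entry_id,
      query_map_id = as.integer(f[cols[["QryContigID"]]]),
      anchor_id = as.integer(f[cols[["RefContigID"]]]),
      query_start_bp = as.numeric(f[cols[["QryStartPos"]]]),
      query_end_bp = as.numeric(f[cols[["QryEndPos"]]]),
      anchor_start_bp = as.numeric(f[cols[["RefStartPos"]]]),
      anchor_end_bp = as.numeric(f[cols[["RefEndPos"]]]),
      orientation = if (ori_sym == "+") "forward" else "reverse",
      confidence = as.numeric(f[cols[["Confidence"]]]),
      channel = ch,
      pairs = parse_pair_string(f[cols[["Alignment"]]], entry_id))
  })
}

#' Write an XMAP file
#'
#' Reverse-orientation records are written with the raw-dialect descending
#' query span, so that `parse_xmap(write_xmap(x))` round-trips.
#'
#' @param alignments List of [map_alignment()] objects.
#' @param path Output path.
#' @export
write_xmap <- function(alignments, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "# XMAP File Version:\t0.2",
    paste0("#h XmapEntryID\tQryContigID\tRefContigID\tQryStartPos\tQryEndPos\t",
           "RefStartPos\tRefEndPos\tOrientation\tConfidence\tHitEnum\t",
           "QryLen\tRefLen\tLabelChannel\tAlignment")), con)
  for (al in alignments) {
    qs <- al$query_start_bp; qe <- al$query_end_bp
    if (al$orientation == "reverse") { tmp <- qs; qs <- qe; qe <- tmp }
    pairs <- paste0("(", al$pairs[, 1L], ",", al$pairs[, 2L], ")",
                    collapse = "")
    writeLines(sprintf("%d\t%d\t%d\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.2f\t%dM\t%.1f\t%.1f\t%d\t%s",
                       al$entry_id, al$query_map_id, al$anchor_id, qs, qe,
                       al$anchor_start_bp, al$anchor_end_bp,
                       if (al$orientation == "forward") "+" else "-",
                       al$confidence, nrow(al$pairs), 0, 0, al$channel,
                       pairs), con)
  }
  invisible(path)
}
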