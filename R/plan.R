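# ScaffoldPlan: the single source from which both the scaffold FASTA and
# the AGP are rendered.  A plan is an ordered list of parts; each part is
# either an oriented slice of an input component or a gap of known length.

#' Scaffold plan part: component slice
#'
#' @param contig Component name.
#' @param start,end 1-based inclusive coordinates on the component.
#' @param strand `"+"` or `"-"` (minus slices are reverse-complemented when
#'   rendered).
#' @return A part list for [scaffold_plan()].
#' @export
part_slice <- function(contig, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  if (end < start) stop("zero- or negative-length slice of ", contig)
  list(type = "slice", contig = contig, start = as.numeric(start),
       end = as.numeric(end), strand = strand)
}

#' Scaffold plan part: gap
#'
#' @param length Emitted gap length in N bases (>= 1).
#' @param estimated The optical-map gap-size estimate behind this gap
#'   (may be negative or below the emitted length when the sentinel
#'   minimum applies).
#' @return A part list for [scaffold_plan()].
#' @export
part_gap <- function(length, estimated = NA_real_) {
  length <- as.numeric(length)
  if (length < 1) stop("gap length must be >= 1")
  list(type = "gap", length = length, estimated = as.numeric(estimated))
}

#' Construct a scaffold plan
#'
#' @param name Scaffold (object) name.
#' @param parts List of [part_slice()] / [part_gap()] parts.
#' @return A `scaffold_plan` object.
#' @export
scaffold_plan <- function(name, parts) {
  types <- vapply(parts, `[[`, "", "type")
  if (any(types == "gap" & c("", head(types, -1L)) == "gap")) {
    stop("plan '", name, "': two consecutive gap parts")
  }
  if (length(parts) == 0L) stop("plan '", name, "': empty part list")
  structure(list(name = name, parts = parts), class = "scaffold_plan")
}

part_length <- function(p) {
  if (p$type == "gap") p$length else p$end - p$start + 1
}

#' Total length of a scaffold plan
#' @param plan A [scaffold_plan()].
#' @return Length in bp.
#' @export
plan_length <- function(plan) {
  sum(vapply(plan$parts, part_length, 0))
}

#' @export
print.scaffold_plan <- function(x, ...) {
  cat(sprintf("scaffold plan '%s': %d part(s), %.0f bp\n", x$name,
              length(x$parts), plan_length(x)))
  for (p in x$parts) {
    if (p$type == "slice") {
      cat(sprintf("  %s:%.0f-%.0f(%s)\n", p$contig, p$start, p$end, p$strand))
    } else {
      cat(sprintf("  gap %0.f N (estimate %.0f)\n", p$length, p$estimated))
    }
  }
  invisible(x)
}

render_part <- function(p, seqs) {
  if (p$type == "gap") return(strrep("N", p$length))
  s <- seqs[[p$contig]]
  if (is.null(s)) stop("unknown component in plan: ", p$contig)
  frag <- substr(s, p$start, p$end)
  if (p$strand == "-") revcomp(frag) else frag
}

#' Render a scaffold plan to its sequence
#'
#' @param plan A [scaffold_plan()].
#' @param seqs Named character vector of component sequences.
#' @return Character scalar, the scaffold sequence.
#' @export
render_plan <- function(plan, seqs) {
  paste(vapply(plan$parts, render_part, "", seqs = seqs), collapse = "")
}

# ---------------------------------------------------------------------------
# Fragment: the mutable junction-resolution representation of one contig
# (possibly with contained contigs already inserted) in anchor orientation.
# Each part carries the interval of the contig's ORIGINAL oriented
# coordinate system it covers, so cut positions derived from label maps
# (which always refer to original coordinates) remain valid after a
# containment insertion changed the fragment's length.  Insert parts carry
# a half-open sentinel interval (a + 0.5) placing them between original
# positions a and a + 1.

frag_new <- function(comp, len, orientation) {
  strand <- if (orientation == "reverse") "-" else "+"
  list(comp = comp, len = as.numeric(len),
       parts = list(part_slice(comp, 1, len, strand)),
       orig = matrix(c(1, len), ncol = 2L,
                     dimnames = list(NULL, c("os", "oe"))))
}

frag_len <- function(frag) sum(vapply(frag$parts, part_length, 0))

# keep the first q oriented bases of a slice part
slice_oriented_prefix <- function(p, q) {
  if (p$strand == "+") part_slice(p$contig, p$start, p$start + q - 1, "+")
  else part_slice(p$contig, p$end - q + 1, p$end, "-")
}

# keep the last q oriented bases of a slice part
slice_oriented_suffix <- function(p, q) {
  if (p$strand == "+") part_slice(p$contig, p$end - q + 1, p$end, "+")
  else part_slice(p$contig, p$start, p$start + q - 1, "-")
}

# map an original-coordinate cut to the fragment's current coordinates;
# positions inside a replaced (insert) region clamp to the insert edge
frag_orig_to_current <- function(frag, pos) {
  cur <- 0
  for (i in seq_along(frag$parts)) {
    os <- frag$orig[i, 1L]; oe <- frag$orig[i, 2L]
    w <- part_length(frag$parts[[i]])
    if (os == oe && os != floor(os)) { # insert sentinel
      if (pos <= os) return(cur)
      cur <- cur + w
      next
    }
    if (pos < os) return(cur)
    if (pos <= oe) return(unname(cur + (pos - os + 1)))
    cur <- cur + w
  }
  unname(cur)
}

# keep current-coordinate interval [1 .. cut]
frag_trim_right <- function(frag, cut) {
  cut <- round_half_up(cut)
  if (cut >= frag_len(frag)) return(frag)
  if (cut < 1) stop("fragment trim would empty contig ", frag$comp)
  parts <- list(); orig <- NULL; cur <- 0
  for (i in seq_along(frag$parts)) {
    w <- part_length(frag$parts[[i]])
    if (cur + w <= cut) {
      parts[[length(parts) + 1L]] <- frag$parts[[i]]
      orig <- rbind(orig, frag$orig[i, , drop = FALSE])
    } else if (cur < cut) {
      q <- cut - cur
      parts[[length(parts) + 1L]] <-
        slice_oriented_prefix(frag$parts[[i]], q)
      os <- frag$orig[i, 1L]
      oe <- if (os == floor(os)) os + q - 1 else os
      orig <- rbind(orig, c(os, oe))
    } else break
    cur <- cur + w
  }
  frag$parts <- parts; frag$orig <- orig
  frag
}

# keep current-coordinate interval (cut .. len]
frag_trim_left <- function(frag, cut) {
  cut <- round_half_up(cut)
  if (cut <= 0) return(frag)
  total <- frag_len(frag)
  if (cut >= total) stop("fragment trim would empty contig ", frag$comp)
  parts <- list(); orig <- NULL; cur <- 0
  for (i in seq_along(frag$parts)) {
    w <- part_length(frag$parts[[i]])
    if (cur >= cut) {
      parts[[length(parts) + 1L]] <- frag$parts[[i]]
      orig <- rbind(orig, frag$orig[i, , drop = FALSE])
    } else if (cur + w > cut) {
      q <- cur + w - cut
      parts[[length(parts) + 1L]] <-
        slice_oriented_suffix(frag$parts[[i]], q)
      oe <- frag$orig[i, 2L]
      os <- if (oe == floor(oe)) oe - q + 1 else oe
      orig <- rbind(orig, c(os, oe))
    }
    cur <- cur + w
  }
  frag$parts <- parts; frag$orig <- orig
  frag
}

# original-coordinate versions (used for label-derived cut positions)
frag_trim_right_orig <- function(frag, cut) {
  frag_trim_right(frag, frag_orig_to_current(frag, round_half_up(cut)))
}
frag_trim_left_orig <- function(frag, cut) {
  frag_trim_left(frag, frag_orig_to_current(frag, round_half_up(cut)))
}

# replace original interval (left_end, right_start) of the host fragment
# by the given slice parts (a containment insertion)
frag_replace <- function(frag, left_end, right_start, insert_parts) {
  left_end <- round_half_up(left_end); right_start <- round_half_up(right_start)
  stopifnot(left_end >= 1, right_start <= frag$len, left_end < right_start)
  head_f <- frag_trim_right_orig(frag, left_end)
  tail_f <- frag_trim_left_orig(frag, right_start - 1)
  sentinel <- matrix(rep(left_end + 0.5, 2L * length(insert_parts)),
                     ncol = 2L)
  frag$parts <- c(head_f$parts, insert_parts, tail_f$parts)
  frag$orig <- rbind(head_f$orig, sentinel, tail_f$orig)
  frag
}

render_frag <- function(frag, seqs) {
  paste(vapply(frag$parts, render_part, "", seqs = seqs), collapse = "")
}
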