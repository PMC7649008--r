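# The junction-resolution engine.  Contig-to-anchor alignments are ordered
# along each anchor; contained contigs are resolved first; every remaining
# adjacent pair is then resolved by one of:
#   shared-label fusion   - the contigs share an aligned anchor label; both
#                           are cut at that label and fused without a gap;
#   alignment rescue      - no shared label but the optical-map gap estimate
#                           is small; the facing contig ends are aligned and
#                           fused when the score clears the threshold;
#   sized gap             - otherwise the estimated number of Ns is emitted
#                           (with a 13-N sentinel floor for non-positive
#                           estimates).

#' Scaffolding parameters
#'
#' @param gap_merge_threshold Gap estimates at or below this many bp
#'   trigger alignment rescue (default 1000).
#' @param min_align_score Minimal local-alignment score for a rescue
#'   fusion (default 5000 under the unit scoring scheme).
#' @param window Window length (bp) taken from each contig end for rescue
#'   alignment (default 30000).
#' @param min_gap Sentinel gap length emitted when an estimate is below it
#'   (default 13, the fixed gap the upstream scaffolder uses).
#' @param align Aligner parameters, see [align_params()].
#' @return Named list of parameters.
#' @export
scaffold_params <- function(gap_merge_threshold = 1000,
                            min_align_score = 5000,
                            window = 30000, min_gap = 13,
                            align = align_params()) {
  stopifnot(gap_merge_threshold > 0, min_align_score > 0, window > 0,
            min_gap >= 1)
  list(gap_merge_threshold = gap_merge_threshold,
       min_align_score = min_align_score, window = window,
       min_gap = min_gap, align = align)
}

#' Resolve key components against the input assembly
#'
#' Materializes the sequence of every key component.  Component names
#' using the Bionano split-contig convention `NAME_subseq_START:END` map
#' to the 1-based inclusive slice `[START, END]` of input contig `NAME`;
#' all other components must match a FASTA record by name.
#'
#' @param assembly Named character vector of input contig sequences.
#' @param key Data.frame from [parse_key()].
#' @return List with `components` (data.frame: `component_id`,
#'   `component_name`, `length`, `source`, `src_start`, `src_end`) and
#'   `seqs` (named character vector of component sequences).
#' @export
resolve_components <- function(assembly, key) {
  m <- regmatches(key$component_name,
                  regexec("^(.*)_subseq_([0-9]+):([0-9]+)$",
                          key$component_name))
  src <- key$component_name; s1 <- rep(1, nrow(key)); s2 <- numeric(nrow(key))
  for (i in seq_len(nrow(key))) {
    if (length(m[[i]]) == 4L) {
      src[i] <- m[[i]][2L]
      s1[i] <- as.numeric(m[[i]][3L]); s2[i] <- as.numeric(m[[i]][4L])
    }
  }
  missing <- setdiff(unique(src), names(assembly))
  if (length(missing) > 0L) {
    stop("key names absent from the assembly FASTA: ",
         paste(missing, collapse = ", "))
  }
  seqs <- character(nrow(key))
  for (i in seq_len(nrow(key))) {
    full <- assembly[[src[i]]]
    if (s2[i] == 0) s2[i] <- nchar(full)
    if (s2[i] > nchar(full)) {
      stop("component ", key$component_name[i],
           ": subseq range exceeds contig ", src[i])
    }
    seqs[i] <- substr(full, s1[i], s2[i])
  }
  names(seqs) <- key$component_name
  comp <- data.frame(component_id = key$component_id,
                     component_name = key$component_name,
                     length = nchar(seqs), source = src,
                     src_start = s1, src_end = s2,
                     stringsAsFactors = FALSE)
  mism <- which(abs(comp$length - key$component_length) > 0)
  if (length(mism) > 0L) {
    warning("key length disagrees with sequence length for: ",
            paste(comp$component_name[mism], collapse = ", "))
  }
  list(components = comp, seqs = seqs)
}

#' Order alignments along an anchor
#'
#' Ascending anchor start; ties broken by descending confidence, then
#' ascending query map id.
#'
#' @param alignments List of [map_alignment()] objects, all referencing
#'   `anchor_id`.
#' @param anchor_id The anchor.
#' @return The reordered list.
#' @export
order_alignments <- function(alignments, anchor_id) {
  if (length(alignments) == 0L) return(alignments)
  stopifnot(all(vapply(alignments, `[[`, 0L, "anchor_id") == anchor_id))
  sa <- vapply(alignments, `[[`, 0, "anchor_start_bp")
  conf <- vapply(alignments, `[[`, 0, "confidence")
  qid <- vapply(alignments, `[[`, 0L, "query_map_id")
  alignments[order(sa, -conf, qid)]
}

#' Shared anchor labels of two alignments
#'
#' The anchor site ids aligned in both pair lists, ordered by anchor
#' position ascending.
#'
#' @param align_k,align_n [map_alignment()] objects on the same anchor and
#'   channel.
#' @param anchor_map The anchor [label_map()] (used to order by position).
#' @return A `shared_label_set`: list with `channel`, `anchor_site_ids`,
#'   `positions_bp`.
#' @export
shared_labels <- function(align_k, align_n, anchor_map) {
  if (align_k$channel != align_n$channel) {
    stop("shared_labels: alignments are on different label channels")
  }
  if (align_k$anchor_id != align_n$anchor_id) {
    stop("shared_labels: alignments are on different anchors")
  }
  ids <- intersect(align_k$pairs[, 1L], align_n$pairs[, 1L])
  pos <- map_positions(anchor_map, align_k$channel)
  pos_ids <- pos[as.character(ids)]
  o <- order(pos_ids)
  structure(list(channel = align_k$channel,
                 anchor_site_ids = as.integer(ids[o]),
                 positions_bp = unname(pos_ids[o])),
            class = "shared_label_set")
}

# label position of an anchor site on a query contig, in anchor-oriented
# coordinates (reverse-aligned contigs are mirrored: p -> len - p + 1)
query_cut_position <- function(align, anchor_site, contig_map, contig_len) {
  hit <- which(align$pairs[, 1L] == anchor_site)
  if (length(hit) == 0L) {
    stop("anchor site ", anchor_site, " not paired in alignment ",
         align$entry_id)
  }
  qsite <- align$pairs[hit[1L], 2L]
  pos <- unname(map_positions(contig_map, align$channel)[as.character(qsite)])
  if (is.na(pos)) {
    stop("data inconsistency: map ", align$query_map_id,
         " has no site ", qsite, " in channel ", align$channel)
  }
  if (align$orientation == "reverse") contig_len - pos + 1 else pos
}

#' Fuse two contigs at their last shared anchor label
#'
#' The shared label closest to the junction (greatest anchor position) is
#' taken; its position on each contig is read from that contig's own label
#' map; the left contig is kept through the label, the right contig from
#' just after it.  Reverse-aligned contigs are mirrored into anchor
#' orientation before the cut.
#'
#' @param align_k,align_n Alignments of the left/right contig.
#' @param shared [shared_labels()] result (non-empty).
#' @param map_k,map_n The contigs' [label_map()]s.
#' @param len_k,len_n Contig lengths (bp).
#' @return A junction decision list with `kind = "fuse_at_label"`, the
#'   oriented cut positions `cut_k`, `cut_n`, the label id and channel.
#' @export
merge_at_shared_label <- function(align_k, align_n, shared, map_k, map_n,
                                  len_k, len_n) {
  if (length(shared$anchor_site_ids) == 0L) {
    stop("merge_at_shared_label: no shared labels")
  }
  l <- shared$anchor_site_ids[length(shared$anchor_site_ids)]
  cut_k <- query_cut_position(align_k, l, map_k, len_k)
  cut_n <- query_cut_position(align_n, l, map_n, len_n)
  list(kind = "fuse_at_label", label = l, channel = shared$channel,
       cut_k = round_half_up(cut_k), cut_n = round_half_up(cut_n))
}

#' Estimate a junction gap size from optical-map coordinates
#'
#' The distance on the anchor between the facing alignment ends, minus the
#' unaligned contig tails: `n = Sa_n - Ea_k`, `d_k = Size_k - Em_k`,
#' `d_n = Sm_n`, `g = n - d_k - d_n`.  For reverse-aligned contigs the
#' query coordinates are mirrored into anchor orientation first.  The
#' estimate may be negative (a predicted overlap).
#'
#' @param align_k,align_n Alignments of the left/right contig on the same
#'   anchor.
#' @param size_k Length of the left contig (bp).
#' @param size_n Length of the right contig; only required when `align_n`
#'   is reverse-oriented.
#' @return The gap estimate `g` in bp.
#' @export
estimate_gap_size <- function(align_k, align_n, size_k, size_n = NULL) {
  n <- align_n$anchor_start_bp - align_k$anchor_end_bp
  em_k <- if (align_k$orientation == "reverse") {
    size_k - align_k$query_start_bp + 1
  } else align_k$query_end_bp
  d_k <- size_k - em_k
  sm_n <- if (align_n$orientation == "reverse") {
    if (is.null(size_n)) {
      stop("size_n is required for a reverse-oriented right contig")
    }
    size_n - align_n$query_end_bp + 1
  } else align_n$query_start_bp
  n - d_k - sm_n
}

#' Resolve a junction without shared labels
#'
#' If the gap estimate is at most `gap_merge_threshold`, the terminal
#' window of the left contig is locally aligned against the initial window
#' of the right contig; a score above `min_align_score` fuses the contigs
#' at the alignment start on each side (removing exactly one copy of the
#' duplicated region).  Otherwise (or when the aligner finds nothing) a
#' run of Ns of the estimated size is emitted, floored at the `min_gap`
#' sentinel.
#'
#' @param seq_k,seq_n Current anchor-oriented sequences of the two
#'   contigs.
#' @param g Gap estimate from [estimate_gap_size()].
#' @param params [scaffold_params()].
#' @param aligner Alignment backend with the [local_align()] contract.
#' @return A junction decision list: `kind = "fuse_by_alignment"` with
#'   current-coordinate `cut_k` (keep left contig through it) and
#'   `keep_n_from` (first kept base of the right contig), or
#'   `kind = "sized_gap"` with `emitted_gap`.
#' @export
resolve_unlabelled_junction <- function(seq_k, seq_n, g,
                                        params = scaffold_params(),
                                        aligner = local_align) {
  len_k <- nchar(seq_k); len_n <- nchar(seq_n)
  if (g <= params$gap_merge_threshold) {
    w_k <- min(params$window, len_k); w_n <- min(params$window, len_n)
    tail_k <- substr(seq_k, len_k - w_k + 1L, len_k)
    head_n <- substr(seq_n, 1L, w_n)
    al <- tryCatch(aligner(tail_k, head_n, params$align),
                   error = function(e) {
                     warning("aligner failed at junction (",
                             conditionMessage(e), "); emitting a gap")
                     NULL
                   })
    if (!is.null(al) && al$score > params$min_align_score) {
      cut_k <- (len_k - w_k) + al$a_start - 1L
      if (cut_k >= 1L && al$b_start < len_n) {
        return(list(kind = "fuse_by_alignment", score = al$score,
                    cut_k = cut_k, keep_n_from = al$b_start,
                    alignment = al))
      }
    }
    emitted <- max(round_half_up(g), params$min_gap)
  } else {
    emitted <- round_half_up(g)
  }
  list(kind = "sized_gap", g = g, emitted_gap = emitted)
}

#' Resolve a contained contig
#'
#' For a contig whose anchor span lies strictly inside another contig's
#' span: the outermost shared labels bound the contained region; whichever
#' contig has more of its labels aligned inside that region wins.  If the
#' contained contig wins, its sequence replaces the host's segment between
#' the two labels; otherwise the host is left unchanged and the contained
#' contig becomes a singleton.  Ties and absent shared labels keep the
#' host (conservative).
#'
#' @param align_k,align_n Host / contained alignments (same anchor and
#'   channel).
#' @param anchor_map The anchor [label_map()].
#' @param map_k,map_n Contig [label_map()]s.
#' @param len_k,len_n Contig lengths.
#' @return A decision list: `kind = "containment_insert"` with host cut
#'   coordinates and the kept insert range (all anchor-oriented), or
#'   `kind = "containment_singleton"`.
#' @export
resolve_containment <- function(align_k, align_n, anchor_map, map_k, map_n,
                                len_k, len_n) {
  shared <- shared_labels(align_k, align_n, anchor_map)
  if (length(shared$anchor_site_ids) < 2L) {
    return(list(kind = "containment_singleton", channel = align_n$channel,
                reason = if (length(shared$anchor_site_ids) == 0L)
                  "no shared labels" else "a single shared label"))
  }
  l_l <- shared$anchor_site_ids[1L]
  l_r <- shared$anchor_site_ids[length(shared$anchor_site_ids)]
  pos <- map_positions(anchor_map, shared$channel)
  lo <- pos[[as.character(l_l)]]; hi <- pos[[as.character(l_r)]]
  count_in <- function(al) {
    p <- pos[as.character(al$pairs[, 1L])]
    sum(!is.na(p) & p >= lo & p <= hi)
  }
  n_k <- count_in(align_k); n_n <- count_in(align_n)
  if (n_n <= n_k) {
    return(list(kind = "containment_singleton", channel = align_n$channel,
                labels_host = n_k, labels_contained = n_n,
                reason = "host has at least as many labels"))
  }
  host_left <- query_cut_position(align_k, l_l, map_k, len_k)
  host_right <- query_cut_position(align_k, l_r, map_k, len_k)
  ins_left <- query_cut_position(align_n, l_l, map_n, len_n)
  ins_right <- query_cut_position(align_n, l_r, map_n, len_n)
  if (host_left < 1 || host_right <= host_left + 1 ||
      ins_right <= ins_left) {
    return(list(kind = "containment_singleton", channel = align_n$channel,
                reason = "degenerate label geometry"))
  }
  list(kind = "containment_insert", channel = align_n$channel,
       labels_host = n_k, labels_contained = n_n,
       host_left_end = round_half_up(host_left),
       host_right_start = round_half_up(host_right) + 1,
       ins_from = round_half_up(ins_left) + 1,
       ins_to = round_half_up(ins_right))
}

# -- helpers for build_scaffolds -------------------------------------------

align_field <- function(alignments, field, type = 0) {
  vapply(alignments, `[[`, type, field)
}

# pick the channel for a shared-label fusion: the channel whose last shared
# label sits furthest along the anchor; ties broken by more shared labels
pick_shared_channel <- function(cands) {
  if (length(cands) == 0L) return(NULL)
  last_pos <- vapply(cands, function(s) max(s$shared$positions_bp), 0)
  n_lab <- vapply(cands, function(s) length(s$shared$anchor_site_ids), 0L)
  cands[[order(-last_pos, -n_lab)[1L]]]
}

#' Build scaffold plans from a hybrid-scaffolding bundle
#'
#' The full junction-resolution pass: per anchor, alignments are ordered,
#' contained contigs are detected and resolved first, and every remaining
#' adjacent pair is resolved by shared-label fusion, alignment rescue, or
#' a sized gap.  Contigs absent from every alignment are emitted unchanged
#' as singletons.
#'
#' @param assembly Named character vector of input contig sequences (from
#'   [read_fasta()]).
#' @param key Key table from [parse_key()], or a named list of key tables
#'   by channel.
#' @param contig_maps,anchor_maps Named lists by channel of [parse_cmap()]
#'   results.
#' @param alignments List of [map_alignment()]s (any channel mix).
#' @param params [scaffold_params()].
#' @return List with `plans` (one [scaffold_plan()] per anchor),
#'   `singletons` (component names emitted unchanged), `report` (one row
#'   per junction decision), `components` (component table), `seqs`
#'   (component sequences), and `ledger` (exact base accounting).
#' @export
build_scaffolds <- function(assembly, key, contig_maps, anchor_maps,
                            alignments, params = scaffold_params()) {
  if (is.data.frame(key)) {
    channels <- unique(align_field(alignments, "channel", 0L))
    if (length(channels) == 0L) channels <- 1L
    key <- setNames(rep(list(key), length(channels)), as.character(channels))
  }
  key_all <- unique(do.call(rbind, unname(key)))
  rc <- resolve_components(assembly, key_all)
  comps <- rc$components; seqs <- rc$seqs

  # (channel, map id) -> component name
  comp_of <- function(al) {
    k <- key[[as.character(al$channel)]]
    if (is.null(k)) k <- key[[1L]]
    i <- match(al$query_map_id, k$component_id)
    if (is.na(i)) NA_character_ else k$component_name[i]
  }
  al_comp <- vapply(alignments, comp_of, "")
  if (anyNA(al_comp) || any(al_comp == "")) {
    bad <- unique(align_field(alignments, "query_map_id",
                              0L)[is.na(al_comp) | al_comp == ""])
    stop("aligned map id(s) missing from the key file: ",
         paste(bad, collapse = ", "))
  }

  # primary alignment per component: highest confidence, then entry id
  primary <- list()
  for (i in seq_along(alignments)) {
    nm <- al_comp[i]; al <- alignments[[i]]
    cur <- primary[[nm]]
    if (is.null(cur) || al$confidence > cur$confidence ||
        (al$confidence == cur$confidence && al$entry_id < cur$entry_id)) {
      primary[[nm]] <- al
    }
  }
  for (nm in names(primary)) {
    others <- which(al_comp == nm &
                      align_field(alignments, "anchor_id", 0L) !=
                      primary[[nm]]$anchor_id)
    if (length(others) > 0L) {
      message("component ", nm, ": discarding ", length(others),
              " alignment(s) to non-primary anchors")
    }
  }
  # alignments usable for junction work: same component & primary anchor
  anchor_of <- function(nm) primary[[nm]]$anchor_id
  comp_aligns <- function(nm) {
    alignments[al_comp == nm &
                 align_field(alignments, "anchor_id", 0L) == anchor_of(nm)]
  }
  cmap_of <- function(nm, ch) {
    k <- key[[as.character(ch)]]
    if (is.null(k)) k <- key[[1L]]
    id <- k$component_id[match(nm, k$component_name)]
    contig_maps[[as.character(ch)]][[as.character(id)]]
  }
  comp_len <- setNames(comps$length, comps$component_name)

  anchors <- sort(unique(vapply(primary, `[[`, 0L, "anchor_id")))
  plans <- list(); report <- list(); singleton_names <- character(0)
  add_report <- function(anchor, left, right, kind, channel = NA,
                         label = NA, score = NA, g = NA, emitted = NA,
                         removed = 0) {
    report[[length(report) + 1L]] <<- data.frame(
      anchor = anchor, left = left, right = right, kind = kind,
      channel = channel, label = label, score = score, g_estimate = g,
      emitted_gap = emitted, removed_bases = removed,
      stringsAsFactors = FALSE)
  }

  for (anchor in anchors) {
    on_anchor <- names(primary)[vapply(primary, `[[`, 0L, "anchor_id") ==
                                  anchor]
    ord <- order_alignments(primary[on_anchor], anchor)
    ord_names <- names(ord)
    frags <- list()
    for (nm in ord_names) {
      frags[[nm]] <- frag_new(nm, comp_len[[nm]],
                              primary[[nm]]$orientation)
    }

    # containment pass: strict span nesting against any kept predecessor
    kept <- character(0)
    for (j in seq_along(ord_names)) {
      nm <- ord_names[j]; a_j <- primary[[nm]]
      host <- NULL
      for (h in rev(kept)) {
        a_h <- primary[[h]]
        if (a_j$anchor_start_bp >= a_h$anchor_start_bp &&
            a_j$anchor_end_bp <= a_h$anchor_end_bp &&
            (a_j$anchor_start_bp > a_h$anchor_start_bp ||
             a_j$anchor_end_bp < a_h$anchor_end_bp)) { host <- h; break }
      }
      if (is.null(host)) { kept <- c(kept, nm); next }
      # choose the channel with the most shared labels
      cands <- list()
      for (ah in comp_aligns(host)) {
        for (an in comp_aligns(nm)) {
          if (ah$channel != an$channel) next
          amap <- anchor_maps[[as.character(ah$channel)]][[as.character(anchor)]]
          sh <- shared_labels(ah, an, amap)
          cands[[length(cands) + 1L]] <- list(
            shared = sh, a_k = ah, a_n = an, amap = amap,
            n = length(sh$anchor_site_ids))
        }
      }
      n_shared <- vapply(cands, `[[`, 0L, "n")
      decision <- list(kind = "containment_singleton",
                       reason = "no shared labels")
      if (length(cands) > 0L && max(n_shared) > 0L) {
        best <- cands[[which.max(n_shared)]]
        decision <- resolve_containment(
          best$a_k, best$a_n, best$amap,
          cmap_of(host, best$a_k$channel), cmap_of(nm, best$a_n$channel),
          comp_len[[host]], comp_len[[nm]])
      }
      if (decision$kind == "containment_insert") {
        strand <- if (primary[[nm]]$orientation == "reverse") "-" else "+"
        ins_part <- if (strand == "+") {
          part_slice(nm, decision$ins_from, decision$ins_to, "+")
        } else {
          part_slice(nm, comp_len[[nm]] - decision$ins_to + 1,
                     comp_len[[nm]] - decision$ins_from + 1, "-")
        }
        before <- frag_len(frags[[host]]) + comp_len[[nm]]
        frags[[host]] <- frag_replace(frags[[host]],
                                      decision$host_left_end,
                                      decision$host_right_start,
                                      list(ins_part))
        removed <- before - frag_len(frags[[host]])
        add_report(anchor, host, nm, "containment_insert",
                   channel = decision$channel, removed = removed)
      } else {
        singleton_names <- c(singleton_names, nm)
        add_report(anchor, host, nm, "containment_singleton",
                   channel = decision$channel %||% NA)
      }
    }

    # adjacent-pair pass over the remaining (linear) contigs
    if (length(kept) == 0L) next
    acc_parts <- NULL
    for (j in seq_along(kept)) {
      nm <- kept[j]
      if (j == 1L) { acc_parts <- NULL; prev <- nm; next }
      left <- prev; right <- nm
      a_l <- primary[[left]]; a_r <- primary[[right]]
      cands <- list()
      for (ak in comp_aligns(left)) {
        for (an in comp_aligns(right)) {
          if (ak$channel != an$channel) next
          amap <- anchor_maps[[as.character(ak$channel)]][[as.character(anchor)]]
          sh <- shared_labels(ak, an, amap)
          if (length(sh$anchor_site_ids) == 0L) next
          cands[[length(cands) + 1L]] <- list(shared = sh, a_k = ak,
                                              a_n = an, amap = amap)
        }
      }
      chosen <- pick_shared_channel(cands)
      fused <- FALSE
      if (!is.null(chosen)) {
        dec <- merge_at_shared_label(
          chosen$a_k, chosen$a_n, chosen$shared,
          cmap_of(left, chosen$a_k$channel),
          cmap_of(right, chosen$a_n$channel),
          comp_len[[left]], comp_len[[right]])
        before_l <- frag_len(frags[[left]])
        before_r <- frag_len(frags[[right]])
        trimmed <- tryCatch(list(
          l = frag_trim_right_orig(frags[[left]], dec$cut_k),
          r = frag_trim_left_orig(frags[[right]], dec$cut_n)),
          error = function(e) NULL)
        if (!is.null(trimmed)) {
          frags[[left]] <- trimmed$l; frags[[right]] <- trimmed$r
          removed <- (before_l - frag_len(trimmed$l)) +
            (before_r - frag_len(trimmed$r))
          add_report(anchor, left, right, "fuse_at_label",
                     channel = dec$channel, label = dec$label,
                     removed = removed)
          fused <- TRUE
        }
      }
      if (!fused) {
        g <- estimate_gap_size(a_l, a_r, comp_len[[left]],
                               comp_len[[right]])
        seq_l <- render_frag(frags[[left]], seqs)
        seq_r <- render_frag(frags[[right]], seqs)
        dec <- resolve_unlabelled_junction(seq_l, seq_r, g, params)
        if (dec$kind == "fuse_by_alignment") {
          before_l <- nchar(seq_l); before_r <- nchar(seq_r)
          trimmed <- tryCatch(list(
            l = frag_trim_right(frags[[left]], dec$cut_k),
            r = frag_trim_left(frags[[right]], dec$keep_n_from - 1L)),
            error = function(e) NULL)
          if (!is.null(trimmed)) {
            frags[[left]] <- trimmed$l; frags[[right]] <- trimmed$r
            removed <- (before_l - frag_len(trimmed$l)) +
              (before_r - frag_len(trimmed$r))
            add_report(anchor, left, right, "fuse_by_alignment",
                       score = dec$score, g = g, removed = removed)
          } else {
            dec <- list(kind = "sized_gap", g = g,
                        emitted_gap = max(round_half_up(g), params$min_gap))
          }
        }
        if (dec$kind == "sized_gap") {
          add_report(anchor, left, right, "sized_gap", g = g,
                     emitted = dec$emitted_gap)
        }
      }
      prev <- nm
    }

    # assemble the plan for this anchor
    parts <- frags[[kept[1L]]]$parts
    if (length(kept) > 1L) {
      rep_rows <- do.call(rbind, report)
      for (j in 2L:length(kept)) {
        left <- kept[j - 1L]; right <- kept[j]
        row <- rep_rows[rep_rows$anchor == anchor &
                          rep_rows$left == left & rep_rows$right == right &
                          rep_rows$kind %in% c("fuse_at_label",
                                               "fuse_by_alignment",
                                               "sized_gap"), ]
        row <- row[nrow(row), ]
        if (row$kind == "sized_gap") {
          parts <- c(parts, list(part_gap(row$emitted_gap, row$g_estimate)))
        }
        parts <- c(parts, frags[[right]]$parts)
      }
    }
    plans[[length(plans) + 1L]] <-
      scaffold_plan(sprintf("scaffold_%d", anchor), parts)
  }

  # contigs absent from every alignment: singletons, input order
  unaligned <- setdiff(comps$component_name, names(primary))
  singleton_names <- c(singleton_names,
                       unaligned[order(match(unaligned,
                                             comps$component_name))])
  report <- if (length(report) > 0L) {
    do.call(rbind, report)
  } else {
    data.frame(anchor = integer(), left = character(), right = character(),
               kind = character(), channel = numeric(), label = numeric(),
               score = numeric(), g_estimate = numeric(),
               emitted_gap = numeric(), removed_bases = numeric())
  }

  input_total <- sum(comps$length)
  gap_total <- sum(report$emitted_gap[report$kind == "sized_gap"])
  removed_total <- sum(report$removed_bases)
  ledger <- list(input_bases = input_total, removed_bases = removed_total,
                 gap_bases = gap_total,
                 expected_output = input_total - removed_total + gap_total)

  list(plans = plans, singletons = singleton_names, report = report,
       components = comps, seqs = seqs, ledger = ledger)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render scaffolder results to FASTA sequences and AGP plans
#'
#' @param result From [build_scaffolds()].
#' @return List with `fasta` (named character vector: scaffolds then
#'   singletons) and `plans` (scaffold plans plus one single-slice plan
#'   per singleton, the input to [write_agp()]).
#' @export
render_scaffolds <- function(result) {
  single_plans <- lapply(result$singletons, function(nm) {
    scaffold_plan(nm, list(part_slice(nm, 1,
                                      result$components$length[
                                        match(nm, result$components$component_name)],
                                      "+")))
  })
  all_plans <- c(result$plans, single_plans)
  fasta <- vapply(all_plans, render_plan, "", seqs = result$seqs)
  names(fasta) <- vapply(all_plans, `[[`, "", "name")
  list(fasta = fasta, plans = all_plans)
}
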