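# Synthetic-fixture simulator: a random genome fragmented into contigs
# with gaps, overlaps and contained contigs, labelled in silico at motif
# occurrences, with a simulated anchor map and XMAP alignments - plus a
# ground-truth manifest.  This emulates the file bundle a Bionano
# hybrid-scaffolding run leaves behind, with every junction's true nature
# known, so the whole junction-resolution engine is testable end to end.

#' Fixture specification
#'
#' Defaults describe the desk-scale simulation: a 5 Mb genome split into
#' contigs by 8 gap junctions (3-100 kb) and 8 overlap junctions, with 2
#' contained contigs, labelled with the DLE-1 (CTTAAG) and BspQI (GCTCTTC)
#' motifs.  Overlap junctions fall into three sub-populations matching the
#' outcome classes seen in practice: `labelled` (the overlap contains at
#' least one shared label site, resolvable by label fusion), `alignable`
#' (>= 6 kb overlap but the right-hand contig's labels in the overlap are
#' not aligned, resolvable only by sequence alignment) and `tiny`
#' (a sub-resolution overlap, default <= 200 bp, not resolvable at all).
#'
#' @param genome_length Genome size in bp.
#' @param seed Integer seed; every generator draw derives from it.
#' @param n_gap_junctions,gap_size_range Count and size range (bp) of
#'   planted gaps.
#' @param n_overlap_junctions,overlap_size_range Count and size range (bp)
#'   of planted overlaps (the `labelled`/`alignable` classes; `tiny`
#'   overlaps use `tiny_range`).
#' @param overlap_classes Named fractions for `labelled`, `alignable`,
#'   `tiny`; must sum to 1.
#' @param tiny_range Size range of `tiny` overlaps.
#' @param n_contained Number of contained contigs (exact subsequences of a
#'   host contig).
#' @param contained_rich_fraction Fraction of contained contigs that carry
#'   more aligned labels than their host segment (these should be
#'   re-inserted; the rest should come out as singletons).
#' @param motifs One recognition motif per label channel.
#' @param label_noise_sd Relative multiplicative noise applied to
#'   inter-label distances on the anchor (sizing error grows with
#'   distance).
#' @param label_fn_rate,label_fp_rate Fractions of anchor labels dropped /
#'   spurious labels added.
#' @param reverse_fraction Fraction of contigs embedded
#'   reverse-complemented.
#' @param n_subseq Number of contigs emitted through the Bionano
#'   split-contig key convention `NAME_subseq_START:END` (the FASTA record
#'   gets flanking filler sequence; the key points at the real slice).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(genome_length = 5e6, seed = 1L,
                         n_gap_junctions = 8L,
                         gap_size_range = c(3400, 100000),
                         n_overlap_junctions = 8L,
                         overlap_size_range = c(6000, 100000),
                         overlap_classes = c(labelled = 0.6,
                                             alignable = 0.2, tiny = 0.2),
                         tiny_range = c(50, 200),
                         n_contained = 2L,
                         contained_rich_fraction = 0.5,
                         motifs = c("CTTAAG", "GCTCTTC"),
                         label_noise_sd = 0.003,
                         label_fn_rate = 0.02,
                         label_fp_rate = 0.01,
                         reverse_fraction = 0.25,
                         n_subseq = 0L) {
  stopifnot(genome_length > 0, n_gap_junctions >= 0,
            n_overlap_junctions >= 0, n_contained >= 0,
            all(gap_size_range > 0), all(overlap_size_range > 0),
            label_noise_sd >= 0, label_fn_rate >= 0, label_fn_rate <= 1,
            label_fp_rate >= 0, label_fp_rate <= 1,
            abs(sum(overlap_classes) - 1) < 1e-9,
            length(motifs) >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a uniform random genome
#'
#' @param length Genome length (> 0).
#' @param seed Integer seed.
#' @return Character scalar of A/C/G/T.
#' @export
generate_genome <- function(length, seed = 1L) {
  if (length <= 0) stop("genome length must be > 0")
  with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  })
}

#' In-silico digestion: label positions of a motif on both strands
#'
#' Returns the label-site coordinate of every occurrence of `motif` on the
#' forward strand and of its reverse complement.  The site coordinate is
#' strand-aware - the first base of a forward occurrence, the last base of
#' a reverse-complement occurrence - so the same physical genomic position
#' is reported no matter which strand a sequence is read from.
#' Palindromic motifs (their own reverse complement, like CTTAAG) match
#' once and report the occurrence start.
#'
#' @param sequence Character scalar.
#' @param motif Non-empty recognition motif.
#' @return Sorted, deduplicated integer positions (1-based).
#' @export
digest_sequence <- function(sequence, motif) {
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  subj <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, subj))
  rc <- revcomp(motif)
  if (rc == motif) return(sort(unique(fwd)))
  rev_end <- Biostrings::end(Biostrings::matchPattern(rc, subj))
  sort(unique(c(fwd, rev_end)))
}

# occurrence intervals (both strands) of a motif; used to decide whether a
# label site lies fully inside a region
digest_intervals <- function(sequence, motif) {
  subj <- Biostrings::DNAString(sequence)
  m <- Biostrings::matchPattern(motif, subj)
  st <- Biostrings::start(m); en <- Biostrings::end(m)
  pos <- st
  rc <- revcomp(motif)
  if (rc != motif) {
    m2 <- Biostrings::matchPattern(rc, subj)
    st <- c(st, Biostrings::start(m2)); en <- c(en, Biostrings::end(m2))
    pos <- c(pos, Biostrings::end(m2))
  }
  o <- order(pos)
  df <- data.frame(start = st[o], end = en[o], pos = pos[o])
  df[!duplicated(df$pos), , drop = FALSE]
}

#' Fragment a genome into contigs with planted junctions
#'
#' Walks the genome left to right placing one contig per step; between
#' consecutive contigs a junction of planned type is planted (a gap skips
#' sequence, an overlap backs up so both contigs carry the shared region).
#' `labelled`-class overlaps are widened, when necessary, so the overlap
#' contains at least one full label-site occurrence of the first motif.
#' Contained contigs are exact subsequences of interior regions of large
#' contigs.  A recorded fraction of contigs is embedded
#' reverse-complemented.
#'
#' @param genome Character scalar from [generate_genome()].
#' @param spec A [fixture_spec()].
#' @return List with `contigs` (named character vector, native
#'   orientation) and `truth` (a `fixture_truth`: `contigs`, `junctions`,
#'   `contained` data frames).
#' @export
fragment_genome <- function(genome, spec) {
  glen <- nchar(genome)
  if (glen != spec$genome_length) spec$genome_length <- glen
  n_gap <- spec$n_gap_junctions; n_ov <- spec$n_overlap_junctions
  n_j <- n_gap + n_ov
  n_contigs <- n_j + 1L

  with_seed(spec$seed + 1L, {
    types <- sample(c(rep("gap", n_gap), rep("overlap", n_ov)))
    cls_counts <- round(spec$overlap_classes * n_ov)
    while (sum(cls_counts) > n_ov) cls_counts[which.max(cls_counts)] <-
        cls_counts[which.max(cls_counts)] - 1L
    while (sum(cls_counts) < n_ov) cls_counts[which.min(cls_counts)] <-
        cls_counts[which.min(cls_counts)] + 1L
    classes <- sample(rep(names(cls_counts), cls_counts))
    jsizes <- numeric(n_j); jclass <- rep(NA_character_, n_j)
    ov_i <- 0L
    for (i in seq_len(n_j)) {
      if (types[i] == "gap") {
        jsizes[i] <- round(runif(1, spec$gap_size_range[1L],
                                 spec$gap_size_range[2L]))
      } else {
        ov_i <- ov_i + 1L
        jclass[i] <- classes[ov_i]
        rng <- switch(classes[ov_i],
                      labelled = c(max(2500, spec$overlap_size_range[1L]),
                                   spec$overlap_size_range[2L]),
                      alignable = c(max(6000, spec$overlap_size_range[1L]),
                                    min(25000, spec$overlap_size_range[2L])),
                      tiny = spec$tiny_range)
        rng[2L] <- max(rng)
        jsizes[i] <- round(runif(1, rng[1L], rng[2L]))
      }
    }
    net <- sum(jsizes[types == "gap"]) - sum(jsizes[types == "overlap"])
    base_len <- (glen - net) / n_contigs
    min_len <- 2 * max(c(jsizes[types == "overlap"], 0)) + 5000
    if (base_len < max(min_len / 2, 10000)) {
      stop("fixture spec infeasible for genome length ", glen,
           "; need at least ", ceiling(n_contigs * min_len + net), " bp")
    }
    lens <- round(base_len * runif(n_contigs, 0.6, 1.4))
    strands <- ifelse(runif(n_contigs) < spec$reverse_fraction, "-", "+")

    # label intervals of channel 1, for forcing labels into overlaps
    occ <- digest_intervals(genome, spec$motifs[[1L]])

    gs <- integer(n_contigs); ge <- integer(n_contigs)
    s <- 1L
    for (i in seq_len(n_contigs)) {
      e <- min(s + lens[i] - 1L, glen)
      if (i == n_contigs) e <- glen
      gs[i] <- s; ge[i] <- e
      if (i <= n_j) {
        if (types[i] == "gap") {
          s <- e + jsizes[i] + 1L
        } else {
          ov <- min(jsizes[i], e - gs[i] - 5000)
          s <- e - ov + 1L
          if (identical(jclass[i], "labelled")) {
            inside <- occ$start >= s & occ$end <= e
            if (!any(inside)) {
              cand <- occ$end <= e & occ$start > gs[i] + 2500
              if (!any(cand)) {
                stop("cannot force a label into overlap at junction ", i)
              }
              s <- max(occ$start[cand]) - 100L
              ov <- e - s + 1L
            }
          }
          jsizes[i] <- ov
        }
        if (s > glen - 5000) {
          stop("fixture spec infeasible for genome length ", glen,
               "; junctions overran the genome")
        }
      }
    }
    if (ge[n_contigs] - gs[n_contigs] < 1000) {
      stop("fixture spec infeasible: last contig too short")
    }

    names_v <- sprintf("contig_%d", seq_len(n_contigs))
    contigs <- character(n_contigs)
    for (i in seq_len(n_contigs)) {
      seq_i <- substr(genome, gs[i], ge[i])
      contigs[i] <- if (strands[i] == "-") revcomp(seq_i) else seq_i
    }
    names(contigs) <- names_v

    junctions <- data.frame(
      left = names_v[seq_len(n_j)], right = names_v[seq_len(n_j) + 1L],
      type = types, class = jclass, true_size = jsizes,
      stringsAsFactors = FALSE)

    # contained contigs: exact interior subsequences of large hosts
    contained <- data.frame(name = character(), host = character(),
                            genome_start = integer(), genome_end = integer(),
                            strand = character(), rich = logical(),
                            stringsAsFactors = FALSE)
    if (spec$n_contained > 0L) {
      # usable host interior: clear of the regions shared with neighbours
      # at overlap junctions, so containment geometry stays unambiguous
      ov_at <- ifelse(types == "overlap", jsizes, 0)
      left_ov <- c(0, ov_at); right_ov <- c(ov_at, 0)
      int_lo <- gs + left_ov + 15000
      int_hi <- ge - right_ov - 15000
      host_ok <- which(int_hi - int_lo + 1 >= 80000)
      if (length(host_ok) < spec$n_contained) {
        stop("fixture spec infeasible: not enough large contigs to host ",
             spec$n_contained, " contained contig(s)")
      }
      hosts <- host_ok[sample.int(length(host_ok), spec$n_contained)]
      n_rich <- round(spec$contained_rich_fraction * spec$n_contained)
      rich <- sample(rep(c(TRUE, FALSE),
                         c(n_rich, spec$n_contained - n_rich)))
      for (j in seq_len(spec$n_contained)) {
        h <- hosts[j]
        room <- int_hi[h] - int_lo[h] + 1
        clen <- round(runif(1, 0.3, 0.6) * room)
        clen <- max(30000L, min(clen, room - 20000L))
        cs <- int_lo[h] + round(runif(1, 0, room - clen))
        ce <- cs + clen - 1L
        cstrand <- if (runif(1) < spec$reverse_fraction) "-" else "+"
        nm <- sprintf("contained_%d", j)
        seq_c <- substr(genome, cs, ce)
        contigs[[nm]] <- if (cstrand == "-") revcomp(seq_c) else seq_c
        contained <- rbind(contained, data.frame(
          name = nm, host = names_v[h], genome_start = cs, genome_end = ce,
          strand = cstrand, rich = rich[j], stringsAsFactors = FALSE))
      }
    }

    contig_df <- data.frame(
      name = names(contigs),
      genome_start = c(gs, contained$genome_start),
      genome_end = c(ge, contained$genome_end),
      strand = c(strands, contained$strand),
      role = c(rep("linear", n_contigs),
               rep("contained", nrow(contained))),
      stringsAsFactors = FALSE)

    truth <- structure(list(genome_length = glen, contigs = contig_df,
                            junctions = junctions, contained = contained),
                       class = "fixture_truth")
    list(contigs = contigs, truth = truth)
  })
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf(
    "fixture truth: %.0f bp genome, %d contig(s), %d junction(s) (%d gap, %d overlap), %d contained\n",
    x$genome_length, nrow(x$contigs), nrow(x$junctions),
    sum(x$junctions$type == "gap"), sum(x$junctions$type == "overlap"),
    nrow(x$contained)))
  invisible(x)
}

#' Build the anchor/alignment bundle for a fragmented genome
#'
#' Simulates what the Bionano scaffolder leaves behind: per channel, an
#' anchor label map (the in-silico digest of the genome with
#' interval-multiplicative sizing noise, false-negative and false-positive
#' labels), per-contig label maps (exact digests of the contig sequences),
#' and XMAP records aligning each contig map to the anchor with its true
#' orientation and explicit site pairs.  Label suppression implements the
#' planted junction classes: `alignable`/`tiny` overlaps lose the
#' right-hand contig's aligned labels inside the overlap, label-rich
#' contained contigs out-label their host in the contained region, and
#' label-poor ones keep only their two outermost shared labels.
#'
#' @param genome Character scalar.
#' @param contigs Named character vector from [fragment_genome()].
#' @param truth The matching `fixture_truth`.
#' @param spec The [fixture_spec()] used.
#' @return List with `key`, `contig_maps`, `anchor_maps` (per-channel
#'   lists), `alignments`, and the augmented `truth` (adds per-junction
#'   `label_in_overlap` and per-contig `aligned`).
#' @export
build_anchor_bundle <- function(genome, contigs, truth, spec) {
  glen <- nchar(genome)
  channels <- seq_along(spec$motifs)
  cdf <- truth$contigs
  with_seed(spec$seed + 2L, {
    anchor_maps <- list(); contig_maps <- list(); alignments <- list()
    label_in_overlap <- rep(NA, nrow(truth$junctions))
    aligned_any <- setNames(rep(FALSE, length(contigs)), names(contigs))
    entry_id <- 0L
    for (ch in channels) {
      motif <- spec$motifs[[ch]]
      tol <- nchar(motif)
      anchor_true <- digest_intervals(genome, motif)

      # false negatives / positives on the anchor
      keep <- runif(nrow(anchor_true)) >= spec$label_fn_rate
      apos_true <- anchor_true$pos[keep]
      n_fp <- round(spec$label_fp_rate * length(apos_true))
      fp_pos <- if (n_fp > 0) round(runif(n_fp, 1, glen)) else numeric(0)
      all_true <- sort(unique(c(apos_true, fp_pos)))
      is_real <- all_true %in% apos_true & !(all_true %in% fp_pos)

      # interval-multiplicative sizing noise, order preserving
      iv <- diff(c(0, all_true))
      noisy <- cumsum(iv * pmax(0.01, 1 + rnorm(length(iv),
                                                sd = spec$label_noise_sd)))
      noisy <- round(noisy, 1)
      anchor_len <- round(max(noisy, 0) + (glen - max(all_true, 0)), 1)
      site_ids <- seq_along(all_true)
      anchor_maps[[as.character(ch)]] <- list(`1` = label_map(
        1L, anchor_len,
        data.frame(channel = rep(ch, length(site_ids)),
                   site_id = site_ids, position_bp = noisy)))
      # lookup: true genome position -> (site id, noisy position)
      a_lookup_pos <- all_true
      a_lookup_id <- site_ids
      a_lookup_noisy <- noisy

      # per-junction overlap regions (for class-based suppression and the
      # label_in_overlap record)
      jr <- truth$junctions
      ov_regions <- lapply(seq_len(nrow(jr)), function(i) {
        if (jr$type[i] != "overlap") return(NULL)
        li <- match(jr$left[i], cdf$name); ri <- match(jr$right[i], cdf$name)
        c(cdf$genome_start[ri], cdf$genome_end[li])
      })

      cmaps <- list()
      for (ci in seq_len(nrow(cdf))) {
        nm <- cdf$name[ci]
        seq_c <- contigs[[nm]]
        clen <- nchar(seq_c)
        sites <- digest_sequence(seq_c, motif)
        cmaps[[as.character(ci)]] <- label_map(
          ci, clen, data.frame(channel = ch,
                               site_id = seq_along(sites),
                               position_bp = as.numeric(sites)))
        if (length(sites) < 2L) next
        gpos <- if (cdf$strand[ci] == "+") {
          cdf$genome_start[ci] - 1L + sites
        } else {
          cdf$genome_end[ci] - sites + 1L
        }
        o <- order(gpos)
        gpos <- gpos[o]; qsite <- seq_along(sites)[o]
        # pair to nearest surviving anchor site within motif-length tolerance
        idx <- findInterval(gpos, a_lookup_pos)
        best <- integer(length(gpos))
        for (k in seq_along(gpos)) {
          cand <- c(idx[k], idx[k] + 1L)
          cand <- cand[cand >= 1L & cand <= length(a_lookup_pos)]
          if (length(cand) == 0L) { best[k] <- NA_integer_; next }
          d <- abs(a_lookup_pos[cand] - gpos[k])
          best[k] <- if (min(d) <= tol) cand[which.min(d)] else NA_integer_
        }
        ok <- !is.na(best)

        # junction-class suppression: drop the right contig's pairs inside
        # unlabelled-class overlaps
        for (i in seq_len(nrow(jr))) {
          if (is.na(jr$class[i]) || jr$class[i] == "labelled") next
          if (jr$right[i] != nm) next
          reg <- ov_regions[[i]]
          ok <- ok & !(gpos >= reg[1L] & gpos <= reg[2L])
        }
        # contained-contig label thinning
        if (nrow(truth$contained) > 0L) {
          for (i in seq_len(nrow(truth$contained))) {
            cc <- truth$contained[i, ]
            inside <- gpos > cc$genome_start + tol &
              gpos < cc$genome_end - tol
            if (cc$rich && nm == cc$host) {
              # host keeps only its outermost labels in the region
              int_idx <- which(ok & inside)
              if (length(int_idx) > 2L) {
                ok[int_idx[-c(1L, length(int_idx))]] <- FALSE
              }
            } else if (!cc$rich && nm == cc$name) {
              int_idx <- which(ok & inside)
              if (length(int_idx) > 2L) {
                ok[int_idx[-c(1L, length(int_idx))]] <- FALSE
              }
            }
          }
        }

        if (sum(ok) < 2L) next
        aligned_any[[nm]] <- TRUE
        anchor_idx <- best[ok]
        pairs <- cbind(a_lookup_id[anchor_idx], qsite[ok])
        qpos_native <- as.numeric(sites)[qsite[ok]]
        entry_id <- entry_id + 1L
        alignments[[length(alignments) + 1L]] <- map_alignment(
          entry_id = entry_id, query_map_id = ci, anchor_id = 1L,
          query_start_bp = min(qpos_native), query_end_bp = max(qpos_native),
          anchor_start_bp = a_lookup_noisy[anchor_idx[1L]],
          anchor_end_bp = a_lookup_noisy[anchor_idx[length(anchor_idx)]],
          orientation = if (cdf$strand[ci] == "+") "forward" else "reverse",
          confidence = round(sum(ok) / 2, 2), channel = ch, pairs = pairs)
      }
      names(cmaps) <- vapply(cmaps, function(m) as.character(m$map_id), "")
      contig_maps[[as.character(ch)]] <- cmaps

      # record whether each overlap contains a full channel-1 label site
      if (ch == 1L) {
        for (i in seq_len(nrow(jr))) {
          if (jr$type[i] != "overlap") next
          reg <- ov_regions[[i]]
          label_in_overlap[i] <- any(anchor_true$start >= reg[1L] &
                                       anchor_true$end <= reg[2L])
        }
      }
    }

    key <- data.frame(component_id = seq_len(nrow(cdf)),
                      component_name = cdf$name,
                      component_length = nchar(contigs[cdf$name]),
                      stringsAsFactors = FALSE)
    truth$junctions$label_in_overlap <- label_in_overlap
    truth$contigs$aligned <- aligned_any[truth$contigs$name]
    list(key = key, contig_maps = contig_maps, anchor_maps = anchor_maps,
         alignments = alignments, truth = truth)
  })
}

#' Simulate a complete fixture
#'
#' Convenience wrapper: genome, fragmentation, anchor bundle.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genome`, `contigs`, `key`, `contig_maps`,
#'   `anchor_maps`, `alignments`, `truth`, `spec`.
#' @export
simulate_fixture <- function(spec = fixture_spec()) {
  genome <- generate_genome(spec$genome_length, spec$seed)
  fr <- fragment_genome(genome, spec)
  contigs <- fr$contigs
  # split-contig key convention exercise: wrap some contigs in filler flanks
  subseq_map <- NULL
  if (spec$n_subseq > 0L) {
    linear <- fr$truth$contigs$name[fr$truth$contigs$role == "linear"]
    pick <- with_seed(spec$seed + 3L,
                      sample(linear, min(spec$n_subseq, length(linear))))
    subseq_map <- data.frame(name = pick, flank = 500L,
                             stringsAsFactors = FALSE)
  }
  bundle <- build_anchor_bundle(genome, contigs, fr$truth, spec)
  fasta <- contigs
  if (!is.null(subseq_map)) {
    for (i in seq_len(nrow(subseq_map))) {
      nm <- subseq_map$name[i]; fl <- subseq_map$flank[i]
      pad <- with_seed(spec$seed + 4L + i,
                       paste(sample(c("A", "C", "G", "T"), 2L * fl,
                                    replace = TRUE), collapse = ""))
      clen <- nchar(contigs[[nm]])
      fasta[[nm]] <- paste0(substr(pad, 1L, fl), contigs[[nm]],
                            substr(pad, fl + 1L, 2L * fl))
      k <- match(nm, bundle$key$component_name)
      bundle$key$component_name[k] <-
        sprintf("%s_subseq_%d:%d", nm, fl + 1L, fl + clen)
    }
  }
  c(list(genome = genome, contigs = fasta, spec = spec), bundle)
}

#' Write a fixture bundle to disk in the formats the parsers consume
#'
#' @param fx A fixture from [simulate_fixture()].
#' @param dir Output directory (created if missing).
#' @return Named list of written paths.
#' @export
write_fixture_bundle <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "contigs.fasta"),
                key = file.path(dir, "components.key"),
                truth = file.path(dir, "truth_junctions.tsv"),
                truth_contigs = file.path(dir, "truth_contigs.tsv"),
                config = file.path(dir, "fixture_config.txt"))
  write_fasta(fx$contigs, paths$fasta)
  write_key(fx$key, paths$key)
  for (ch in names(fx$contig_maps)) {
    paths[[paste0("contig_cmap_", ch)]] <-
      file.path(dir, sprintf("contigs_ch%s.cmap", ch))
    write_cmap(fx$contig_maps[[ch]], paths[[paste0("contig_cmap_", ch)]])
    paths[[paste0("anchor_cmap_", ch)]] <-
      file.path(dir, sprintf("anchor_ch%s.cmap", ch))
    write_cmap(fx$anchor_maps[[ch]], paths[[paste0("anchor_cmap_", ch)]])
    paths[[paste0("xmap_", ch)]] <-
      file.path(dir, sprintf("alignments_ch%s.xmap", ch))
    ch_al <- Filter(function(a) a$channel == as.integer(ch), fx$alignments)
    write_xmap(ch_al, paths[[paste0("xmap_", ch)]])
  }
  write.table(fx$truth$junctions, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(fx$truth$contigs, paths$truth_contigs, sep = "\t",
              quote = FALSE, row.names = FALSE)
  sp <- fx$spec
  writeLines(sprintf("%s=%s", names(sp),
                     vapply(sp, function(v) paste(v, collapse = ","), "")),
             paths$config)
  invisible(paths)
}
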