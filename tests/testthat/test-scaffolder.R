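mk_align <- function(entry, qid, sa, ea, qs, qe, conf = 10, ch = 1L,
                     ori = "forward", pairs = cbind(1L, 1L), anchor = 1L) {
  map_alignment(entry, qid, anchor, qs, qe, sa, ea, ori, conf, ch, pairs)
}

test_that("alignments are ordered by anchor start with stated tie-breaks", {
  a1 <- mk_align(1, 5, 300, 400, 1, 100)
  a2 <- mk_align(2, 6, 100, 200, 1, 100)
  a3 <- mk_align(3, 7, 200, 300, 1, 100)
  ord <- order_alignments(list(a1, a2, a3), 1L)
  expect_equal(vapply(ord, `[[`, 0, "anchor_start_bp"), c(100, 200, 300))

  # equal starts: higher confidence first
  b1 <- mk_align(1, 5, 100, 400, 1, 100, conf = 9)
  b2 <- mk_align(2, 6, 100, 200, 1, 100, conf = 12)
  ord <- order_alignments(list(b1, b2), 1L)
  expect_equal(ord[[1L]]$confidence, 12)

  # equal starts and confidence: ascending query map id
  c1 <- mk_align(1, 9, 100, 400, 1, 100)
  c2 <- mk_align(2, 4, 100, 200, 1, 100)
  ord <- order_alignments(list(c1, c2), 1L)
  expect_equal(ord[[1L]]$query_map_id, 4L)

  expect_equal(order_alignments(list(), 1L), list())
  expect_equal(order_alignments(list(a1), 1L), list(a1))
})

test_that("shared labels are the anchor-ordered intersection of pair lists", {
  amap <- label_map(1L, 1e6, data.frame(channel = 1L, site_id = 1:10,
                                        position_bp = (1:10) * 1000))
  ak <- mk_align(1, 5, 5000, 7000, 1, 100, pairs = cbind(5:7, 1:3))
  an <- mk_align(2, 6, 7000, 8000, 1, 100, pairs = cbind(7:8, 1:2))
  sh <- shared_labels(ak, an, amap)
  expect_equal(sh$anchor_site_ids, 7L)

  disjoint <- mk_align(3, 7, 9000, 9500, 1, 50, pairs = cbind(9:10, 1:2))
  expect_length(shared_labels(ak, disjoint, amap)$anchor_site_ids, 0L)

  same <- mk_align(4, 8, 5000, 8000, 1, 100, pairs = cbind(c(7L, 5L, 6L, 8L), 1:4))
  both <- mk_align(5, 9, 5000, 8000, 1, 100, pairs = cbind(5:8, 1:4))
  sh4 <- shared_labels(same, both, amap)
  expect_equal(sh4$anchor_site_ids, 5:8)  # anchor-position order

  ch2 <- mk_align(6, 9, 5000, 8000, 1, 100, ch = 2L)
  expect_error(shared_labels(ak, ch2, amap), "channel")
})

test_that("shared-label fusion cuts both contigs at the last shared label", {
  amap <- label_map(1L, 1e6, data.frame(channel = 1L, site_id = 1:3,
                                        position_bp = c(1e5, 2e5, 3e5)))
  map_k <- label_map(5L, 10000, data.frame(channel = 1L, site_id = 1:2,
                                           position_bp = c(4000, 8000)))
  map_n <- label_map(6L, 9000, data.frame(channel = 1L, site_id = 1:2,
                                          position_bp = c(1500, 7000)))
  ak <- mk_align(1, 5, 1e5, 2e5, 4000, 8000, pairs = cbind(1:2, 1:2))
  an <- mk_align(2, 6, 2e5, 3e5, 1500, 7000, pairs = cbind(2:3, 1:2))
  sh <- shared_labels(ak, an, amap)
  dec <- merge_at_shared_label(ak, an, sh, map_k, map_n, 10000, 9000)
  expect_equal(dec$kind, "fuse_at_label")
  expect_equal(dec$cut_k, 8000)
  expect_equal(dec$cut_n, 1500)
  # fused length under keep-through / keep-after semantics
  expect_equal(dec$cut_k + (9000 - dec$cut_n), 15500)

  # reverse-oriented right contig: cut mirrored into anchor orientation
  an_rev <- mk_align(3, 6, 2e5, 3e5, 1500, 7000, ori = "reverse",
                     pairs = cbind(c(3L, 2L), 1:2))
  # for the reverse contig the anchor-last shared label (id 2) pairs with
  # query site 2 at native 7000 -> oriented 9000 - 7000 + 1 = 2001
  dec_r <- merge_at_shared_label(ak, an_rev, sh, map_k, map_n, 10000, 9000)
  expect_equal(dec_r$cut_n, 2001)

  # a label id absent from the contig map is a data-inconsistency error
  bad_map_n <- label_map(6L, 9000, data.frame(channel = 1L, site_id = 9L,
                                              position_bp = 100))
  expect_error(merge_at_shared_label(ak, an, sh, map_k, bad_map_n,
                                     10000, 9000), "site")
})

test_that("gap estimation follows the anchor-minus-tails identity", {
  # Sa_n = 1,012,000, Ea_k = 1,000,000, Size_k = 100,000, Em_k = 95,000,
  # Sm_n = 2,000  ->  n = 12,000, d_k = 5,000, d_n = 2,000, g = 5,000
  ak <- mk_align(1, 5, 900000, 1000000, 5000, 95000)
  an <- mk_align(2, 6, 1012000, 1100000, 2000, 60000)
  expect_equal(estimate_gap_size(ak, an, 100000), 5000)

  ak2 <- mk_align(3, 5, 1000, 2000, 100, 1500)  # d_k = 3000 - 1500 = 1500
  an2 <- mk_align(4, 6, 5000, 6000, 1400, 2000) # n = 3000, d_n = 1400
  expect_equal(estimate_gap_size(ak2, an2, 3000), 100)

  ak3 <- mk_align(5, 5, 1000, 2000, 100, 1000)  # d_k = 3000 - 1000 = 2000
  an3 <- mk_align(6, 6, 3000, 6000, 500, 2000)  # n = 1000, d_n = 500
  expect_equal(estimate_gap_size(ak3, an3, 3000), -1500)

  # reverse right contig requires its size for mirroring
  an_rev <- mk_align(7, 6, 1012000, 1100000, 2000, 60000, ori = "reverse")
  expect_error(estimate_gap_size(ak, an_rev, 100000), "size_n")
  # mirrored Sm = 61000 - 60000 + 1 = 1001
  expect_equal(estimate_gap_size(ak, an_rev, 100000, 61000),
               12000 - 5000 - 1001)
})

test_that("unlabelled junctions fuse on strong alignment or emit sized/sentinel gaps", {
  set.seed(9)
  # above-threshold estimate: sized gap of the estimate, no alignment run
  dec <- resolve_unlabelled_junction(rnd_dna(1000), rnd_dna(1000), 5000)
  expect_equal(dec$kind, "sized_gap")
  expect_equal(dec$emitted_gap, 5000)

  # planted exact 6 kb terminal/initial overlap: fused without duplication
  left_u <- rnd_dna(14000); ov <- rnd_dna(6000); right_u <- rnd_dna(14000)
  seq_k <- paste0(left_u, ov); seq_n <- paste0(ov, right_u)
  dec <- resolve_unlabelled_junction(seq_k, seq_n, g = 100)
  expect_equal(dec$kind, "fuse_by_alignment")
  expect_equal(dec$score, 6000)
  fused <- paste0(substr(seq_k, 1, dec$cut_k),
                  substr(seq_n, dec$keep_n_from, nchar(seq_n)))
  expect_equal(fused, paste0(left_u, ov, right_u))
  expect_equal(nchar(fused), nchar(seq_k) + nchar(seq_n) - 6000)

  # negative estimate but unrelated sequence: clamped 13-N sentinel
  dec <- resolve_unlabelled_junction(rnd_dna(30000), rnd_dna(30000), -200)
  expect_equal(dec$kind, "sized_gap")
  expect_equal(dec$emitted_gap, 13)

  # failing aligner backend falls back to a gap with a warning
  boom <- function(a, b, p) stop("backend down")
  expect_warning(
    dec <- resolve_unlabelled_junction(rnd_dna(100), rnd_dna(100), 0,
                                       aligner = boom),
    "gap")
  expect_equal(dec$kind, "sized_gap")
  expect_equal(dec$emitted_gap, 13)
})

test_that("containment resolution follows the label-count rule with conservative ties", {
  amap <- label_map(1L, 1e6, data.frame(channel = 1L, site_id = 1:20,
                                        position_bp = (1:20) * 1000))
  # host aligned over sites 1..20, contained over 5..10
  host_map <- label_map(5L, 300000,
                        data.frame(channel = 1L, site_id = 1:6,
                                   position_bp = c(1, 5, 6, 9, 10, 20) * 10000))
  cont_map <- label_map(6L, 60000,
                        data.frame(channel = 1L, site_id = 1:6,
                                   position_bp = c(1, 2, 3, 4, 5, 6) * 9000))
  # host pairs: anchor sites 1, 5, 6, 9, 10, 20 (4 of them inside [5,10])
  ak <- mk_align(1, 5, 1000, 20000, 10000, 200000,
                 pairs = cbind(c(1L, 5L, 6L, 9L, 10L, 20L), 1:6))
  # contained pairs: anchor sites 5..10 (6 inside) -> insert wins
  an <- mk_align(2, 6, 5000, 10000, 9000, 54000,
                 pairs = cbind(5:10, 1:6))
  dec <- resolve_containment(ak, an, amap, host_map, cont_map, 300000, 60000)
  expect_equal(dec$kind, "containment_insert")
  expect_equal(dec$labels_contained, 6)
  expect_equal(dec$labels_host, 4)
  # host cut at its positions for anchor sites 5 and 10
  expect_equal(dec$host_left_end, 50000)
  expect_equal(dec$host_right_start, 100001)
  expect_equal(dec$ins_from, 9001)
  expect_equal(dec$ins_to, 54000)

  # tie keeps the host
  an_tie <- mk_align(3, 6, 5000, 10000, 9000, 36000,
                     pairs = cbind(c(5L, 6L, 9L, 10L), 1:4))
  dec_tie <- resolve_containment(ak, an_tie, amap, host_map, cont_map,
                                 300000, 60000)
  expect_equal(dec_tie$kind, "containment_singleton")

  # no shared labels at all: singleton
  an_none <- mk_align(4, 6, 5000, 10000, 9000, 36000,
                      pairs = cbind(c(7L, 8L), 1:2))
  expect_equal(resolve_containment(ak, an_none, amap, host_map, cont_map,
                                   300000, 60000)$kind,
               "containment_singleton")
})

test_that("a bundle with no alignments yields only singletons", {
  assembly <- c(a = rnd_dna(500, 20), b = rnd_dna(300, 21))
  key <- data.frame(component_id = 1:2, component_name = c("a", "b"),
                    component_length = c(500, 300))
  res <- build_scaffolds(assembly, key, list(), list(), list())
  expect_length(res$plans, 0L)
  expect_equal(res$singletons, c("a", "b"))
  out <- render_scaffolds(res)
  expect_equal(out$fasta[["a"]], assembly[["a"]])
})

test_that("aligned map ids missing from the key are a hard error", {
  assembly <- c(a = rnd_dna(500, 22))
  key <- data.frame(component_id = 1L, component_name = "a",
                    component_length = 500)
  al <- mk_align(1, 99, 100, 200, 1, 100)
  amap <- list(`1` = label_map(1L, 1e6,
                               data.frame(channel = 1L, site_id = 1L,
                                          position_bp = 100)))
  expect_error(
    build_scaffolds(assembly, key, list(`1` = list()), list(`1` = amap),
                    list(al)),
    "99")
})

test_that("fixture junctions resolve to their planted kinds", {
  ex <- exact_fixture()
  tr <- ex$fx$truth$junctions
  rep <- ex$res$report
  for (i in seq_len(nrow(tr))) {
    row <- report_row(rep, tr$left[i], tr$right[i])
    expect_equal(nrow(row), 1L)
    expected_kind <- if (tr$type[i] == "gap") "sized_gap"
      else if (tr$class[i] == "labelled") "fuse_at_label"
      else "fuse_by_alignment"
    expect_equal(row$kind, expected_kind,
                 label = paste("junction", tr$left[i], tr$right[i]))
  }
  # every contained contig resolved as planted
  for (i in seq_len(nrow(ex$fx$truth$contained))) {
    cc <- ex$fx$truth$contained[i, ]
    row <- report_row(rep, cc$host, cc$name)
    expect_equal(row$kind,
                 if (cc$rich) "containment_insert" else "containment_singleton")
  }
})
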