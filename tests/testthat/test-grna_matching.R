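rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                        collapse = "")

test_that("duplex alignment scores WC, G:U and mismatches antiparallel", {
  mrna <- "ACGTACGTACGT"
  perfect <- rc(mrna)
  d <- duplex_align(mrna, perfect)
  expect_equal(d$n_wc, 12L)
  expect_equal(d$n_gu, 0L)
  expect_equal(d$n_mismatch, 0L)
  expect_equal(d$score, 24)

  # one mRNA G opposite a guide U: wobble, not mismatch
  g2 <- perfect
  substr(g2, 6, 6) <- "T"   # guide position pairing mRNA position 7 (G)
  d2 <- duplex_align(mrna, g2)
  expect_equal(d2$n_wc, 11L)
  expect_equal(d2$n_gu, 1L)
  expect_equal(d2$score, 23)

  # two candidate placements: the higher-scoring offset wins, and the
  # result equals exhaustive enumeration
  mrna2 <- paste0("AAATTTGGGCCC", "ACGTACGTACGT", "TTT")
  guide <- rc("ACGTACGTACGT")
  best <- duplex_align(mrna2, guide)
  scores <- vapply(seq_len(nchar(mrna2) - nchar(guide) + 1), function(s)
    duplex_align(mrna2, guide, offsets = s)$score, numeric(1))
  expect_equal(best$offset, 13L)
  expect_equal(best$score, max(scores))

  # strand-swap symmetry of the duplex score
  set.seed(47)
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    expect_equal(duplex_align(a, b)$score, duplex_align(b, a)$score)
  }
  expect_error(duplex_align("ACGTACGT", "ACGT", offsets = integer(0)),
               "empty offset")
})

test_that("anchor discovery respects length, wobble and mismatch limits", {
  tab <- toy2_table()
  g <- make_guide(tab, ess = 1, block_u = tab$full_U[2:3], anchor_len = 8)
  full <- render_sequence(tab, tab$full_U, "full")
  anchors <- find_anchor(full, g$sequence, min_len = 6)
  expect_gt(nrow(anchors), 0L)
  # the guide pairs its template region perfectly, so the top anchor has
  # no mismatches and covers at least the designed 8 nt
  expect_equal(anchors$n_mismatch[1], 0L)
  expect_gte(anchors$length[1], 8L)

  # an anchor with one G:U and one mismatch is admitted only when both
  # are tolerated
  mrna <- "CCAACGTACGTACC"
  anchor_region <- substr(mrna, 5, 12)  # CGTACGTA
  guide <- rc(anchor_region)            # TACGTACG
  substr(guide, 2, 2) <- "G"            # wobble against mRNA position 11 (U)
  substr(guide, 4, 4) <- "T"            # mismatch against mRNA position 9 (C)
  hit <- find_anchor(mrna, guide, min_len = 6, allow_gu = TRUE,
                     max_mismatch = 1)
  expect_gt(nrow(hit), 0L)
  expect_equal(hit$n_mismatch[1], 1L)
  expect_gte(hit$n_gu[1], 1L)
  strict <- find_anchor(mrna, guide, min_len = 8, allow_gu = TRUE,
                        max_mismatch = 0)
  expect_equal(nrow(strict), 0L)
})

test_that("templating walks purine runs into U counts", {
  # two skeleton bases with k unconsumed As between pairings template k Us
  for (k in c(0, 1, 5)) {
    window <- "CA"                     # 3'->5': A then C
    guide <- paste0(c("GGGG", "T", strrep("A", k), "G"), collapse = "")
    pred <- predict_templated_block(guide, window, anchor_len = 4)
    expect_equal(pred$u_counts, c(0L, k))
    expect_equal(pred$status, "ok")
  }
  # an unpairable guide pyrimidine stops the walk
  bad <- predict_templated_block("GGGGTC", "AA", anchor_len = 4)
  expect_equal(bad$status, "failure")
  expect_equal(bad$fail_at, 2L)
})

test_that("encoded uridines may be deleted only when deletions are allowed", {
  # window 3' end: A, then two encoded Us, then C (5'->3' "CTTA")
  window <- "CTTA"
  guide <- "GGGGTG"   # pairs A then C with no purines between: deletes both Us
  pred <- predict_templated_block(guide, window, anchor_len = 4)
  expect_equal(pred$u_counts, c(0L, 0L))
  expect_equal(pred$encoded, c(0L, 2L))
  expect_equal(pred$status, "ok")
  strict <- predict_templated_block(guide, window, anchor_len = 4,
                                    allow_deletion = FALSE)
  expect_equal(strict$status, "failure")
})

test_that("a single-U bulge merges a 5-U and 4-U run into 9 Us", {
  tab <- toy2_table()
  expect_equal(tab$full_U, c(0L, 5L, 4L, 0L))
  g <- make_guide(tab, ess = 1, block_u = tab$full_U[2:3], anchor_len = 8)
  pre_full <- render_sequence(tab, tab$pre_U, "full")
  pos <- uindel:::skeleton_positions(tab, tab$pre_U)
  j_a <- tab$n_sites + 1L - 1L          # element 3' of site 2
  window <- substr(pre_full, pos[1], pos[j_a] - 1)

  canon <- predict_templated_block(g$sequence, window, anchor_len = 8)
  expect_equal(canon$u_counts, c(5L, 4L))

  bulged <- predict_templated_block(g$sequence, window, anchor_len = 8,
                                    bulge = TRUE)
  expect_equal(bulged$u_counts, 9L)
  expect_equal(bulged$status, "truncated")
  expect_true(bulged$bulged)
})

test_that("templated blocks re-pair against their guide without mismatch", {
  tab <- build_site_table(demo_template())
  set.seed(53)
  for (i in 1:10) {
    ess <- sample(3:30, 1)
    L <- sample(2:4, 1)
    block <- vapply(ess + seq_len(L), function(s) {
      v <- sample(0:8, 1)
      while (v == tab$full_U[s] && s == ess + 1) v <- sample(0:8, 1)
      v
    }, numeric(1))
    g <- make_guide(tab, ess = ess, block_u = block, anchor_len = 10)
    # predicted counts must reproduce the designed block ...
    pre_full <- render_sequence(tab, tab$pre_U, "full")
    pos <- uindel:::skeleton_positions(tab, tab$pre_U)
    j_a <- tab$n_sites + 1L - ess
    window <- substr(pre_full, pos[1], pos[j_a] - 1)
    pred <- predict_templated_block(g$sequence, window, anchor_len = 10)
    expect_gte(length(pred$u_counts), L)
    expect_equal(pred$u_counts[seq_len(L)], as.integer(block))
    # ... and the rendered block forms a mismatch-free duplex with the
    # guiding region of the guide
    u <- tab$pre_U
    u[seq_len(ess)] <- tab$full_U[seq_len(ess)]
    u[ess + seq_len(L)] <- as.integer(block)
    full <- render_sequence(tab, u, "full")
    posu <- uindel:::skeleton_positions(tab, u)
    span <- substr(full, posu[j_a - L], posu[j_a] + 10 - 1)
    d <- duplex_align(span, g$sequence)
    expect_equal(d$n_mismatch, 0L)
  }
})

test_that("guide search recovers the planted guide ahead of decoys", {
  tab <- build_site_table(demo_template())
  block <- c(9L, 2L, 1L)
  u <- tab$pre_U
  u[1:7] <- tab$full_U[1:7]
  u[8:10] <- block
  alt <- make_guide(tab, ess = 7, block_u = block, anchor_len = 12)
  set.seed(59)
  decoys <- vapply(1:15, function(i)
    paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = ""), "")
  guides <- c(alt_guide = alt$sequence,
              stats::setNames(decoys, paste0("decoy", 1:15)))
  res <- search_grna_db(u, tab, guides)
  expect_equal(res$guide[1], "alt_guide")
  expect_equal(res$n_explained[1], 3L)
  expect_equal(res$explained_labels[1],
               paste(site_label(tab, 8:10), collapse = ","))
  # no decoy explains more junction sites than chance placements allow
  decoy_best <- res$n_explained[res$guide != "alt_guide"]
  if (length(decoy_best)) expect_lt(max(decoy_best), 3L)

  # a guide "annotated" to another transcript is still reported
  guides2 <- c(other_transcript_guide = alt$sequence)
  res2 <- search_grna_db(u, tab, guides2)
  expect_equal(res2$guide[1], "other_transcript_guide")
})
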