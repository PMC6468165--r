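# Guide RNA matching: antiparallel mRNA:gRNA duplexes with Watson-Crick
# and G:U wobble pairing, anchor discovery, prediction of the uridine
# block a guide would template (with a single-base bulge/misalignment
# mode), and search of a guide set against an observed junction.
#
# All sequences are held internally as DNA (U -> T); gRNAs are given
# 5'->3'. In a duplex the gRNA 5' region (the anchor) pairs the mRNA
# region 3' of the block it edits, and editing walks the mRNA 3'->5',
# i.e. toward the gRNA 3' end.

# pair class of mRNA base m against gRNA base g (both DNA letters)
pair_class <- function(m, g) {
  wc <- (m == "A" & g == "T") | (m == "T" & g == "A") |
        (m == "G" & g == "C") | (m == "C" & g == "G")
  gu <- (m == "G" & g == "T") | (m == "T" & g == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "mismatch"))
}

#' Read a guide RNA set from FASTA
#'
#' @param path FASTA file of gRNA sequences (RNA or DNA alphabet; `U` is
#'   converted to `T`), 5'->3'.
#' @return Named character vector of guide sequences.
#' @export
read_guides <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- clean_seq(as.character(x))
  names(out) <- names(x)
  out
}

#' Best ungapped antiparallel duplex between an mRNA segment and a guide
#'
#' Slides the guide along the mRNA segment (antiparallel: the guide's 5'
#' end pairs the 3'-most base of the mRNA window) over the given start
#' offsets, scores each full-overlap placement (+2 per Watson-Crick pair,
#' +1 per G:U, -2 per mismatch by default) and returns the best; ties go
#' to the 3'-most mRNA placement. Scores are symmetric in the two strands
#' (swapping the mRNA and guide roles leaves the score unchanged).
#'
#' @param mrna,grna Sequences (5'->3'; U/T synonyms).
#' @param offsets Candidate start positions of the mRNA window; default
#'   all full-overlap placements. Must be non-empty.
#' @param score Named vector with `wc`, `gu`, `mismatch` weights.
#' @return List: `offset` (window start), `mrna_window` = c(start, end),
#'   `pair_classes` (per mRNA position, 5'->3'), `n_wc`, `n_gu`,
#'   `n_mismatch`, `score`, `anchor_span` (mRNA coordinates of the
#'   3'-most contiguous run of paired bases).
#' @export
duplex_align <- function(mrna, grna, offsets = NULL,
                         score = c(wc = 2, gu = 1, mismatch = -2)) {
  mrna <- clean_seq(mrna); grna <- clean_seq(grna)
  mch <- strsplit(mrna, "", fixed = TRUE)[[1]]
  gch <- rev(strsplit(grna, "", fixed = TRUE)[[1]])  # gRNA read 3'->5'
  L <- length(mch); G <- length(gch)
  if (L < G) stop("mRNA segment shorter than guide", call. = FALSE)
  if (is.null(offsets)) offsets <- seq_len(L - G + 1L)
  offsets <- as.integer(offsets)
  if (!length(offsets)) stop("empty offset range", call. = FALSE)
  if (any(offsets < 1L | offsets > L - G + 1L))
    stop("offset outside full-overlap range", call. = FALSE)
  best <- NULL
  for (s in sort(offsets)) {
    pc <- pair_class(mch[s:(s + G - 1L)], gch)
    sc <- sum(score[c(WC = "wc", GU = "gu", mismatch = "mismatch")[pc]])
    if (is.null(best) || sc >= best$score) {   # >= : ties to 3'-most (largest s)
      paired <- pc != "mismatch"
      runs <- rle(paired)
      if (any(runs$values)) {
        ends <- cumsum(runs$lengths)
        k <- max(which(runs$values))
        anchor_span <- c(ends[k] - runs$lengths[k] + 1L, ends[k]) + s - 1L
      } else anchor_span <- c(NA_integer_, NA_integer_)
      best <- list(offset = s, mrna_window = c(s, s + G - 1L),
                   pair_classes = pc,
                   n_wc = sum(pc == "WC"), n_gu = sum(pc == "GU"),
                   n_mismatch = sum(pc == "mismatch"),
                   score = sc, anchor_span = anchor_span)
    }
  }
  best
}

#' Find candidate anchor duplexes of a guide on an mRNA
#'
#' Enumerates contiguous antiparallel duplexes between the guide's 5'
#' region (a prefix of the guide) and the mRNA, of length at least
#' `min_len`, with at most `max_mismatch` internal mismatches (G:U wobble
#' pairs count as pairing when `allow_gu`). For each mRNA 3' end position
#' the longest admissible duplex ending on a paired base is kept;
#' placements are ranked by mismatches (ascending) then length
#' (descending).
#'
#' @param mrna,grna Sequences (5'->3').
#' @param min_len Minimum anchor length (nt).
#' @param allow_gu Count G:U as pairing.
#' @param max_mismatch Maximum mismatches tolerated inside the anchor.
#' @return A data.frame (possibly empty): `start`, `end` (mRNA window,
#'   `start` = 5'-most), `length`, `n_wc`, `n_gu`, `n_mismatch`, `score`.
#' @export
find_anchor <- function(mrna, grna, min_len = 6L, allow_gu = TRUE,
                        max_mismatch = 1L) {
  mrna <- clean_seq(mrna); grna <- clean_seq(grna)
  mch <- strsplit(mrna, "", fixed = TRUE)[[1]]
  gch <- strsplit(grna, "", fixed = TRUE)[[1]]
  L <- length(mch); G <- length(gch)
  rows <- list()
  for (b in seq_len(L)) {
    lmax <- min(b, G)
    if (lmax < min_len) next
    ks <- seq_len(lmax)
    pc <- pair_class(mch[b - ks + 1L], gch[ks])
    ispair <- pc == "WC" | (allow_gu & pc == "GU")
    mm <- cumsum(!ispair)
    ok <- which(ispair & mm <= max_mismatch)
    if (!length(ok)) next
    l <- max(ok)
    if (l < min_len) next
    seg <- pc[seq_len(l)]
    n_wc <- sum(seg == "WC")
    n_gu <- if (allow_gu) sum(seg == "GU") else 0L
    n_mm <- l - n_wc - n_gu
    rows[[length(rows) + 1L]] <- data.frame(
      start = b - l + 1L, end = b, length = l,
      n_wc = n_wc, n_gu = n_gu, n_mismatch = n_mm,
      score = 2L * n_wc + n_gu - 2L * n_mm)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_wc = integer(0),
                      n_gu = integer(0), n_mismatch = integer(0),
                      score = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_mismatch, -out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the uridine block a guide would template
#'
#' Walks the mRNA 3'->5' from the anchor, consuming one guide base (after
#' the `anchor_len` bases used by the anchor) per skeleton base of the
#' encoded mRNA window. Guide bases that pair the pending skeleton base
#' (WC, or G:U when `allow_gu`; a guide `G` is consumed by a skeleton `C`,
#' otherwise it joins the purine run) close the current editing site;
#' maximal runs of unconsumed purines (`A`/`G`) between pairings template
#' that many uridines at the intervening site. Encoded uridines in the
#' window need not be re-templated: a site templated below its encoded
#' count is a U deletion (an error unless `allow_deletion`). A guide
#' pyrimidine that can neither pair nor template stops the walk as a
#' templating failure. With `bulge = TRUE` the first guide `U` that would
#' pair its skeleton base is instead bulged out of register, merging its
#' flanking purine runs (the misalignment mechanism); the merged run is
#' reported at the current site and the walk is truncated there.
#'
#' @param grna Guide sequence, 5'->3'.
#' @param window Encoded (pre-edited) mRNA sequence 5' of the anchor,
#'   5'->3'; its 3' end abuts the anchor, so trailing `T`s are the encoded
#'   uridines of the first templated site.
#' @param anchor_len Number of guide 5' bases consumed by the anchor.
#' @param allow_gu Allow G:U pairs in the walk.
#' @param allow_deletion Permit templated counts below the encoded count.
#' @param bulge Single-base bulge (misalignment) mode.
#' @return List: `u_counts` (templated U count per site, 3'->5'; element 1
#'   is the site between the window and the anchor), `encoded` (encoded U
#'   counts over the same sites), `status` (`"ok"`, `"guide_exhausted"`,
#'   `"truncated"` for a bulge stop, or `"failure"`), `fail_at` (skeleton
#'   position, 3'->5', that could not pair; NA otherwise), `n_paired`
#'   (skeleton bases paired), `bulged` (logical).
#' @export
predict_templated_block <- function(grna, window, anchor_len,
                                    allow_gu = TRUE, allow_deletion = TRUE,
                                    bulge = FALSE) {
  grna <- clean_seq(grna); window <- clean_seq(window)
  gch_all <- strsplit(grna, "", fixed = TRUE)[[1]]
  if (anchor_len < 0L || anchor_len >= length(gch_all))
    stop("anchor_len must leave at least one guiding base", call. = FALSE)
  g <- gch_all[(anchor_len + 1L):length(gch_all)]
  wch <- rev(strsplit(window, "", fixed = TRUE)[[1]])  # 3'->5'
  sk_idx <- which(wch != "T")
  n_sk <- length(sk_idx)
  # encoded U runs 3' of each skeleton base (element 1 = trailing run)
  enc <- diff(c(0L, sk_idx)) - 1L
  pairs_base <- function(gc, b) {
    switch(gc,
           T = b == "A" || (allow_gu && b == "G"),
           C = b == "G",
           G = b == "C",
           A = FALSE,
           FALSE)
  }
  u <- integer(0); paired <- logical(0)
  status <- "ok"; fail_at <- NA_integer_; bulged <- FALSE
  j <- 1L; k <- 1L
  while (k <= n_sk) {
    run <- 0L
    closed <- FALSE
    while (j <= length(g)) {
      gc <- g[j]
      if (pairs_base(gc, wch[sk_idx[k]])) {
        if (bulge && !bulged && gc == "T") {
          bulged <- TRUE; j <- j + 1L; next   # bulge the pairing U out
        }
        j <- j + 1L; closed <- TRUE; break
      }
      if (gc %in% c("A", "G")) { run <- run + 1L; j <- j + 1L; next }
      if (bulge && !bulged && gc == "T") { bulged <- TRUE; j <- j + 1L; next }
      status <- "failure"; fail_at <- k
      break
    }
    if (closed) {
      u <- c(u, run); paired <- c(paired, TRUE)
      k <- k + 1L
      if (bulged && status == "ok") { status <- "truncated"; break }
      next
    }
    # walk ended without pairing skeleton base k
    if (status != "failure" && j > length(g)) status <- "guide_exhausted"
    if (status == "failure" && bulged) {     # bulge shifted the register;
      status <- "truncated"; fail_at <- NA_integer_   # editing stops here
    }
    if (run > 0L) { u <- c(u, run); paired <- c(paired, FALSE) }
    break
  }
  n <- length(u)
  res_enc <- if (n) enc[seq_len(n)] else integer(0)
  if (!allow_deletion && any(u < res_enc & paired))
    status <- "failure"
  list(u_counts = u, encoded = res_enc, status = status, fail_at = fail_at,
       n_paired = sum(paired), bulged = bulged)
}

# Rendered positions of the skeleton elements (1..m+1, 5'->3') of an
# extended domain carrying the given U counts, within the full molecule
# (flank5 + domain + flank3).
skeleton_positions <- function(table, u_counts) {
  u53 <- rev(as.integer(u_counts))
  # element j sits after elements 1..j-1 and the gaps between them
  ext_pos <- cumsum(c(1L, u53 + 1L))
  nchar(table$config$flank5) - 1L + ext_pos
}

#' Construct the guide that would template a given junction block
#'
#' Builds, by reverse complement, the guide RNA whose anchor pairs the
#' canonically edited mRNA 3' of a junction and whose guiding region
#' templates exactly the given U counts at the sites 5' of the stop site.
#' Useful for constructing cognate-style and alternative guides with known
#' ground truth.
#'
#' @param table An `es_table`.
#' @param ess Stop site: sites `1..ess` carry fully edited counts; the
#'   block starts at site `ess + 1`.
#' @param block_u U counts templated at sites `ess+1, ess+2, ...` (3'->5').
#' @param anchor_len Anchor length in nt over the canonical mRNA 3' of the
#'   block.
#' @return List: `sequence` (guide, 5'->3', DNA letters), `anchor_len`,
#'   `first_site` (= ess + 1), `n_sites`.
#' @export
make_guide <- function(table, ess, block_u, anchor_len = 12L) {
  m <- table$n_sites
  L <- length(block_u)
  stopifnot(ess >= 0L, ess + L <= m, L >= 1L)
  u <- table$pre_U
  if (ess > 0L) u[seq_len(ess)] <- table$full_U[seq_len(ess)]
  u[ess + seq_len(L)] <- as.integer(block_u)
  full <- render_sequence(table, u, "full")
  pos <- skeleton_positions(table, u)
  a <- pos[m + 1L - ess]          # element 3' of the block's first site
  p5 <- pos[m + 1L - ess - L]     # element bounding the block's 5' end
  if (a + anchor_len - 1L > nchar(full))
    stop("anchor_len runs past the 3' end of the molecule", call. = FALSE)
  segment <- substr(full, p5, a + anchor_len - 1L)
  list(sequence = revcomp(segment), anchor_len = anchor_len,
       first_site = ess + 1L, n_sites = L)
}

#' Search a guide set for candidates directing an observed junction
#'
#' For each guide, anchors on the observed (rendered) molecule are found
#' with [find_anchor()]; anchors whose 5' end coincides with a skeleton
#' base 3' of the junction are extended by [predict_templated_block()]
#' over the encoded sequence 5' of the anchor, and the predicted per-site
#' U counts are compared with the observed junction. Candidates are
#' ranked by the number of junction sites exactly explained, then by
#' anchor duplex score. Guides annotated to other transcripts are treated
#' no differently (promiscuous usage is permitted).
#'
#' @param u_counts Observed U-count vector (3'->5', length `n_sites`).
#' @param table An `es_table`.
#' @param guides Named character vector of guide sequences (5'->3'), e.g.
#'   from [read_guides()].
#' @param ess Stop site of the junction; defaults to the ESS landmark of
#'   `u_counts`.
#' @param min_anchor,allow_gu,max_mismatch Anchor admission parameters
#'   (see [find_anchor()]).
#' @param score_floor Drop candidates with anchor duplex score below this.
#' @return A data.frame ranked best-first: `guide`, `anchor_start`,
#'   `anchor_len`, `n_wc`, `n_gu`, `n_mismatch`, `anchor_score`,
#'   `first_site`, `n_explained`, `explained_labels` (comma-joined
#'   published labels), `predicted` (comma-joined templated counts,
#'   3'->5' from `first_site`), `status`.
#' @export
search_grna_db <- function(u_counts, table, guides, ess = NULL,
                           min_anchor = 6L, allow_gu = TRUE,
                           max_mismatch = 1L, score_floor = 0L) {
  stopifnot(length(guides) >= 1L)
  if (is.null(names(guides)))
    names(guides) <- paste0("gRNA_", seq_along(guides))
  m <- table$n_sites
  lm <- classify_and_landmark(u_counts, table)
  if (is.null(ess)) ess <- lm$ESS
  junction_sites <- if (lm$JES > ess) seq(ess + 1L, lm$JES) else integer(0)
  obs_full <- render_sequence(table, u_counts, "full")
  pos <- skeleton_positions(table, u_counts)
  pre_full <- render_sequence(table, table$pre_U, "full")
  pre_pos <- skeleton_positions(table, table$pre_U)

  obs_ch <- strsplit(obs_full, "", fixed = TRUE)[[1]]
  rows <- list()
  for (id in names(guides)) {
    gseq <- clean_seq(guides[[id]])
    gch <- strsplit(gseq, "", fixed = TRUE)[[1]]
    G <- length(gch)
    # enumerate anchor placements (j_a = skeleton element at the anchor's
    # 5' end, l = anchor length in guide 5' bases); a cognate guide also
    # pairs the junction it explains, so anchors are not simply maximal
    # duplex extensions
    for (b in seq_along(obs_ch)) {
      lmax <- min(b, G - 1L)             # keep >= 1 guiding base
      if (lmax < min_anchor) next
      ks <- seq_len(lmax)
      pc <- pair_class(obs_ch[b - ks + 1L], gch[ks])
      ispair <- pc == "WC" | (allow_gu & pc == "GU")
      mm <- cumsum(!ispair)
      for (l in seq(min_anchor, lmax)) {
        if (!ispair[l] || mm[l] > max_mismatch) next
        a <- b - l + 1L
        j_a <- match(a, pos)             # anchor begins on a skeleton base
        if (is.na(j_a) || j_a < 2L) next
        i0 <- m + 2L - j_a               # first templated site (3'->5')
        if (i0 > ess + 1L) next          # anchor must lie 3' of the junction
        seg <- pc[seq_len(l)]
        n_wc <- sum(seg == "WC"); n_gu <- sum(seg == "GU")
        n_mm <- l - n_wc - n_gu
        a_score <- 2L * n_wc + n_gu - 2L * n_mm
        if (a_score < score_floor) next
        window <- substr(pre_full, pre_pos[1L], pre_pos[j_a] - 1L)
        pred <- predict_templated_block(gseq, window, anchor_len = l,
                                        allow_gu = allow_gu)
        np <- length(pred$u_counts)
        if (!np) next
        covered <- i0 + seq_len(np) - 1L
        keep <- covered <= m
        covered <- covered[keep]
        pred_u <- pred$u_counts[keep]
        expl <- covered[covered %in% junction_sites &
                          pred_u == u_counts[covered]]
        rows[[length(rows) + 1L]] <- data.frame(
          guide = id, anchor_start = a, anchor_len = l,
          n_wc = n_wc, n_gu = n_gu, n_mismatch = n_mm,
          anchor_score = a_score,
          first_site = site_label(table, i0),
          n_explained = length(expl),
          explained_labels = paste(site_label(table, expl), collapse = ","),
          predicted = paste(pred_u, collapse = ","),
          status = pred$status, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(guide = character(0), anchor_start = integer(0),
                      anchor_len = integer(0), n_wc = integer(0),
                      n_gu = integer(0), n_mismatch = integer(0),
                      anchor_score = integer(0), first_site = integer(0),
                      n_explained = integer(0),
                      explained_labels = character(0),
                      predicted = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_explained, -out$anchor_score, out$guide), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
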