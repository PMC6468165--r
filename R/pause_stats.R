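# Pause-site statistics: Tukey-outlier intrinsic pause sites (IPS) per
# replicate with replicate consensus, and differential (exacerbated) pause
# sites (EPS) between induced and uninduced sample groups.

#' Tukey outlier threshold for intrinsic pause sites
#'
#' `threshold = Q3 + 1.5 * IQR` over the multiset of stop-site histogram
#' values (every site of the domain, zeros included; pre-edited and fully
#' edited transcripts are already excluded from the histogram itself).
#' Quartiles use linear interpolation of order statistics (R's default
#' quantile type 7); sites count as pausing only when strictly above the
#' threshold.
#'
#' @param H Numeric stop-site histogram (see [stop_site_histogram()]).
#' @return The outlier threshold (a single number).
#' @export
ips_threshold <- function(H) {
  H <- as.numeric(H)
  if (!length(H) || any(is.na(H)))
    stop("empty or NA histogram", call. = FALSE)
  q <- stats::quantile(H, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Detect intrinsic pause sites across replicates
#'
#' Flags, in each replicate, the stop sites whose histogram value exceeds
#' that replicate's Tukey outlier threshold, and reports sites flagged in
#' at least `min_support` replicates. Calls supported by every replicate
#' are distinguished from those short by one (the filled vs outlined
#' convention of consensus displays). The degree of pausing is summarized
#' as the mean over replicates of `H[site] / threshold`.
#'
#' @param hists List of stop-site histograms (equal length, same site
#'   domain), one per replicate.
#' @param table Optional `es_table` used to attach published site labels.
#' @param min_support Minimum number of flagging replicates for a call.
#' @return A data.frame of calls (site, label, support, `in_all`,
#'   `fold_over_threshold`), ordered by site, with attributes `flags`
#'   (site x replicate logical matrix), `thresholds` (per replicate) and
#'   `H` (site x replicate values).
#' @export
detect_ips <- function(hists, table = NULL, min_support = 4L) {
  stopifnot(is.list(hists), length(hists) >= 2L)
  len <- vapply(hists, length, integer(1))
  if (length(unique(len)) != 1L)
    stop("replicate histograms cover different site domains", call. = FALSE)
  Hm <- do.call(cbind, lapply(hists, as.numeric))
  sites <- if (!is.null(names(hists[[1]]))) as.integer(names(hists[[1]]))
           else seq_len(nrow(Hm)) - 1L
  thresholds <- apply(Hm, 2L, ips_threshold)
  flags <- sweep(Hm, 2L, thresholds, ">")
  support <- rowSums(flags)
  fold <- rowMeans(sweep(Hm, 2L, thresholds, "/"))
  called <- which(support >= min_support)
  out <- data.frame(
    site = sites[called],
    label = if (!is.null(table)) site_label(table, sites[called])
            else sites[called],
    support = as.integer(support[called]),
    in_all = support[called] == ncol(Hm),
    fold_over_threshold = fold[called])
  out <- out[order(out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flags") <- flags
  attr(out, "thresholds") <- thresholds
  attr(out, "H") <- Hm
  out
}

# Two-sample Student's t (equal variance by default); handles the
# degenerate all-equal case: p = 1 when the group means are equal,
# otherwise the pooled variance is floored at machine epsilon.
two_group_t <- function(x, y, var_equal = TRUE) {
  vx <- stats::var(x); vy <- stats::var(y)
  if (isTRUE(all.equal(vx + vy, 0, tolerance = 0)) || (vx == 0 && vy == 0)) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t = 0, p = 1))
    n1 <- length(x); n2 <- length(y); df <- n1 + n2 - 2L
    se <- sqrt(.Machine$double.eps * (1 / n1 + 1 / n2))
    t <- d / se
    return(list(t = t, p = 2 * stats::pt(-abs(t), df)))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Detect exacerbated pause sites between induced and uninduced groups
#'
#' Per stop site, a two-sample Student's t-test compares (re)normalized
#' stop-site counts between induced (knockdown) and uninduced replicates;
#' p-values are Benjamini-Hochberg adjusted across all sites of the
#' transcript. A site is an EPS when `p < alpha`, `q < q_alpha`, the
#' induced mean exceeds the uninduced mean, and every induced replicate
#' individually exceeds the uninduced mean (direction consistency, the
#' default reading of "increased in both replicates"; `rule =
#' "per_replicate"` instead requires each induced replicate to be
#' individually significant against the uninduced group). Calls whose mean
#' count is below `low_abundance` in both groups are annotated, not
#' removed.
#'
#' @param induced,uninduced Lists of `sample_population` objects
#'   (at least 2 each).
#' @param alpha,q_alpha Significance thresholds on p and BH q.
#' @param drop_pre Renormalize each population to its scale after removing
#'   pre-edited sequences before testing (the default); fully edited
#'   sequences are retained in the pool (set `drop_full = TRUE` to remove
#'   them as well).
#' @param drop_full Also drop fully edited sequences before renormalizing.
#' @param var_equal Equal-variance Student's t (default); `FALSE` = Welch.
#' @param rule `"group_t"` (default) or `"per_replicate"` (see above).
#' @param low_abundance Annotation threshold on mean renormalized counts.
#' @return A data.frame with one row per site: `site`, `label`,
#'   `mean_uninduced`, `mean_induced`, `t`, `p`, `q`,
#'   `direction_consistent`, `is_eps`, `low_abundance`.
#' @export
detect_eps <- function(induced, uninduced, alpha = 0.05, q_alpha = 0.05,
                       drop_pre = TRUE, drop_full = FALSE,
                       var_equal = TRUE, rule = c("group_t", "per_replicate"),
                       low_abundance = 500) {
  rule <- match.arg(rule)
  if (length(induced) < 2L || length(uninduced) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  drop <- c(if (drop_pre) "pre_edited", if (drop_full) "fully_edited")
  prep <- function(p) if (length(drop)) renormalize_excluding(p, drop) else p
  Hi <- vapply(lapply(induced, prep), stop_site_histogram,
               numeric(induced[[1]]$table$n_sites + 1L))
  Hu <- vapply(lapply(uninduced, prep), stop_site_histogram,
               numeric(uninduced[[1]]$table$n_sites + 1L))
  table <- induced[[1]]$table
  m1 <- rowMeans(Hi); m0 <- rowMeans(Hu)
  tests <- lapply(seq_len(nrow(Hi)), function(s)
    two_group_t(Hi[s, ], Hu[s, ], var_equal = var_equal))
  p <- vapply(tests, `[[`, numeric(1), "p")
  tstat <- vapply(tests, `[[`, numeric(1), "t")
  q <- stats::p.adjust(p, method = "BH")
  direction <- vapply(seq_len(nrow(Hi)), function(s)
    all(Hi[s, ] > m0[s]), logical(1))
  sig <- if (rule == "group_t") {
    p < alpha & q < q_alpha
  } else {
    # each induced replicate individually significant vs the uninduced group
    per_rep <- vapply(seq_len(nrow(Hi)), function(s) {
      all(vapply(Hi[s, ], function(v) {
        tt <- two_group_t(rep(v, 2L), Hu[s, ], var_equal = var_equal)
        tt$p < alpha && v > m0[s]
      }, logical(1)))
    }, logical(1))
    per_rep & q < q_alpha
  }
  sites <- 0:(nrow(Hi) - 1L)
  out <- data.frame(
    site = sites, label = site_label(table, sites),
    mean_uninduced = m0, mean_induced = m1,
    t = tstat, p = p, q = q,
    direction_consistent = direction,
    is_eps = sig & m1 > m0 & direction,
    low_abundance = m1 < low_abundance & m0 < low_abundance)
  rownames(out) <- NULL
  out
}

#' Test class-level changes between induced and uninduced groups
#'
#' Student's t-test on the percentages of pre-edited, partially edited and
#' fully edited sequences between the two sample groups.
#'
#' @inheritParams detect_eps
#' @return A data.frame: `class`, `mean_uninduced`, `mean_induced`, `t`,
#'   `p` (two-sided).
#' @export
class_change_test <- function(induced, uninduced, var_equal = TRUE) {
  if (length(induced) < 2L || length(uninduced) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  Fi <- vapply(induced, class_fractions, numeric(3))
  Fu <- vapply(uninduced, class_fractions, numeric(3))
  res <- lapply(rownames(Fi), function(cl) {
    tt <- two_group_t(Fi[cl, ], Fu[cl, ], var_equal = var_equal)
    data.frame(class = cl, mean_uninduced = mean(Fu[cl, ]),
               mean_induced = mean(Fi[cl, ]), t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write IPS and EPS tables as TSV
#'
#' The IPS table carries per-replicate histogram values and thresholds in
#' addition to the consensus call columns, so threshold-adjacent calls can
#' be audited; the quartile convention (linear interpolation, quantile
#' type 7) is recorded in a header comment.
#'
#' @param ips Result of [detect_ips()] (or NULL to skip).
#' @param eps Result of [detect_eps()] (or NULL to skip).
#' @param dir Output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_pause_tsv <- function(ips = NULL, eps = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(ips)) {
    path <- file.path(dir, "ips.tsv")
    H <- attr(ips, "H"); thr <- attr(ips, "thresholds")
    extra <- NULL
    if (!is.null(H) && nrow(ips)) {
      idx <- ips$site + 1L
      extra <- as.data.frame(H[idx, , drop = FALSE])
      names(extra) <- paste0("H_rep", seq_len(ncol(H)))
    }
    con <- file(path, "w")
    writeLines("# quartile convention: linear interpolation (quantile type 7)", con)
    if (!is.null(thr))
      writeLines(paste0("# thresholds: ",
                        paste(format(thr), collapse = "\t")), con)
    df <- if (is.null(extra)) as.data.frame(ips) else cbind(as.data.frame(ips), extra)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <- c(paths, ips = path)
  }
  if (!is.null(eps)) {
    path <- file.path(dir, "eps.tsv")
    utils::write.table(eps, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, eps = path)
  }
  invisible(paths)
}
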