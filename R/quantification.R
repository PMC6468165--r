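# Population-level quantification: normalization to a common scale,
# class fractions, editing-stop-site histograms, renormalized
# sub-populations, and cross-sample QC.

#' Build a normalized sample population
#'
#' Rescales the standard alignments of one sample so that their counts sum
#' to `scale` (100 000 by default), enabling comparison of relative
#' abundance across samples. Normalized counts stay fractional; no
#' rounding is applied.
#'
#' @param processed Result of [process_reads()], or a data.frame with at
#'   least `count`, `u_key`, `eclass`, `ESS`, `JSS`, `JES`, `JL` columns.
#' @param table The `es_table` the sample was aligned against.
#' @param sample_id Sample identifier.
#' @param scale Normalization target (total normalized count).
#' @return An object of class `sample_population`: list with `sample_id`,
#'   `entries` (the aligned data.frame plus `norm_count`), `scale`, `qc`,
#'   and `table`.
#' @export
normalize_sample <- function(processed, table, sample_id = "sample",
                             scale = 1e5) {
  if (is.data.frame(processed)) {
    entries <- processed
    qc <- c(total = sum(entries$count), unique = nrow(entries),
            standard = sum(entries$count), non_standard = 0L, unanchored = 0L)
  } else {
    entries <- processed$aligned
    qc <- processed$qc
  }
  total <- sum(entries$count)
  if (!nrow(entries) || total <= 0)
    stop("empty sample: no standard alignments to normalize", call. = FALSE)
  entries$norm_count <- entries$count * scale / total
  structure(list(sample_id = sample_id, entries = entries,
                 scale = scale, qc = qc, table = table),
            class = "sample_population")
}

#' @export
print.sample_population <- function(x, ...) {
  cat("sample_population:", x$sample_id, "-", nrow(x$entries),
      "unique standard sequences, scale", format(x$scale), "\n")
  fr <- class_fractions(x)
  cat(sprintf("  pre %.1f%% / partial %.1f%% / full %.1f%%\n",
              fr[["pre"]], fr[["partial"]], fr[["full"]]))
  invisible(x)
}

#' Percentages of pre-, partially and fully edited sequences
#'
#' @param pop A `sample_population`.
#' @return Named numeric vector `c(pre=, partial=, full=)` summing to 100.
#' @export
class_fractions <- function(pop) {
  stopifnot(inherits(pop, "sample_population"))
  tot <- sum(pop$entries$norm_count)
  frac <- function(cl) 100 * sum(pop$entries$norm_count[pop$entries$eclass == cl]) / tot
  c(pre = frac("pre_edited"), partial = frac("partially_edited"),
    full = frac("fully_edited"))
}

#' Editing-stop-site histogram of a population
#'
#' Total normalized count of sequences sharing each editing stop site,
#' over the full site domain `0..n_sites` (zero-filled). By default
#' pre-edited and fully edited transcripts are excluded, so the histogram
#' describes where partially edited transcripts pause.
#'
#' @param pop A `sample_population`.
#' @param exclude Character vector of classes to exclude.
#' @return Named numeric vector of length `n_sites + 1` (names `"0"` ..
#'   `"n_sites"`, local 3'->5' indices).
#' @export
stop_site_histogram <- function(pop,
                                exclude = c("pre_edited", "fully_edited")) {
  stopifnot(inherits(pop, "sample_population"))
  m <- pop$table$n_sites
  H <- stats::setNames(numeric(m + 1L), as.character(0:m))
  e <- pop$entries[!(pop$entries$eclass %in% exclude), , drop = FALSE]
  if (nrow(e)) {
    agg <- tapply(e$norm_count, factor(e$ESS, levels = 0:m), sum,
                  default = 0)
    H[] <- as.numeric(agg)
  }
  H
}

#' Renormalize a population after dropping classes
#'
#' Removes the given classes (pre-edited sequences by default, i.e. keeps
#' only transcripts that have entered the editing pathway) and rescales the
#' remainder back to the population's scale. Pairwise abundance ratios of
#' retained sequences are preserved.
#'
#' @param pop A `sample_population`.
#' @param drop Classes to remove before rescaling.
#' @return A new `sample_population` on the same scale.
#' @export
renormalize_excluding <- function(pop, drop = "pre_edited") {
  stopifnot(inherits(pop, "sample_population"))
  keep <- !(pop$entries$eclass %in% drop)
  e <- pop$entries[keep, , drop = FALSE]
  tot <- sum(e$norm_count)
  if (!nrow(e) || tot <= 0)
    stop("empty sample: nothing retained after dropping ",
         paste(drop, collapse = ", "), call. = FALSE)
  e$norm_count <- e$norm_count * pop$scale / tot
  rownames(e) <- NULL
  out <- pop
  out$entries <- e
  out
}

#' Cross-sample QC summary
#'
#' Per-sample totals of reads, unique sequences, and standard /
#' non-standard / unanchored alignments, plus flags for any pair of
#' samples whose standard totals differ by more than two-fold (libraries
#' compared downstream should be within about two-fold of one another).
#'
#' @param pops List of `sample_population` objects.
#' @return A list with `table` (one row per sample) and `flagged_pairs`
#'   (data.frame of sample pairs exceeding two-fold, possibly empty).
#' @export
qc_summary <- function(pops) {
  stopifnot(length(pops) >= 1L)
  tab <- do.call(rbind, lapply(pops, function(p) {
    data.frame(sample_id = p$sample_id, t(p$qc), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  pairs <- data.frame(sample_a = character(0), sample_b = character(0),
                      ratio = numeric(0), stringsAsFactors = FALSE)
  n <- nrow(tab)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      a <- tab$standard[i]; b <- tab$standard[j]
      ratio <- max(a, b) / max(min(a, b), 1)
      if (ratio > 2) {
        pairs <- rbind(pairs, data.frame(
          sample_a = tab$sample_id[i], sample_b = tab$sample_id[j],
          ratio = ratio, stringsAsFactors = FALSE))
      }
    }
  }
  list(table = tab, flagged_pairs = pairs)
}

#' Write class fractions, histogram and QC tables as TSV
#'
#' @param pops List of `sample_population` objects (same template).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_population_tsv <- function(pops, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table <- pops[[1]]$table
  cf <- do.call(rbind, lapply(pops, function(p)
    data.frame(sample_id = p$sample_id, t(class_fractions(p)))))
  hist <- do.call(cbind, lapply(pops, function(p) stop_site_histogram(p)))
  colnames(hist) <- vapply(pops, function(p) p$sample_id, character(1))
  hist_df <- data.frame(site = 0:table$n_sites,
                        label = site_label(table, 0:table$n_sites), hist,
                        check.names = FALSE)
  qc <- qc_summary(pops)$table
  paths <- c(class_fractions = file.path(dir, "class_fractions.tsv"),
             histogram = file.path(dir, "stop_site_histogram.tsv"),
             qc = file.path(dir, "qc.tsv"))
  utils::write.table(cf, paths[["class_fractions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hist_df, paths[["histogram"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qc, paths[["qc"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
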