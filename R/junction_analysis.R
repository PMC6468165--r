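# Junction characterization: ranking the junction sequences arising at a
# stop site, junction-length distributions, and pattern matching (e.g.
# "hybrid" sequences with a non-canonical block flanked by canonical
# editing).

#' Most abundant junction sequences at an editing stop site
#'
#' Groups partially edited sequences sharing the given ESS by exact
#' U-count-vector identity, averages their normalized counts across
#' replicates (sequences absent from a replicate contribute zero, so the
#' average is over all `length(pops)` replicates), and keeps groups whose
#' average is at least `min_avg`. Each group's share of the stop site is
#' the percentage of the chosen denominator population its average
#' represents.
#'
#' @param pops List of `sample_population` objects on a common scale.
#' @param ess Local stop-site index (3'->5'), or use `label` instead.
#' @param label Published site label (alternative to `ess`).
#' @param min_avg Minimum average normalized count to report.
#' @param denominator `"entered"` (default): all sequences that entered
#'   the editing pathway (non-pre-edited) sharing the ESS; `"all"`: all
#'   sequences sharing the ESS including pre-edited ones.
#' @return A data.frame sorted by decreasing `avg_norm_count`: `u_key`,
#'   `avg_norm_count`, `share_of_ESS`, `JL`, `JES`, `display` (rendered
#'   junction sequence, inserted Us in lowercase `u`), `matched_sites`
#'   (comma-joined 0/1 mask, 3'->5', of sites matching the fully edited
#'   template).
#' @export
top_junctions <- function(pops, ess = NULL, label = NULL, min_avg = 100,
                          denominator = c("entered", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(length(pops) >= 1L)
  table <- pops[[1]]$table
  if (is.null(ess)) {
    if (is.null(label)) stop("give either ess or label", call. = FALSE)
    ess <- label_to_site(table, label)
  }
  if (ess < 0L || ess > table$n_sites)
    stop("ess out of range 0..", table$n_sites, call. = FALSE)
  n_rep <- length(pops)

  per_pop <- lapply(pops, function(p) {
    e <- p$entries[p$entries$ESS == ess, , drop = FALSE]
    list(all = e,
         entered = e[e$eclass != "pre_edited", , drop = FALSE],
         partial = e[e$eclass == "partially_edited", , drop = FALSE])
  })
  denom_avg <- mean(vapply(per_pop, function(x)
    sum(x[[denominator]]$norm_count), numeric(1)))

  # sum normalized counts per u_key within each replicate, then zero-fill
  sums <- lapply(per_pop, function(x)
    tapply(x$partial$norm_count, x$partial$u_key, sum))
  keys <- unique(unlist(lapply(sums, names)))
  if (!length(keys)) {
    return(data.frame(u_key = character(0), avg_norm_count = numeric(0),
                      share_of_ESS = numeric(0), JL = integer(0),
                      JES = integer(0), display = character(0),
                      matched_sites = character(0), stringsAsFactors = FALSE))
  }
  key_mat <- matrix(vapply(sums, function(s) {
    v <- s[keys]; v[is.na(v)] <- 0; as.numeric(v)
  }, numeric(length(keys))), nrow = length(keys))
  avg <- rowSums(key_mat) / n_rep
  u_mat <- do.call(rbind, lapply(strsplit(keys, ",", fixed = TRUE),
                                 as.integer))
  lm <- classify_matrix(u_mat, table)
  out <- data.frame(
    u_key = keys,
    avg_norm_count = avg,
    share_of_ESS = if (denom_avg > 0) 100 * avg / denom_avg else NA_real_,
    JL = lm$JL, JES = lm$JES,
    display = vapply(seq_along(keys), function(i)
      render_display(table, u_mat[i, ]), character(1)),
    matched_sites = vapply(seq_along(keys), function(i)
      paste(as.integer(u_mat[i, ] == table$full_U), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  out <- out[out$avg_norm_count >= min_avg, , drop = FALSE]
  out <- out[order(-out$avg_norm_count, out$u_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Junction-length distribution per sample group
#'
#' Sums the normalized counts of partially edited sequences into junction
#' length (JL) bins within each replicate and averages across the
#' replicates of each group. Default bins follow the conventional 0, 1-2
#' and 11-13 split.
#'
#' @param groups Named list of sample groups, each a list of
#'   `sample_population` objects.
#' @param bins Named list of inclusive `c(lo, hi)` JL ranges; must not
#'   overlap.
#' @return A data.frame: `group`, `bin`, `avg_norm_count`.
#' @export
junction_length_distribution <- function(groups,
                                         bins = list(`0` = c(0, 0),
                                                     `1-2` = c(1, 2),
                                                     `11-13` = c(11, 13))) {
  stopifnot(is.list(groups), length(groups) >= 1L, is.list(bins))
  lo <- vapply(bins, `[`, numeric(1), 1L)
  hi <- vapply(bins, `[`, numeric(1), 2L)
  if (any(hi < lo)) stop("bin with hi < lo", call. = FALSE)
  o <- order(lo)
  if (any(lo[o][-1] <= hi[o][-length(o)]))
    stop("overlapping junction-length bins", call. = FALSE)
  rows <- list()
  for (g in names(groups)) {
    pops <- groups[[g]]
    per_bin <- vapply(pops, function(p) {
      part <- p$entries[p$entries$eclass == "partially_edited", , drop = FALSE]
      vapply(seq_along(bins), function(b)
        sum(part$norm_count[part$JL >= lo[b] & part$JL <= hi[b]]),
        numeric(1))
    }, numeric(length(bins)))
    per_bin <- matrix(per_bin, nrow = length(bins))
    rows[[g]] <- data.frame(group = g, bin = names(bins),
                            avg_norm_count = rowMeans(per_bin),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a junction pattern specification
#'
#' A pattern is a set of per-site predicates on U counts, addressed by
#' published site labels: `exact` (a specific count), `canonical` (the
#' fully edited count), `pre` (the pre-edited count) or `any`. For
#' example, a "hybrid" pattern demands a specific non-canonical count at
#' one site with canonical editing at its neighbours.
#'
#' @param ... Named arguments: names are site labels (coercible to
#'   integer), values either an integer (exact count), or one of the
#'   strings `"canonical"`, `"pre"`, `"any"`.
#' @return An object of class `pattern_spec`.
#' @examples
#' hybrid <- pattern_spec(`447` = 9, `446` = "canonical", `448` = "canonical")
#' @export
pattern_spec <- function(...) {
  preds <- list(...)
  if (length(preds) && is.null(names(preds)))
    stop("pattern predicates must be named by site label", call. = FALSE)
  out <- lapply(seq_along(preds), function(i) {
    v <- preds[[i]]
    if (is.numeric(v)) list(label = as.integer(names(preds)[i]),
                            type = "exact", k = as.integer(v))
    else if (is.character(v) && v %in% c("canonical", "pre", "any"))
      list(label = as.integer(names(preds)[i]), type = v, k = NA_integer_)
    else stop("predicate must be a count or one of canonical/pre/any",
              call. = FALSE)
  })
  structure(out, class = "pattern_spec")
}

#' Match a U-count vector against a junction pattern
#'
#' @param u_counts Integer vector (3'->5', length `n_sites`).
#' @param spec A [pattern_spec()].
#' @param table An `es_table` (resolves labels and canonical counts).
#' @return `TRUE` iff every predicate holds (vacuously `TRUE` for an
#'   empty pattern).
#' @export
match_pattern <- function(u_counts, spec, table) {
  stopifnot(inherits(spec, "pattern_spec"),
            length(u_counts) == table$n_sites)
  u <- as.integer(u_counts)
  for (p in spec) {
    i <- label_to_site(table, p$label)
    ok <- switch(p$type,
                 exact = u[i] == p$k,
                 canonical = u[i] == table$full_U[i],
                 pre = u[i] == table$pre_U[i],
                 any = TRUE)
    if (!ok) return(FALSE)
  }
  TRUE
}
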