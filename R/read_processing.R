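# Read handling: collapsing, flank anchoring, per-site U counting,
# classification and editing landmarks (ESS/JSS/JES/JL).

#' Collapse identical reads into unique sequences with counts
#'
#' Exact-identity grouping: the returned table has one row per distinct
#' sequence with its multiplicity, ordered by count (descending) then
#' lexicographically, so output is deterministic for a given multiset of
#' reads.
#'
#' @param reads Character vector of read sequences.
#' @return A data.frame with columns `sequence` and `count`
#'   (`sum(count) == length(reads)`).
#' @export
collapse_reads <- function(reads) {
  reads <- as.character(reads)
  if (!length(reads)) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  d <- data.frame(sequence = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper over `Biostrings` readers. Qualities are dropped: all
#' downstream analysis operates on merged sequence identity only. Format is
#' inferred from the file extension (`.fq`/`.fastq`, optionally `.gz`,
#' means FASTQ) unless given.
#'
#' @param path File path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Character vector of sequences (names = record ids).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

revcomp <- function(seq) {
  ch <- strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]
  paste(rev(ch), collapse = "")
}

# locate an exact, unique occurrence of `pattern` in `seq`; NA if absent,
# error if multiple (ambiguous anchoring)
locate_unique <- function(seq, pattern, flank_name) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  if (length(hits) > 1L)
    stop("ambiguous alignment: multiple placements of ", flank_name,
         call. = FALSE)
  hits[1]
}

#' Align one read to the template coordinate system
#'
#' Anchors the read by exact match of both never-edited flanks (forward
#' first, then reverse complement), extracts the editing domain between
#' them, and compares its non-T skeleton to the template's. Reads whose
#' flanks cannot be placed are `unanchored`; reads with any non-T mismatch
#' in the domain are `non_standard` and carry no U counts; the remainder
#' are `standard` with per-site U counts in 3'->5' site coordinates.
#'
#' @param seq A single read sequence (character).
#' @param table An `es_table` from [build_site_table()].
#' @return A list with `category` (`"standard"`, `"non_standard"`,
#'   `"unanchored"`), `orientation` (`"forward"`/`"reverse_complement"`/
#'   `NA`), and `u_counts` (integer vector of length `n_sites`, or `NULL`).
#' @export
align_to_templates <- function(seq, table) {
  stopifnot(inherits(table, "es_table"), length(seq) == 1L)
  cfg <- table$config
  seq <- clean_seq(seq)

  anchored <- function(s) {
    i5 <- locate_unique(s, cfg$flank5, "flank5")
    if (is.na(i5)) return(NULL)
    after <- substr(s, i5 + nchar(cfg$flank5), nchar(s))
    i3 <- locate_unique(after, cfg$flank3, "flank3")
    if (is.na(i3)) return(NULL)
    substr(after, 1L, i3 - 1L)
  }

  dom <- anchored(seq)
  orientation <- "forward"
  if (is.null(dom)) {
    dom <- anchored(revcomp(seq))
    orientation <- "reverse_complement"
  }
  if (is.null(dom)) {
    return(list(category = "unanchored", orientation = NA_character_,
                u_counts = NULL))
  }
  ext <- ext_domain(cfg, dom)
  sk <- skeleton_chars(ext)
  if (length(sk) != length(table$skeleton) || any(sk != table$skeleton)) {
    return(list(category = "non_standard", orientation = orientation,
                u_counts = NULL))
  }
  list(category = "standard", orientation = orientation,
       u_counts = gap_u_counts(ext))
}

#' Classify a standard alignment and compute its editing landmarks
#'
#' Classification is by exact U-count vector equality: equal to the
#' pre-edited template is `pre_edited`, equal to the fully edited template
#' is `fully_edited`, anything else `partially_edited` (when the two
#' templates are identical the pre-edited label wins). Landmarks follow
#' the standard definitions, all in 3'->5' local site indices:
#' * **ESS** (editing stop site): the largest `k` such that sites `1..k`
#'   all match the fully edited template (0 if site 1 already differs);
#' * **JSS** = ESS + 1, the first site, moving 3'->5', that does not match;
#' * **JES**: the 5'-most site with any editing action, i.e. the largest
#'   site differing from the pre-edited template (0 if none);
#' * **JL** = max(0, JES - ESS), the junction length in editing sites
#'   (e.g. ESS 15 with JES at site 20 gives JL 5).
#'
#' @param u_counts Integer vector of per-site U counts (3'->5').
#' @param table An `es_table`.
#' @return A list with `eclass`, `ESS`, `JSS`, `JES`, `JL`.
#' @export
classify_and_landmark <- function(u_counts, table) {
  m <- table$n_sites
  if (length(u_counts) != m)
    stop("u_counts has length ", length(u_counts), ", expected ", m,
         call. = FALSE)
  u <- as.integer(u_counts)
  eclass <- if (all(u == table$pre_U)) "pre_edited"
            else if (all(u == table$full_U)) "fully_edited"
            else "partially_edited"
  mism_full <- which(u != table$full_U)
  ESS <- if (length(mism_full)) mism_full[1L] - 1L else m
  act <- which(u != table$pre_U)
  JES <- if (length(act)) act[length(act)] else 0L
  list(eclass = eclass, ESS = ESS, JSS = ESS + 1L, JES = JES,
       JL = max(0L, JES - ESS))
}

# Vectorized classification of a matrix of U-count vectors (rows = reads,
# columns = sites 3'->5'). Same contract as classify_and_landmark.
classify_matrix <- function(u_mat, table) {
  m <- table$n_sites
  stopifnot(ncol(u_mat) == m)
  n <- nrow(u_mat)
  pre  <- matrix(table$pre_U,  n, m, byrow = TRUE)
  full <- matrix(table$full_U, n, m, byrow = TRUE)
  mm_full <- u_mat != full
  mm_pre  <- u_mat != pre
  any_full <- rowSums(mm_full) > 0L
  any_pre  <- rowSums(mm_pre) > 0L
  first_mm <- max.col(mm_full, ties.method = "first")
  ESS <- ifelse(any_full, first_mm - 1L, m)
  last_act <- max.col(mm_pre, ties.method = "last")
  JES <- ifelse(any_pre, last_act, 0L)
  eclass <- ifelse(!any_pre, "pre_edited",
                   ifelse(!any_full, "fully_edited", "partially_edited"))
  data.frame(eclass = eclass, ESS = as.integer(ESS), JSS = as.integer(ESS) + 1L,
             JES = as.integer(JES), JL = pmax(0L, as.integer(JES) - as.integer(ESS)),
             stringsAsFactors = FALSE)
}

#' Process one sample's reads through collapse, alignment and landmarks
#'
#' The per-sample front half of the pipeline: collapse to unique sequences,
#' align each to the templates, classify and landmark the standard
#' alignments, and tally QC categories. Reads that trigger an ambiguous
#' flank placement are tallied as unanchored.
#'
#' @param reads Character vector of merged read sequences.
#' @param table An `es_table`.
#' @return A list with `aligned` (data.frame over standard alignments:
#'   `sequence`, `count`, `orientation`, `u_key` (comma-joined U counts),
#'   `eclass`, `ESS`, `JSS`, `JES`, `JL`), `u_mat` (matrix of U counts,
#'   rows matching `aligned`), and `qc` (named counts: total, unique,
#'   standard, non_standard, unanchored -- read totals, not uniques).
#' @export
process_reads <- function(reads, table) {
  uniq <- collapse_reads(reads)
  n_uniq <- nrow(uniq)
  category <- character(n_uniq)
  orientation <- rep(NA_character_, n_uniq)
  u_list <- vector("list", n_uniq)
  for (i in seq_len(n_uniq)) {
    out <- tryCatch(align_to_templates(uniq$sequence[i], table),
                    error = function(e) list(category = "unanchored",
                                             orientation = NA_character_,
                                             u_counts = NULL))
    category[i] <- out$category
    orientation[i] <- out$orientation
    if (out$category == "standard") u_list[[i]] <- out$u_counts
  }
  std <- category == "standard"
  qc <- c(total       = sum(uniq$count),
          unique      = n_uniq,
          standard    = sum(uniq$count[std]),
          non_standard = sum(uniq$count[category == "non_standard"]),
          unanchored  = sum(uniq$count[category == "unanchored"]))
  if (!any(std)) {
    u_mat <- matrix(0L, 0L, table$n_sites)
    aligned <- data.frame(sequence = character(0), count = integer(0),
                          orientation = character(0), u_key = character(0),
                          eclass = character(0), ESS = integer(0),
                          JSS = integer(0), JES = integer(0), JL = integer(0),
                          stringsAsFactors = FALSE)
    return(list(aligned = aligned, u_mat = u_mat, qc = qc))
  }
  u_mat <- do.call(rbind, u_list[std])
  lm <- classify_matrix(u_mat, table)
  aligned <- data.frame(
    sequence = uniq$sequence[std],
    count = uniq$count[std],
    orientation = orientation[std],
    u_key = apply(u_mat, 1L, paste, collapse = ","),
    lm, stringsAsFactors = FALSE)
  rownames(aligned) <- NULL
  list(aligned = aligned, u_mat = u_mat, qc = qc)
}

#' Write per-sequence alignment results as TSV
#'
#' One row per unique standard-aligned sequence: sequence, count, category
#' fields, landmarks with both local and published ESS labels, and the
#' per-site U counts comma-joined 3'->5'.
#'
#' @param processed Result of [process_reads()].
#' @param table The `es_table` used.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_alignment_tsv <- function(processed, table, path) {
  a <- processed$aligned
  out <- data.frame(
    sequence = a$sequence, count = a$count, orientation = a$orientation,
    eclass = a$eclass, ESS = a$ESS,
    ESS_label = site_label(table, a$ESS),
    JSS = a$JSS, JES = a$JES, JL = a$JL, u_counts = a$u_key,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
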