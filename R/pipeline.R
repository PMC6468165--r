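# End-to-end orchestration: per-sample runs (collapse -> align -> classify
# -> normalize -> histogram, with TSV outputs and a reproducibility
# manifest) and group comparisons (IPS / EPS / junction reports).
#
# There is no separate shell entry point: these functions, together with
# the per-stage functions they wrap, are the pipeline interface.

write_manifest <- function(path, fields) {
  lines <- c(sprintf("uindel_version: %s",
                     as.character(utils::packageVersion("uindel"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             vapply(names(fields), function(k)
               sprintf("%s: %s", k, paste(fields[[k]], collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the per-sample half of the pipeline and write its tables
#'
#' Reads (a FASTA/FASTQ path or a character vector) are collapsed,
#' aligned to the templates, classified, normalized and histogrammed; the
#' per-sequence alignment table, class fractions, stop-site histogram, QC
#' table and a run manifest (parameters, input checksum, package version)
#' are written under `out_dir`.
#'
#' @param reads Character vector of read sequences, or a file path.
#' @param config A [gene_template()].
#' @param out_dir Output directory.
#' @param sample_id Sample identifier.
#' @param scale Normalization target.
#' @return The `sample_population`, invisibly.
#' @export
run_sample <- function(reads, config, out_dir, sample_id = "sample",
                       scale = 1e5) {
  table <- build_site_table(config)
  input_md5 <- NA_character_
  if (length(reads) == 1L && file.exists(reads)) {
    input_md5 <- unname(tools::md5sum(reads))
    reads <- read_sequences(reads)
  }
  if (!length(reads)) stop("no reads supplied", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  processed <- process_reads(reads, table)
  pop <- normalize_sample(processed, table, sample_id = sample_id,
                          scale = scale)
  write_alignment_tsv(processed, table, file.path(out_dir, "sequences.tsv"))
  write_population_tsv(list(pop), out_dir)
  write_manifest(file.path(out_dir, "manifest.txt"), list(
    sample_id = sample_id, gene = config$gene_name, scale = scale,
    input_md5 = input_md5, n_reads = sum(processed$qc["total"]),
    quartile_convention = "linear interpolation (type 7)"))
  invisible(pop)
}

#' Run a group comparison: IPS consensus, EPS detection, junction lengths
#'
#' Calls intrinsic pause sites on the uninduced replicate set, detects
#' exacerbated pause sites between the induced and uninduced groups,
#' computes the junction-length distribution of both groups, and writes
#' all reports plus a manifest of the statistical parameters used.
#'
#' @param induced,uninduced Lists of `sample_population` objects (>= 2
#'   each for EPS; `induced` may be `NULL` for an IPS-only run).
#' @param out_dir Output directory.
#' @param min_support IPS replicate-consensus threshold.
#' @param alpha,q_alpha,drop_pre,rule,low_abundance Passed to
#'   [detect_eps()].
#' @return List with `ips`, `eps` (NULL if not computed), `class_change`,
#'   `jl_distribution`, invisibly.
#' @export
run_comparison <- function(induced = NULL, uninduced, out_dir,
                           min_support = 4L, alpha = 0.05, q_alpha = 0.05,
                           drop_pre = TRUE, rule = "group_t",
                           low_abundance = 500) {
  if (length(uninduced) < 2L)
    stop("need at least 2 uninduced replicates", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- uninduced[[1]]$table
  hists <- lapply(uninduced, stop_site_histogram)
  ips <- detect_ips(hists, table = table, min_support = min_support)
  eps <- NULL; cls <- NULL
  groups <- list(uninduced = uninduced)
  if (!is.null(induced)) {
    if (length(induced) < 2L)
      stop("need at least 2 induced replicates for EPS detection",
           call. = FALSE)
    eps <- detect_eps(induced, uninduced, alpha = alpha, q_alpha = q_alpha,
                      drop_pre = drop_pre, rule = rule,
                      low_abundance = low_abundance)
    cls <- class_change_test(induced, uninduced)
    groups$induced <- induced
  }
  jl <- junction_length_distribution(groups)
  write_pause_tsv(ips = ips, eps = eps, dir = out_dir)
  utils::write.table(jl, file.path(out_dir, "junction_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cls))
    utils::write.table(cls, file.path(out_dir, "class_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.txt"), list(
    gene = table$gene_name,
    n_uninduced = length(uninduced),
    n_induced = if (is.null(induced)) 0L else length(induced),
    min_support = min_support, alpha = alpha, q_alpha = q_alpha,
    drop_pre = drop_pre, eps_rule = rule, low_abundance = low_abundance,
    quartile_convention = "linear interpolation (type 7)"))
  invisible(list(ips = ips, eps = eps, class_change = cls,
                 jl_distribution = jl))
}
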