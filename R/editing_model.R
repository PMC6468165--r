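# Editing-site coordinate system: templates, site tables, rendering.
#
# An editing site (ES) is any gap between two consecutive non-T bases of the
# editing domain (cDNA sense). Sites are numbered 3'->5', 1-based, following
# the direction of editing; published labels are obtained by adding a
# per-gene offset. The gaps between the domain's terminal skeleton bases and
# the flanks' adjacent non-T bases are in-domain sites, so flanks are
# required to abut the domain with a non-T base.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Gene template configuration
#'
#' Bundles the pre-edited and fully edited template sequences of one editing
#' domain together with its never-edited flanks and the published label of
#' its 3'-most editing site. Sequences are cDNA-sense DNA strings (`T`
#' stands for uridine); `U` on input is accepted and converted.
#'
#' @param gene_name Gene identifier, e.g. `"CYb"`.
#' @param pre_edited Full pre-edited template: `flank5 + domain + flank3`.
#' @param fully_edited Full fully edited template, same flanks.
#' @param flank5 Never-edited 5' flank (primer-proximal); must end on a
#'   non-T base so the 5' boundary editing site is well defined.
#' @param flank3 Never-edited 3' flank; must begin on a non-T base.
#' @param es_offset Published number of the 3'-most editing site of the
#'   domain (local site 1), e.g. `441` maps local site 1 to "ES441".
#' @return An object of class `gene_template`.
#' @seealso [build_site_table()], [validate_templates()]
#' @export
gene_template <- function(gene_name, pre_edited, fully_edited,
                          flank5, flank3, es_offset = 1L) {
  cfg <- structure(list(
    gene_name    = as.character(gene_name),
    pre_edited   = clean_seq(pre_edited),
    fully_edited = clean_seq(fully_edited),
    flank5       = clean_seq(flank5),
    flank3       = clean_seq(flank3),
    es_offset    = as.integer(es_offset)
  ), class = "gene_template")
  cfg
}

# uppercase, U->T; no validation here (validate_templates reports problems)
clean_seq <- function(x) {
  chartr("uU", "tT", toupper(as.character(x)))
}

#' @export
print.gene_template <- function(x, ...) {
  cat("gene_template:", x$gene_name, "\n")
  cat("  pre-edited  ", nchar(x$pre_edited), "nt; fully edited",
      nchar(x$fully_edited), "nt\n")
  cat("  flanks", nchar(x$flank5), "/", nchar(x$flank3),
      "nt; es_offset", x$es_offset, "\n")
  invisible(x)
}

#' Validate a gene template configuration
#'
#' Checks every structural invariant of a [gene_template()] and returns the
#' full list of violations rather than stopping at the first. An empty
#' report means [build_site_table()] will succeed.
#'
#' @param config A `gene_template`.
#' @return Character vector of violation messages (length 0 if valid).
#' @export
validate_templates <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  for (fld in c("pre_edited", "fully_edited", "flank5", "flank3")) {
    s <- config[[fld]]
    if (!nzchar(s)) { note(sprintf("%s is empty", fld)); next }
    bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), DNA_ALPHABET)
    if (length(bad))
      note(sprintf("%s contains non-ACGT characters: %s", fld,
                   paste(bad, collapse = ",")))
  }
  if (length(problems)) return(problems)

  if (substring(config$flank5, nchar(config$flank5)) == "T")
    note("flank5 ends on T: the 5' flank must abut the domain with a non-T base")
  if (substring(config$flank3, 1L, 1L) == "T")
    note("flank3 begins with T: the 3' flank must abut the domain with a non-T base")
  for (fld in c("pre_edited", "fully_edited")) {
    s <- config[[fld]]
    if (!startsWith(s, config$flank5))
      note(sprintf("%s does not begin with flank5", fld))
    if (!endsWith(s, config$flank3))
      note(sprintf("%s does not end with flank3", fld))
    if (nchar(s) < nchar(config$flank5) + nchar(config$flank3))
      note(sprintf("%s is shorter than the two flanks combined", fld))
  }
  if (length(problems)) return(problems)

  pre  <- domain_of(config, "pre_edited")
  full <- domain_of(config, "fully_edited")
  sk_pre  <- skeleton_chars(ext_domain(config, pre))
  sk_full <- skeleton_chars(ext_domain(config, full))
  if (length(sk_pre) != length(sk_full) || any(sk_pre != sk_full)) {
    k <- min(length(sk_pre), length(sk_full))
    div <- if (k && any(sk_pre[seq_len(k)] != sk_full[seq_len(k)]))
      which(sk_pre[seq_len(k)] != sk_full[seq_len(k)])[1L] else k + 1L
    note(sprintf(
      "skeleton mismatch between pre-edited and fully edited domains at skeleton position %d",
      div))
  }
  problems
}

# extract the editing domain (between the flanks) of a template field
domain_of <- function(config, field) {
  s <- config[[field]]
  substr(s, nchar(config$flank5) + 1L, nchar(s) - nchar(config$flank3))
}

# extended domain: bracket the domain with the flank-adjacent non-T anchor
# bases so that both boundary gaps become ordinary inter-base gaps
ext_domain <- function(config, domain) {
  paste0(substring(config$flank5, nchar(config$flank5)), domain,
         substring(config$flank3, 1L, 1L))
}

skeleton_chars <- function(ext) {
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  ch[ch != "T"]
}

# U counts per gap of an extended domain, 3'->5' order
gap_u_counts <- function(ext) {
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  pos <- which(ch != "T")
  rev(diff(pos) - 1L)
}

#' Compile a gene template into an editing-site table
#'
#' Scans both templates for editing sites -- every gap between two
#' consecutive non-T bases of the domain, boundary gaps against the flank
#' anchor bases included -- and records the uridine count of each site in
#' the pre-edited and fully edited templates. The two templates must share
#' an identical non-T skeleton.
#'
#' @param config A valid [gene_template()].
#' @return An object of class `es_table` with elements `gene_name`,
#'   `skeleton` (non-T bases, 5'->3', flank anchor bases at both ends),
#'   `n_sites`, `pre_U`, `full_U`, `requires_editing` (all 3'->5', site 1 =
#'   3'-most gap), `es_offset`, and the originating `config`.
#' @examples
#' cfg <- gene_template("toy",
#'   pre_edited   = "CCGACGACC", fully_edited = "CCGATTCGTTTACC",
#'   flank5 = "CCG", flank3 = "ACC", es_offset = 101)
#' tab <- build_site_table(cfg)
#' tab$full_U          # 3'->5' U counts of the edited template
#' site_label(tab, 1)  # published label of the 3'-most site
#' @export
build_site_table <- function(config) {
  stopifnot(inherits(config, "gene_template"))
  problems <- validate_templates(config)
  if (length(problems)) {
    stop("invalid gene template:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  pre  <- domain_of(config, "pre_edited")
  full <- domain_of(config, "fully_edited")
  ext_pre  <- ext_domain(config, pre)
  ext_full <- ext_domain(config, full)
  skeleton <- skeleton_chars(ext_pre)
  pre_U  <- gap_u_counts(ext_pre)
  full_U <- gap_u_counts(ext_full)
  m <- length(skeleton) - 1L
  stopifnot(length(pre_U) == m, length(full_U) == m)
  structure(list(
    gene_name        = config$gene_name,
    skeleton         = skeleton,
    n_sites          = m,
    pre_U            = as.integer(pre_U),
    full_U           = as.integer(full_U),
    requires_editing = pre_U != full_U,
    es_offset        = config$es_offset,
    config           = config
  ), class = "es_table")
}

#' @export
print.es_table <- function(x, ...) {
  cat("es_table:", x$gene_name, "-", x$n_sites, "editing sites (",
      sum(x$requires_editing), "require editing )\n")
  cat("  labels", site_label(x, 1L), "..", site_label(x, x$n_sites),
      "( 3'->5' )\n")
  invisible(x)
}

#' Published label of a local editing site
#'
#' Local site indices run 3'->5' with 1 the 3'-most gap of the domain;
#' `site_label()` converts them to published "ESnnn"-style numbers via the
#' template's `es_offset`. Site 0 (no canonical progress) maps to the label
#' of the site 3' of the domain, `es_offset - 1`.
#'
#' @param table An `es_table`.
#' @param i Local site index (vectorized), in `0..n_sites`.
#' @return Integer label(s).
#' @export
site_label <- function(table, i) {
  i <- as.integer(i)
  if (any(i < 0L | i > table$n_sites))
    stop("site index out of range 0..", table$n_sites, call. = FALSE)
  table$es_offset + i - 1L
}

#' Convert a published site label back to a local index
#'
#' @inheritParams site_label
#' @param label Published editing-site number(s).
#' @return Local 3'->5' site index in `1..n_sites`.
#' @export
label_to_site <- function(table, label) {
  i <- as.integer(label) - table$es_offset + 1L
  if (any(i < 1L | i > table$n_sites))
    stop("label outside the editing domain of ", table$gene_name, call. = FALSE)
  i
}

# Render a U-count vector (3'->5') over the table's skeleton back into the
# extended-domain string (anchors included). Inverse of gap_u_counts.
render_ext <- function(table, u_counts) {
  m <- table$n_sites
  stopifnot(length(u_counts) == m)
  u53 <- rev(as.integer(u_counts))          # 5'->3' gap order
  n <- m + 1L
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <- table$skeleton
  parts[seq(2L, 2L * n - 2L, by = 2L)] <- strrep("T", u53)
  paste(parts, collapse = "")
}

#' Render a U-count vector as a domain or full-molecule sequence
#'
#' Reconstructs the cDNA-sense sequence carrying the given per-site U
#' counts. With `what = "domain"` the string spans the editing domain only
#' (flank anchor bases excluded); `"full"` prepends/appends the flanks,
#' giving the complete amplicon a read with those counts would produce.
#'
#' @param table An `es_table`.
#' @param u_counts Integer vector of U counts, 3'->5', length `n_sites`.
#' @param what `"domain"` or `"full"`.
#' @return A character string.
#' @export
render_sequence <- function(table, u_counts, what = c("domain", "full")) {
  what <- match.arg(what)
  ext <- render_ext(table, u_counts)
  dom <- substr(ext, 2L, nchar(ext) - 1L)
  if (what == "domain") return(dom)
  paste0(table$config$flank5, dom, table$config$flank3)
}

#' Display a U-count vector in the figures' lowercase-u convention
#'
#' Renders the domain with inserted uridines in lowercase `u` and
#' genome-encoded bases (including encoded uridines, shown as `U`) in upper
#' case, the display convention used for junction tables.
#'
#' @inheritParams render_sequence
#' @return A character string over `A,C,G,U,u`.
#' @export
render_display <- function(table, u_counts) {
  m <- table$n_sites
  stopifnot(length(u_counts) == m)
  u53   <- rev(as.integer(u_counts))
  pre53 <- rev(table$pre_U)
  runs <- vapply(seq_len(m), function(j) {
    enc <- min(u53[j], pre53[j])           # encoded Us retained
    paste0(strrep("U", enc), strrep("u", u53[j] - enc))
  }, character(1))
  sk <- table$skeleton
  paste0(paste0(sk[seq_len(m)], runs, collapse = ""), sk[m + 1L])
}

#' Built-in synthetic demonstration template
#'
#' A fixed, synthetic minimally-edited-style gene ("synDemo") with 40
#' editing sites, 32 of which require editing (insertions and deletions of
#' up to six uridines), flanked by 25-nt never-edited regions. It is not
#' derived from any real mitochondrial gene; it exists so that examples,
#' simulations and tests have a realistic-sized domain with known structure.
#'
#' @return A [gene_template()].
#' @examples
#' tab <- build_site_table(demo_template())
#' tab$n_sites
#' @export
demo_template <- function() {
  flank5 <- "TGTGCGCGTGCATGATTTGCTAGCG"
  flank3 <- "CCCCTTGCAACTTTATCAGAATTCA"
  pre_dom  <- "AGAAGATGTACTTATTCTTACATCATGTTAACTGCTGGGAACCAAAAAAAAAG"
  full_dom <- paste0(
    "TTTATGTTTTTTATTTTATTTTTTGTTATTTTTTGTTTTATTTTCTTATCTACATCTTATTTTGTT",
    "TTATTACTTTTGCGGTGTTTTTTATTATTTTTCTTCTTTATATTTTTATTTTTATTTATTTTTATTAATATGTT")
  gene_template(
    gene_name    = "synDemo",
    pre_edited   = paste0(flank5, pre_dom, flank3),
    fully_edited = paste0(flank5, full_dom, flank3),
    flank5       = flank5,
    flank3       = flank3,
    es_offset    = 101L
  )
}
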