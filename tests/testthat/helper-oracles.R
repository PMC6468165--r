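# Shared fixtures and independent oracles.

# 4-site toy template: pre domain ext "GACGA", fully edited ext "GATCGTTA"
# (one U inserted in the second gap, two in the fourth, 5'->3')
toy_config <- function() {
  gene_template("toy",
                pre_edited   = "CCGACGACC",
                fully_edited = "CCGATCGTTACC",
                flank5 = "CCG", flank3 = "ACC", es_offset = 1L)
}

toy_table <- function() build_site_table(toy_config())

# toy2: a minimally-edited-style template whose fully edited domain carries
# a 5-U site and a 4-U site separated by one skeleton base (A) -- the
# configuration in which a single-U bulge in the guide merges purine runs
toy2_table <- function() {
  build_site_table(gene_template(
    "toy2",
    pre_edited   = paste0("CATTACGACG", "GAC", "GTACCGTTAG"),
    fully_edited = paste0("CATTACGACG", "GTTTTATTTTTC", "GTACCGTTAG"),
    flank5 = "CATTACGACG", flank3 = "GTACCGTTAG", es_offset = 445L))
}

# independent landmark derivation, written directly from the definitions:
# ESS = the final (5'-most) site matching the canonical fully edited
# sequence with every site 3' of it matching too; JSS = first mismatching
# site moving 3'->5'; JES = 5'-most site with any editing action; JL =
# number of sites within the junction
oracle_landmarks <- function(u, pre_U, full_U) {
  m <- length(u)
  ESS <- 0L
  for (k in seq_len(m)) {
    matches_through_k <- TRUE
    for (i in seq_len(k)) if (u[i] != full_U[i]) matches_through_k <- FALSE
    if (matches_through_k) ESS <- k
  }
  JES <- 0L
  for (i in seq_len(m)) if (u[i] != pre_U[i]) JES <- i
  eclass <- "partially_edited"
  if (identical(as.integer(u), as.integer(pre_U))) eclass <- "pre_edited"
  else if (identical(as.integer(u), as.integer(full_U))) eclass <- "fully_edited"
  list(eclass = eclass, ESS = ESS, JSS = ESS + 1L, JES = JES,
       JL = max(0L, JES - ESS))
}

# brute-force Tukey threshold: full sort + linearly interpolated quartiles
oracle_tukey <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  interp <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  q1 <- interp(0.25); q3 <- interp(0.75)
  q3 + 1.5 * (q3 - q1)
}

# build a sample_population from explicit U-count rows and counts
mk_pop <- function(tab, u_rows, counts, id = "s", scale = 1e5) {
  lm <- do.call(rbind, lapply(seq_len(nrow(u_rows)), function(i) {
    as.data.frame(classify_and_landmark(u_rows[i, ], tab))
  }))
  df <- data.frame(
    sequence = apply(u_rows, 1, paste, collapse = ","),
    count = counts,
    orientation = "forward",
    u_key = apply(u_rows, 1, paste, collapse = ","),
    lm, stringsAsFactors = FALSE)
  normalize_sample(df, tab, sample_id = id, scale = scale)
}

# build a population realizing a given partial-read stop-site histogram
mk_pop_hist <- function(tab, H, id = "s") {
  sites <- which(H > 0) - 1L
  df <- data.frame(
    sequence = NA_character_, count = as.numeric(H[H > 0]),
    orientation = "forward", u_key = NA_character_,
    eclass = "partially_edited", ESS = sites, JSS = sites + 1L,
    JES = sites + 1L, JL = 1L, stringsAsFactors = FALSE)
  normalize_sample(df, tab, sample_id = id, scale = sum(H))
}

# stop sites at which a pause is representable (next site requires editing)
valid_stops <- function(tab) which(tab$requires_editing) - 1L

# generator fast path: populations at the landmark collapse level
fast_pops <- function(params, prefix = "r") {
  sims <- generate_population(params, render = FALSE, keys = FALSE)
  lapply(seq_along(sims), function(i)
    truth_population(sims[[i]]$truth, params$table,
                     sample_id = paste0(prefix, i), collapse = "landmark"))
}
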