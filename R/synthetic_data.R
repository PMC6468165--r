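# Synthetic amplicon read generator with known ground truth.
#
# Reads are drawn per replicate in a fixed order so the seed contract is
# testable: (1) class per read, (2) editing stop site for partial reads,
# (3) junction mechanism, (4) junction content randomness, (5) sequencing
# errors. Replicate r uses seed `seed + r - 1`.

key_of <- function(u_mat) {
  do.call(paste, c(as.data.frame(u_mat), sep = ","))
}

#' Simulation parameters for the synthetic read generator
#'
#' Defines one study condition: class mixture, stop-site distribution,
#' junction mechanisms and sequencing error rate. Defaults describe a
#' wild-type-like population of a minimally edited mRNA: 30% pre-edited,
#' 60% partially edited, 10% fully edited, stop sites uniform over the
#' sites at which a transcript can pause (those whose next site requires
#' editing), a junction mix dominated by pauses without junctions and
#' random per-site U jitter with a small admixture of guide-templated
#' mechanisms, and a 0.1% per-base substitution error rate on non-T bases.
#'
#' @param template A [gene_template()]; default [demo_template()].
#' @param depth Reads per replicate.
#' @param n_replicates Number of replicates.
#' @param p_pre,p_full Class probabilities (partial = 1 - p_pre - p_full).
#' @param stop_site_weights Numeric vector of length `n_sites + 1` over
#'   stop sites `0..n_sites`; the entry for site `n_sites` must be 0
#'   (fully edited mass is governed by `p_full`), and positive weight is
#'   only allowed at sites whose next site requires editing. `NULL` =
#'   uniform over the allowed sites.
#' @param junction_mix Probabilities over mechanisms `no_junction`,
#'   `random_perturbation`, `grna_misalignment`, `alt_grna` (sum 1).
#' @param jl_weights Categorical weights over junction lengths `1, 2, ...`
#'   for the random-perturbation mechanism.
#' @param u_jitter_max Maximum jittered U count per junction site.
#' @param misalignment List `(site, count)`: the merged-purine-run
#'   mechanism stamps `count` uridines at that site on reads stopping
#'   immediately 3' of it.
#' @param alt_block List `(start_site, block)`: the alternative-guide
#'   mechanism stamps the block of U counts at `start_site, start_site+1,
#'   ...` on reads stopping immediately 3' of it.
#' @param epsilon Per-base substitution error rate applied to non-T bases
#'   (guaranteeing errors surface as non-standard alignments).
#' @param seed Base RNG seed.
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(template = demo_template(),
                              depth = 1e5, n_replicates = 5L,
                              p_pre = 0.30, p_full = 0.10,
                              stop_site_weights = NULL,
                              junction_mix = c(no_junction = 0.45,
                                               random_perturbation = 0.35,
                                               grna_misalignment = 0.10,
                                               alt_grna = 0.10),
                              jl_weights = c(0.35, 0.25, 0.10, 0.05, 0.04,
                                             0.03, 0.02, 0.02, 0.02, 0.02,
                                             0.04, 0.04, 0.02),
                              u_jitter_max = 9L,
                              misalignment = list(site = 6L, count = 9L),
                              alt_block = list(start_site = 8L,
                                               block = c(9L, 2L, 1L)),
                              epsilon = 0.001, seed = 1L) {
  table <- build_site_table(template)
  m <- table$n_sites
  allowed <- c(table$requires_editing, FALSE)   # stop s valid iff site s+1 requires editing
  if (is.null(stop_site_weights)) {
    stop_site_weights <- as.numeric(allowed)
  }
  if (length(stop_site_weights) != m + 1L)
    stop("stop_site_weights must have length n_sites + 1 (sites 0..",
         m, ")", call. = FALSE)
  if (stop_site_weights[m + 1L] != 0)
    stop("stop-site weight at site ", m,
         " must be 0 (fully edited mass is set by p_full)", call. = FALSE)
  if (any(stop_site_weights < 0) || sum(stop_site_weights) <= 0)
    stop("stop_site_weights must be nonnegative with positive sum",
         call. = FALSE)
  if (any(stop_site_weights > 0 & !allowed))
    stop("positive stop-site weight at a site whose next site requires no ",
         "editing (such a pause is not representable)", call. = FALSE)
  mech_names <- c("no_junction", "random_perturbation",
                  "grna_misalignment", "alt_grna")
  if (!setequal(names(junction_mix), mech_names))
    stop("junction_mix must name exactly: ",
         paste(mech_names, collapse = ", "), call. = FALSE)
  junction_mix <- junction_mix[mech_names]
  if (abs(sum(junction_mix) - 1) > 1e-8 || any(junction_mix < 0))
    stop("junction_mix must be a probability vector summing to 1",
         call. = FALSE)
  if (p_pre < 0 || p_full < 0 || p_pre + p_full > 1)
    stop("class probabilities invalid", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (junction_mix[["grna_misalignment"]] > 0) {
    s <- misalignment$site
    if (s < 1L || s > m || !table$requires_editing[s] ||
        misalignment$count == table$full_U[s] ||
        misalignment$count == table$pre_U[s])
      stop("misalignment site/count incompatible with the template",
           call. = FALSE)
  }
  if (junction_mix[["alt_grna"]] > 0) {
    i0 <- alt_block$start_site; bl <- as.integer(alt_block$block)
    if (i0 < 1L || i0 + length(bl) - 1L > m)
      stop("alt_block outside the site domain", call. = FALSE)
    if (bl[1] == table$full_U[i0])
      stop("alt_block must start with a non-canonical count", call. = FALSE)
    if (bl[length(bl)] == table$pre_U[i0 + length(bl) - 1L])
      stop("alt_block must end with an edited (non-pre) count", call. = FALSE)
  }
  structure(list(template = template, table = table, depth = as.integer(depth),
                 n_replicates = as.integer(n_replicates),
                 p_pre = p_pre, p_full = p_full,
                 stop_site_weights = stop_site_weights,
                 junction_mix = junction_mix, jl_weights = jl_weights,
                 u_jitter_max = as.integer(u_jitter_max),
                 misalignment = misalignment, alt_block = alt_block,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "sim_params")
}

# draw one value per row from 0..u_max excluding per-row forbidden values
# (vectorized rejection sampling; forbid1/forbid2 may be NA = no constraint)
sample_excluding <- function(n, u_max, forbid1, forbid2 = rep(NA_integer_, n)) {
  if (!n) return(integer(0))
  hits <- function(idx) {
    cond <- (v[idx] == forbid1[idx]) | (v[idx] == forbid2[idx])
    cond[is.na(cond)] <- FALSE
    idx[cond]
  }
  v <- sample.int(u_max + 1L, n, replace = TRUE) - 1L
  bad <- hits(seq_len(n))
  while (length(bad)) {
    v[bad] <- sample.int(u_max + 1L, length(bad), replace = TRUE) - 1L
    bad <- hits(bad)
  }
  v
}

# generate one replicate (per-read truth); keys = FALSE skips the U-count
# key column (content draws are unchanged, so seeds stay aligned)
generate_replicate <- function(params, seed, keys = TRUE) {
  set.seed(seed)
  table <- params$table
  m <- table$n_sites
  depth <- params$depth
  first_req <- if (any(table$requires_editing))
    min(which(table$requires_editing)) else m + 1L
  pre_ess <- min(first_req - 1L, m)

  # (1) class
  cls <- sample(c("pre_edited", "partially_edited", "fully_edited"), depth,
                replace = TRUE,
                prob = c(params$p_pre, 1 - params$p_pre - params$p_full,
                         params$p_full))
  part <- which(cls == "partially_edited")
  n_part <- length(part)

  # (2) editing stop site for partial reads
  s <- if (n_part) sample(0:m, n_part, replace = TRUE,
                          prob = params$stop_site_weights) else integer(0)

  # (3) mechanism; templated mechanisms pin the stop site next to their
  # target block, and a junction-free pause 3' of the first editable site
  # would be indistinguishable from a pre-edited read, so it falls back to
  # random perturbation
  mech <- if (n_part) sample(names(params$junction_mix), n_part,
                             replace = TRUE, prob = params$junction_mix)
          else character(0)
  mech[mech == "no_junction" & s < first_req] <- "random_perturbation"
  s[mech == "grna_misalignment"] <- params$misalignment$site - 1L
  s[mech == "alt_grna"] <- params$alt_block$start_site - 1L

  # (4) junction content; when keys = FALSE the U-count matrix itself is
  # not materialized, but every content draw still happens so the RNG
  # stream is identical
  u <- NULL
  if (keys) {
    u <- matrix(rep(table$pre_U, each = depth), depth, m)
    if (any(cls == "fully_edited"))
      u[cls == "fully_edited", ] <- matrix(rep(table$full_U,
                                               each = sum(cls == "fully_edited")),
                                           ncol = m)
  }
  JL <- integer(depth)
  if (n_part) {
    if (keys) {
      # canonical prefix up to the stop site
      for (j in seq_len(m)) {
        rows <- part[s >= j]
        if (length(rows)) u[rows, j] <- table$full_U[j]
      }
    }
    jit <- which(mech == "random_perturbation")
    if (length(jit)) {
      jl <- sample(seq_along(params$jl_weights), length(jit),
                   replace = TRUE, prob = params$jl_weights)
      jl <- pmin(jl, m - s[jit])
      jl[jl < 1L] <- 1L                       # s <= m-1, so s+1 exists
      for (d in seq_len(max(jl))) {
        sel <- which(jl >= d)
        if (!length(sel)) next
        site <- s[jit[sel]] + d
        forbid1 <- if (d == 1L) table$full_U[site]
                   else rep(NA_integer_, length(sel))
        forbid2 <- ifelse(jl[sel] == d, table$pre_U[site], NA_integer_)
        v <- sample_excluding(length(sel), params$u_jitter_max,
                              forbid1, forbid2)
        if (keys) u[cbind(part[jit[sel]], site)] <- v
      }
      JL[part[jit]] <- jl
    }
    mis <- which(mech == "grna_misalignment")
    if (length(mis)) {
      if (keys)
        u[cbind(part[mis], params$misalignment$site)] <- params$misalignment$count
      JL[part[mis]] <- 1L
    }
    alt <- which(mech == "alt_grna")
    if (length(alt)) {
      bl <- as.integer(params$alt_block$block)
      if (keys)
        for (d in seq_along(bl))
          u[part[alt], params$alt_block$start_site + d - 1L] <- bl[d]
      JL[part[alt]] <- length(bl)
    }
  }

  ESS <- integer(depth)
  ESS[cls == "pre_edited"] <- pre_ess
  ESS[cls == "fully_edited"] <- m
  ESS[part] <- s
  mechanism <- rep(NA_character_, depth)
  mechanism[part] <- mech
  guide <- ifelse(mechanism %in% "alt_grna", "alt_guide", NA_character_)

  truth <- data.frame(
    read = seq_len(depth), class = cls, ESS = ESS, JL = JL,
    mechanism = mechanism, guide = guide,
    u_key = if (keys) key_of(u) else NA_character_,
    n_errors = 0L, stringsAsFactors = FALSE)
  truth
}

render_reads <- function(truth, table) {
  keys <- unique(truth$u_key)
  seqs <- vapply(strsplit(keys, ",", fixed = TRUE), function(k)
    render_sequence(table, as.integer(k), "full"), character(1))
  seqs[match(truth$u_key, keys)]
}

apply_errors <- function(reads, epsilon) {
  n <- length(reads)
  if (epsilon <= 0) return(list(reads = reads, n_errors = integer(n)))
  n_t <- nchar(reads) - nchar(gsub("T", "", reads, fixed = TRUE))
  n_nonT <- nchar(reads) - n_t
  k <- stats::rbinom(n, n_nonT, epsilon)
  n_errors <- as.integer(k)
  for (i in which(k > 0L)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    nonT <- which(ch != "T")
    posn <- if (length(nonT) == 1L) nonT else sample(nonT, k[i])
    for (p in posn) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  list(reads = reads, n_errors = n_errors)
}

#' Generate a multi-replicate synthetic read population
#'
#' Draws reads per the documented order (class, stop site, mechanism,
#' junction content, errors), each replicate from seed
#' `params$seed + replicate - 1`. The ground-truth table is consistent
#' with the emitted sequences at `epsilon = 0`: aligning and landmarking
#' the reads reproduces `class`, `ESS` and `JL` exactly.
#'
#' @param params A [simulation_params()] object.
#' @param render Emit read sequences (`TRUE`, default). With `FALSE`, only
#'   the ground-truth tables (including the per-read U-count key) are
#'   returned -- sufficient to build populations via [truth_population()]
#'   when sequence-level processing is not under study.
#' @param keys Include the per-read U-count key in the truth table
#'   (required when `render = TRUE`). `FALSE` skips the key construction
#'   -- the content draws are unchanged, so seeded draws stay aligned --
#'   for simulation studies that only consume class/ESS/JL.
#' @return A list of replicates; each has `truth` (data.frame: `read`,
#'   `class`, `ESS`, `JL`, `mechanism`, `guide`, `u_key`, `n_errors`) and
#'   `reads` (character vector, or `NULL` when `render = FALSE`).
#' @export
generate_population <- function(params, render = TRUE, keys = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (render && !keys) stop("render = TRUE requires keys = TRUE", call. = FALSE)
  lapply(seq_len(params$n_replicates), function(r) {
    truth <- generate_replicate(params, params$seed + r - 1L, keys = keys)
    reads <- NULL
    if (render) {
      reads <- render_reads(truth, params$table)
      err <- apply_errors(reads, params$epsilon)
      reads <- err$reads
      truth$n_errors <- err$n_errors
    }
    list(truth = truth, reads = reads)
  })
}

#' Build a normalized population directly from a ground-truth table
#'
#' Collapses the per-read U-count keys of a truth table, classifies and
#' landmarks them, and normalizes -- equivalent to rendering the reads and
#' running [process_reads()] at `epsilon = 0` (an equivalence the test
#' suite asserts), but skipping sequence rendering and string alignment.
#' Intended for simulation studies where the statistics downstream of
#' alignment are under study.
#'
#' @param truth A truth data.frame from [generate_population()].
#' @param table The matching `es_table`.
#' @param sample_id,scale As in [normalize_sample()].
#' @param collapse `"sequence"` (default): one entry per distinct U-count
#'   vector, as the read pipeline would produce. `"landmark"`: one entry
#'   per (class, ESS, JL) combination -- normalization, class fractions,
#'   stop-site histograms and pause statistics are identical under this
#'   coarser grouping, and it is much faster for simulation studies; the
#'   truth table need not carry U-count keys.
#' @return A `sample_population`.
#' @export
truth_population <- function(truth, table, sample_id = "sim", scale = 1e5,
                             collapse = c("sequence", "landmark")) {
  collapse <- match.arg(collapse)
  if (collapse == "landmark") {
    classes <- c("pre_edited", "partially_edited", "fully_edited")
    gid <- (match(truth$class, classes) * 1000L + truth$ESS) * 1000L +
      truth$JL
    uid <- sort(unique(gid))
    counts <- tabulate(match(gid, uid), length(uid))
    JL <- uid %% 1000L
    ESS <- (uid %/% 1000L) %% 1000L
    aligned <- data.frame(
      sequence = NA_character_, count = counts,
      orientation = "forward", u_key = NA_character_,
      eclass = classes[uid %/% 1000000L],
      ESS = ESS, JSS = ESS + 1L,
      JES = ESS + JL, JL = JL, stringsAsFactors = FALSE)
  } else {
    tab <- table(truth$u_key)
    keys <- names(tab)
    u_mat <- do.call(rbind, lapply(strsplit(keys, ",", fixed = TRUE),
                                   as.integer))
    lm <- classify_matrix(u_mat, table)
    aligned <- data.frame(sequence = keys, count = as.integer(tab),
                          orientation = "forward", u_key = keys, lm,
                          stringsAsFactors = FALSE)
    aligned <- aligned[order(-aligned$count, aligned$sequence), , drop = FALSE]
  }
  rownames(aligned) <- NULL
  normalize_sample(aligned, table, sample_id = sample_id, scale = scale)
}

#' Generate matched uninduced and induced (knockdown) sample sets
#'
#' The uninduced set follows `params`; the induced set re-weights the
#' stop-site distribution by `multiplier` at the designated sites and/or
#' replaces the class mixture, emulating depletion of an editing factor.
#' Induced replicates are drawn from seeds `params$seed + 10000 + r - 1`.
#'
#' @param params Base [simulation_params()] (defines the uninduced set).
#' @param sites Stop sites (local indices) whose weight is multiplied.
#' @param multiplier Weight multiplier at `sites` (1 = null).
#' @param class_shift Optional named vector `c(pre=, partial=, full=)`
#'   replacing the induced class mixture.
#' @param n_induced Number of induced replicates.
#' @param render,keys Passed to [generate_population()].
#' @return A list with `uninduced`, `induced` (lists of replicates) and
#'   `eps_sites` (the designated sites, empty when `multiplier == 1`).
#' @export
generate_knockdown_pair <- function(params, sites = integer(0),
                                    multiplier = 1, class_shift = NULL,
                                    n_induced = 2L, render = TRUE,
                                    keys = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  m <- params$table$n_sites
  if (any(sites < 0L | sites > m))
    stop("effect sites outside the site domain", call. = FALSE)
  ind <- params
  if (length(sites) && multiplier != 1) {
    w <- ind$stop_site_weights
    if (any(w[sites + 1L] == 0))
      stop("effect site has zero base weight", call. = FALSE)
    w[sites + 1L] <- w[sites + 1L] * multiplier
    ind$stop_site_weights <- w
  }
  if (!is.null(class_shift)) {
    ind$p_pre <- class_shift[["pre"]]
    ind$p_full <- class_shift[["full"]]
  }
  ind$seed <- params$seed + 10000L
  ind$n_replicates <- as.integer(n_induced)
  list(uninduced = generate_population(params, render = render, keys = keys),
       induced = generate_population(ind, render = render, keys = keys),
       eps_sites = if (multiplier != 1) as.integer(sites) else integer(0))
}

#' Write a replicate's reads as FASTA or FASTQ
#'
#' FASTQ output carries a constant quality (`I`); qualities are not
#' modeled.
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return The path, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0("read_", seq_along(reads))
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path)
  } else {
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}
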