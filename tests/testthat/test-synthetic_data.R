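test_that("generation is deterministic under a fixed seed", {
  ps <- simulation_params(depth = 2000, n_replicates = 2, seed = 71)
  a <- generate_population(ps)
  b <- generate_population(ps)
  expect_identical(a, b)
  ps2 <- simulation_params(depth = 2000, n_replicates = 2, seed = 72)
  c <- generate_population(ps2)
  expect_false(identical(a[[1]]$reads, c[[1]]$reads))
  # replicates differ from each other
  expect_false(identical(a[[1]]$reads, a[[2]]$reads))
})

test_that("degenerate mixtures produce pure template populations", {
  ps <- simulation_params(depth = 500, n_replicates = 1, p_pre = 0,
                          p_full = 1, epsilon = 0, seed = 5)
  sim <- generate_population(ps)
  expect_true(all(sim[[1]]$reads == ps$template$fully_edited))
  expect_true(all(sim[[1]]$truth$class == "fully_edited"))
})

test_that("class draws replicate an independent multinomial with the stated order", {
  ps <- simulation_params(depth = 5000, n_replicates = 1, seed = 83)
  sim <- generate_population(ps, render = FALSE)
  # the generator's first RNG use for replicate r (seed + r - 1) is the
  # per-read class draw
  set.seed(83)
  cls <- sample(c("pre_edited", "partially_edited", "fully_edited"), 5000,
                replace = TRUE,
                prob = c(ps$p_pre, 1 - ps$p_pre - ps$p_full, ps$p_full))
  expect_identical(sim[[1]]$truth$class, cls)
})

test_that("at epsilon zero the pipeline reproduces the ground truth", {
  ps <- simulation_params(depth = 4000, n_replicates = 1, epsilon = 0,
                          seed = 89)
  sim <- generate_population(ps)
  tab <- ps$table
  proc <- process_reads(sim[[1]]$reads, tab)
  expect_equal(unname(proc$qc["non_standard"]), 0L)
  expect_equal(unname(proc$qc["unanchored"]), 0L)
  idx <- match(sim[[1]]$reads, proc$aligned$sequence)
  expect_false(anyNA(idx))
  expect_identical(proc$aligned$eclass[idx], sim[[1]]$truth$class)
  expect_identical(proc$aligned$ESS[idx], sim[[1]]$truth$ESS)
  expect_identical(proc$aligned$JL[idx], sim[[1]]$truth$JL)
})

test_that("substitution errors surface as excluded alignments", {
  ps <- simulation_params(depth = 3000, n_replicates = 1, epsilon = 0.01,
                          seed = 97)
  sim <- generate_population(ps)
  proc <- process_reads(sim[[1]]$reads, ps$table)
  n_err_reads <- sum(sim[[1]]$truth$n_errors > 0)
  excluded <- proc$qc["non_standard"] + proc$qc["unanchored"]
  expect_equal(unname(excluded), n_err_reads)
  expect_gt(n_err_reads, 0L)
})

test_that("landmark-level population collapse matches the sequence level", {
  ps <- simulation_params(depth = 20000, n_replicates = 1, epsilon = 0,
                          seed = 101)
  sim <- generate_population(ps, render = FALSE)
  pa <- truth_population(sim[[1]]$truth, ps$table)
  pb <- truth_population(sim[[1]]$truth, ps$table, collapse = "landmark")
  expect_equal(stop_site_histogram(pa), stop_site_histogram(pb))
  expect_equal(class_fractions(pa), class_fractions(pb))
  expect_equal(sum(pa$entries$norm_count), sum(pb$entries$norm_count))
})

test_that("knockdown pairs re-weight the designated stop sites only", {
  tab <- build_site_table(demo_template())
  ps <- simulation_params(depth = 20000, n_replicates = 2, epsilon = 0,
                          junction_mix = c(no_junction = 0.6,
                                           random_perturbation = 0.4,
                                           grna_misalignment = 0,
                                           alt_grna = 0),
                          seed = 103)
  sites <- valid_stops(tab)[c(5, 12)]
  kd <- generate_knockdown_pair(ps, sites = sites, multiplier = 10,
                                n_induced = 2, render = FALSE)
  expect_equal(kd$eps_sites, sites)
  # null: multiplier 1 leaves the induced distribution at the base setting
  kd0 <- generate_knockdown_pair(ps, multiplier = 1, n_induced = 2,
                                 render = FALSE)
  expect_length(kd0$eps_sites, 0L)
  h_ind <- table(factor(kd$induced[[1]]$truth$ESS[
    kd$induced[[1]]$truth$class == "partially_edited"], levels = 0:40))
  h0 <- table(factor(kd0$induced[[1]]$truth$ESS[
    kd0$induced[[1]]$truth$class == "partially_edited"], levels = 0:40))
  ratio <- (as.numeric(h_ind[as.character(sites)]) + 1) /
    (as.numeric(h0[as.character(sites)]) + 1)
  expect_true(all(ratio > 4))

  # class shift reproduces a strong pre-edited takeover
  kds <- generate_knockdown_pair(ps, class_shift = c(pre = 0.94, full = 0.02),
                                 n_induced = 2, render = FALSE)
  fr <- class_fractions(truth_population(kds$induced[[1]]$truth, tab))
  expect_gt(fr[["pre"]], 90)
})

test_that("invalid simulation settings are rejected at construction", {
  expect_error(simulation_params(p_pre = 0.8, p_full = 0.5),
               "class probabilities")
  tab <- build_site_table(demo_template())
  w <- as.numeric(c(tab$requires_editing, FALSE))
  expect_error(simulation_params(stop_site_weights = w[-1]),
               "length n_sites")
  bad_w <- as.numeric(c(tab$requires_editing, FALSE))
  inv <- which(!tab$requires_editing[-1])[1]   # site inv+1 requires no editing
  bad_w[inv + 1] <- 1
  expect_error(simulation_params(stop_site_weights = bad_w),
               "requires no")
  expect_error(simulation_params(junction_mix = c(no_junction = 1)),
               "junction_mix")
  expect_error(simulation_params(alt_block = list(start_site = 8L,
                                                  block = c(5L, 0L))),
               "alt_block")
})
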