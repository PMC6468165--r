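test_that("top junctions average across replicates with zero fill", {
  tab <- build_site_table(demo_template())
  ess <- 8L
  u_j <- tab$pre_U; u_j[1:ess] <- tab$full_U[1:ess]; u_j[9] <- 9L
  u_other <- u_j; u_other[9] <- 7L; u_other[10] <- 2L
  filler <- tab$pre_U   # keeps totals comparable across replicates

  # same junction at 150 normalized in all five replicates
  pops <- lapply(1:5, function(i)
    mk_pop(tab, rbind(u_j, filler), c(150, 99850), id = paste0("r", i)))
  tj <- top_junctions(pops, ess = ess, min_avg = 100)
  expect_equal(nrow(tj), 1L)
  expect_equal(tj$avg_norm_count, 150)
  expect_equal(tj$share_of_ESS, 100)
  expect_equal(tj$JL, 1L)

  # present at 150 in one of five replicates: average 30, excluded at 100
  pops2 <- c(list(pops[[1]]),
             lapply(2:5, function(i)
               mk_pop(tab, rbind(u_other, filler), c(150, 99850),
                      id = paste0("r", i))))
  tj2 <- top_junctions(pops2, ess = ess, min_avg = 100)
  expect_false(paste(u_j, collapse = ",") %in% tj2$u_key)
  tj2_all <- top_junctions(pops2, ess = ess, min_avg = 0)
  expect_equal(tj2_all$avg_norm_count[tj2_all$u_key ==
                                        paste(u_j, collapse = ",")], 30)
  # shares sum to 100 with no abundance floor
  expect_equal(sum(tj2_all$share_of_ESS), 100)
})

test_that("planted junction shares match the generator ground truth", {
  tab <- build_site_table(demo_template())
  ps <- simulation_params(
    depth = 2e4, n_replicates = 3, epsilon = 0,
    junction_mix = c(no_junction = 0.5, random_perturbation = 0.3,
                     grna_misalignment = 0.2, alt_grna = 0),
    seed = 61)
  sims <- generate_population(ps, render = FALSE)
  pops <- lapply(seq_along(sims), function(i)
    truth_population(sims[[i]]$truth, tab, paste0("r", i)))
  ess <- ps$misalignment$site - 1L
  tj <- top_junctions(pops, ess = ess, min_avg = 0)
  planted <- tab$pre_U
  planted[seq_len(ess)] <- tab$full_U[seq_len(ess)]
  planted[ps$misalignment$site] <- ps$misalignment$count
  key <- paste(planted, collapse = ",")
  expect_true(key %in% tj$u_key)
  # expected share from the truth tables themselves
  shares <- vapply(sims, function(s) {
    tr <- s$truth
    at <- tr$class == "partially_edited" & tr$ESS == ess
    sum(at & tr$mechanism == "grna_misalignment") / sum(at)
  }, numeric(1))
  got <- tj$share_of_ESS[tj$u_key == key] / 100
  expect_lt(abs(got - mean(shares)), 0.02)
  expect_gt(tj$share_of_ESS[tj$u_key == key],
            max(tj$share_of_ESS[tj$u_key != key]))
})

test_that("junction lengths bin correctly and ignore replicate order", {
  tab <- build_site_table(demo_template())
  mk_jl <- function(jls, counts, id) {
    u <- do.call(rbind, lapply(jls, function(jl) {
      v <- tab$pre_U
      v[1:4] <- tab$full_U[1:4]              # ESS 4
      v[5] <- tab$full_U[5] + 1L             # junction opens at site 5
      if (jl > 1) v[4 + jl] <- tab$pre_U[4 + jl] + 2L
      v
    }))
    mk_pop(tab, u, counts, id = id)
  }
  pop_a <- mk_jl(c(1, 2, 12), c(10, 10, 20), "a")
  jd <- junction_length_distribution(list(g = list(pop_a)))
  expect_equal(jd$avg_norm_count[jd$bin == "1-2"], 50000)
  expect_equal(jd$avg_norm_count[jd$bin == "11-13"], 50000)
  expect_equal(jd$avg_norm_count[jd$bin == "0"], 0)

  pop_b <- mk_jl(c(1, 12), c(30, 10), "b")
  j1 <- junction_length_distribution(list(g = list(pop_a, pop_b)))
  j2 <- junction_length_distribution(list(g = list(pop_b, pop_a)))
  expect_equal(j1, j2)

  expect_error(junction_length_distribution(
    list(g = list(pop_a)), bins = list(a = c(0, 2), b = c(2, 5))),
    "overlapping")
})

test_that("pattern matching resolves labels and predicate types", {
  tab <- build_site_table(demo_template())
  # hybrid: nine Us at one site, canonical editing on both sides
  site <- 9L
  lab <- site_label(tab, site)
  spec <- do.call(pattern_spec, stats::setNames(
    list(9, "canonical", "canonical"),
    c(lab, site_label(tab, site - 1L), site_label(tab, site + 1L))))
  u <- tab$full_U
  u[site] <- 9L
  expect_true(match_pattern(u, spec, tab))
  expect_false(match_pattern(tab$full_U, spec, tab))
  expect_true(match_pattern(tab$full_U, pattern_spec(), tab))

  spec_pre <- do.call(pattern_spec, stats::setNames(list("pre"), lab))
  expect_true(match_pattern(tab$pre_U, spec_pre, tab))

  bad <- do.call(pattern_spec, stats::setNames(list(2), "999"))
  expect_error(match_pattern(u, bad, tab), "outside")
})
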