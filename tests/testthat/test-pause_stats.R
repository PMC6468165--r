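test_that("Tukey threshold uses interpolated quartiles", {
  H <- rep(42, 20)
  expect_equal(ips_threshold(H), 42)
  expect_false(any(H > ips_threshold(H)))

  x <- c(9, 10, 10, 11, 11, 12, 13, 100)
  thr <- ips_threshold(x)
  expect_equal(thr, oracle_tukey(x))
  expect_identical(which(x > thr), 8L)

  set.seed(3)
  y <- rpois(41, 800)
  expect_equal(ips_threshold(7 * y), 7 * ips_threshold(y))

  for (i in 1:100) {
    z <- rgamma(sample(10:60, 1), shape = 0.8, scale = 500)
    expect_equal(ips_threshold(z), oracle_tukey(z))
  }
  expect_error(ips_threshold(numeric(0)), "empty")
})

test_that("IPS consensus requires support across replicates", {
  set.seed(17)
  m <- 30
  base <- lapply(1:5, function(r) {
    h <- rpois(m + 1, 1000); names(h) <- 0:m; h
  })
  spiked <- lapply(base, function(h) { h["12"] <- h["12"] * 20; h })
  calls <- detect_ips(spiked, min_support = 4)
  expect_true(12 %in% calls$site)
  expect_equal(calls$support[calls$site == 12], 5L)
  expect_true(calls$in_all[calls$site == 12])
  expect_gt(calls$fold_over_threshold[calls$site == 12], 1)

  # spike in only 3 of 5 replicates is not reported at min_support 4
  partial_spike <- base
  for (r in 1:3) partial_spike[[r]]["12"] <- partial_spike[[r]]["12"] * 20
  calls2 <- detect_ips(partial_spike, min_support = 4)
  expect_false(12 %in% calls2$site)

  # relabeling replicates never changes the calls
  perm <- detect_ips(spiked[c(4, 1, 5, 2, 3)], min_support = 4)
  expect_equal(calls[, c("site", "support", "fold_over_threshold")],
               perm[, c("site", "support", "fold_over_threshold")])

  expect_error(detect_ips(list(base[[1]], base[[2]][-1])), "site domains")
})

test_that("EPS calls need significance, direction and consistency", {
  tab <- build_site_table(demo_template())
  m <- tab$n_sites
  set.seed(29)
  mk <- function(mult = NULL) {
    H <- numeric(m + 1)
    H[valid_stops(tab) + 1] <- rpois(length(valid_stops(tab)), 1500)
    if (!is.null(mult)) H[mult + 1] <- H[mult + 1] * 10
    mk_pop_hist(tab, H)
  }
  unind <- lapply(1:4, function(i) mk())
  # same data in both groups: no calls
  null_eps <- detect_eps(unind[1:2], unind[1:2], drop_pre = FALSE)
  expect_equal(sum(null_eps$is_eps), 0L)
  expect_true(all(null_eps$p == 1))   # identical groups: zero mean difference

  ind <- lapply(1:2, function(i) mk(mult = c(8, 21)))
  eps <- detect_eps(ind, unind, drop_pre = FALSE)
  expect_setequal(eps$site[eps$is_eps], c(8, 21))
  expect_true(all(eps$q[eps$is_eps] < 0.05))

  # direction flip in one induced replicate blocks the call
  ind_flip <- ind
  h <- stop_site_histogram(ind_flip[[2]])
  h[8 + 1] <- 0.1 * mean(vapply(unind, function(p)
    stop_site_histogram(p)[["8"]], numeric(1)))
  ind_flip[[2]] <- mk_pop_hist(tab, h)
  eps2 <- detect_eps(ind_flip, unind, drop_pre = FALSE)
  expect_false(eps2$direction_consistent[eps2$site == 8])
  expect_false(eps2$is_eps[eps2$site == 8])

  expect_error(detect_eps(ind[1], unind), "at least 2")
})

test_that("BH q-values are monotone in p-value rank", {
  tab <- build_site_table(demo_template())
  set.seed(31)
  mk <- function() {
    H <- numeric(tab$n_sites + 1)
    H[valid_stops(tab) + 1] <- rpois(length(valid_stops(tab)), 900)
    mk_pop_hist(tab, H)
  }
  eps <- detect_eps(lapply(1:2, function(i) mk()),
                    lapply(1:4, function(i) mk()), drop_pre = FALSE)
  o <- order(eps$p)
  expect_true(all(diff(eps$q[o]) >= -1e-12))
})

test_that("zero-variance sites give p = 1 when means are equal", {
  tab <- toy_table()
  H <- c(0, 500, 0, 300, 0); names(H) <- 0:4
  pops <- lapply(1:2, function(i) mk_pop_hist(tab, H))
  eps <- detect_eps(pops, pops, drop_pre = FALSE)
  expect_true(all(eps$p == 1))
  expect_equal(sum(eps$is_eps), 0L)
})

test_that("class-change tests are antisymmetric under group relabeling", {
  tab <- toy_table()
  uX <- c(2L, 0L, 0L, 0L)
  set.seed(37)
  mk <- function(pre_n) mk_pop(tab, rbind(tab$pre_U, uX, tab$full_U),
                               c(pre_n, 40 + rpois(1, 5), 20 + rpois(1, 5)))
  a <- lapply(c(200, 210), mk)
  b <- lapply(c(40, 45, 38, 42), mk)
  ab <- class_change_test(a, b)
  ba <- class_change_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_lt(ab$p[ab$class == "pre"], 0.05)
  expect_gt(ab$mean_induced[ab$class == "pre"],
            ab$mean_uninduced[ab$class == "pre"])

  same <- class_change_test(a, a)
  expect_true(all(same$p == 1))
})
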