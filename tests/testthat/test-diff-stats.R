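# statistical kernels: normalization, filters, dispersion, exact test, FDR

test_that("quantile normalization equalizes columns with the stated tie rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # constant column: its ties get the mean of all spanned quantile values
  m2 <- cbind(a = c(2, 2, 2), b = c(1, 2, 3))
  qn <- quantile_normalize(m2)
  expect_equal(unname(qn[, "a"]), rep(2, 3))
  expect_equal(unname(qn[, "b"]), c(1.5, 2, 2.5))
  # identical columns unchanged; idempotent on tie-free data (columns that
  # already share the sorted multiset re-normalize to themselves)
  m3 <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(quantile_normalize(m3), m3, ignore_attr = TRUE)
  qn1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(qn1), qn1)
  set.seed(44)
  m4 <- matrix(sample(1000, 40), ncol = 4)
  qn4 <- quantile_normalize(m4)
  expect_equal(quantile_normalize(qn4), qn4, tolerance = 1e-12)
  expect_warning(quantile_normalize(cbind(a = 1:3)), "single column")
})

test_that("position validity and gene filters apply the stated thresholds", {
  m <- rbind(c(2, 2, 0, 0), c(1, 1, 1, 1), c(5, 0, 0, 0))
  expect_equal(valid_position_mask(m), c(TRUE, FALSE, FALSE))
  counts <- c(gA = 49L, gB = 50L, gC = 0L, gD = 120L)
  expect_equal(filter_genes(counts), c("gB", "gD"))
})

test_that("TMM factors: identities and oracle agreement", {
  set.seed(5)
  base <- matrix(rpois(200, 50) + 1, ncol = 2)
  ident <- cbind(base[, 1], base[, 1])
  expect_equal(tmm_factors(ident), c(1, 1))
  scaled <- cbind(base[, 1], base[, 1] * 3)
  expect_equal(tmm_factors(scaled), c(1, 1), tolerance = 1e-9)
  # 100 positions with 10 inflated: match straight-line oracle to 1e-6
  m <- matrix(rpois(400, 40) + 1, ncol = 4)
  m[1:10, 2] <- m[1:10, 2] * 6
  expect_equal(tmm_factors(m), tmm_oracle(m), tolerance = 1e-6)
  # independent cross-check against the reference implementation
  expect_equal(tmm_factors(m), unname(edgeR::calcNormFactors(m)),
               tolerance = 1e-6)
  expect_warning(
    f <- tmm_factors(rbind(c(1, 0), c(0, 1), c(2, 0), c(0, 3), c(1, 1)),
                     lib_sizes = c(10, 10)),
    "fewer than 5")
})

test_that("direction-mixture filter drops only strict majorities beyond 2/3", {
  mk <- function(n_pos, n_neg, n_zero) {
    rows <- rbind(
      matrix(rep(c(5, 5, 8, 8), n_pos), ncol = 4, byrow = TRUE),
      matrix(rep(c(5, 5, 2, 2), n_neg), ncol = 4, byrow = TRUE),
      matrix(rep(c(5, 5, 5, 5), n_zero), ncol = 4, byrow = TRUE))
    direction_mixture_filter(rows, c("A", "A", "B", "B"), rep(1, 4))
  }
  expect_false(mk(9, 3, 0)$keep)   # 9/12 = 0.75 > 2/3
  expect_true(mk(8, 4, 0)$keep)    # 8/12 = 2/3 exactly: kept (strict >)
  expect_true(mk(6, 6, 0)$keep)
  expect_true(mk(8, 4, 10)$keep)   # zero fold changes excluded from tally
})

test_that("library equalization scales to the geometric mean size", {
  m <- rbind(c(10, 40), c(20, 80))
  eq <- equalize_libraries(m, c(100, 400))
  expect_equal(eq$common_size, 200)
  expect_equal(eq$counts, rbind(c(20, 20), c(40, 40)))
  same <- equalize_libraries(m, c(300, 300))
  expect_equal(same$counts, m)
  # columns proportional to their sizes end up with equal sums
  m2 <- cbind(1:50, (1:50) * 4)
  eq2 <- equalize_libraries(m2, c(sum(m2[, 1]), sum(m2[, 2])))
  expect_equal(sum(eq2$counts[, 1]), sum(eq2$counts[, 2]), tolerance = 1e-9)
  expect_error(equalize_libraries(m, c(0, 100)), "positive")
})

test_that("common dispersion recovers simulated truth", {
  sim_mat <- function(phi, seed) {
    sim <- simulate_count_study(n_genes = 1, n_positions = 500,
                                dispersion = phi, baseline_mean = 20,
                                frac_planted = 0, position_cv = 0,
                                libsize_cv = 0, seed = seed)
    as.matrix(tidyr::pivot_wider(
      sim$counts[, c("gene", "position", "sample", "count")],
      names_from = "sample", values_from = "count")[, c("A1", "A2", "B1", "B2")])
  }
  cond <- c("A", "A", "B", "B")
  # Poisson limit: estimate collapses toward zero
  expect_lte(estimate_common_dispersion(sim_mat(0, 101), cond), 0.01)
  # parameter recovery across seeds
  est <- vapply(1:20, function(s) {
    estimate_common_dispersion(sim_mat(0.2, s), cond)
  }, numeric(1))
  expect_true(all(est > 0.1 & est < 0.3))
  # golden-section optimum agrees with a fine grid search
  m <- sim_mat(0.2, 7)
  grid <- seq(-6, 1, by = 1e-3)
  ll <- vapply(grid, function(x) {
    sum(occudiff:::cond_ll(m, cond, 10^x))
  }, numeric(1))
  expect_equal(log10(estimate_common_dispersion(m, cond)),
               grid[which.max(ll)], tolerance = 2e-3)
})

test_that("tagwise dispersion obeys the shrinkage limits and ordering", {
  set.seed(2)
  m <- matrix(rnbinom(120 * 4, mu = 20, size = 5), ncol = 4)
  cond <- c("A", "A", "B", "B")
  phi_common <- estimate_common_dispersion(m, cond)
  huge <- estimate_tagwise_dispersion(m, cond, prior_weight = 1e9)
  expect_true(all(abs(huge - phi_common) < 1e-3))
  # zero weight: per-position maximum likelihood (grid-search oracle)
  free <- estimate_tagwise_dispersion(m, cond, prior_weight = 0)
  grid <- 10^seq(-6, 1, by = 1e-3)
  for (i in c(1, 30, 77)) {
    ll <- vapply(grid, function(p) {
      occudiff:::cond_ll(m[i, , drop = FALSE], cond, p)
    }, numeric(1))
    expect_equal(log10(free[i]), log10(grid[which.max(ll)]),
                 tolerance = 2e-3)
  }
  # intermediate weight lies between the two limits
  mid <- estimate_tagwise_dispersion(m, cond, prior_weight = 10)
  expect_true(all(mid >= pmin(free, phi_common) - 1e-6 &
                    mid <= pmax(free, phi_common) + 1e-6))
})

test_that("exact test matches its closed forms and handles edge cases", {
  # observed split at the mode: everything is as or less likely
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), 0.1), 1)
  # Poisson limit, 1v1, equal sizes: Binomial(10, 1/2) tail pair
  expect_equal(nb_exact_test(10, 0, phi = 0), 2 / 1024)
  # zero total
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.3), 1)
  # Poisson limit equals the two-sided binomial exact test
  for (sa in c(2, 7, 12)) {
    bt <- binom.test(sa, 16, 0.5)$p.value
    expect_equal(nb_exact_test(sa, 16 - sa, phi = 0), bt, tolerance = 1e-12)
  }
})

test_that("exact test equals brute-force composition enumeration", {
  # unit-scale sweep; the exhaustive sweep lives in the acceptance suite
  set.seed(31)
  for (phi in c(0, 0.05, 0.5)) {
    for (design in list(c(1, 1), c(2, 2))) {
      for (tot in c(3, 11, 17)) {
        sa <- sample(0:tot, 1)
        mine <- nb_exact_test(c(sa, rep(0, design[1] - 1)),
                              c(tot - sa, rep(0, design[2] - 1)), phi)
        oracle <- exact_test_oracle(sa, tot - sa, design[1], design[2], phi)
        expect_equal(mine, oracle, tolerance = 1e-9)
      }
    }
  }
})

test_that("empirical FDR counts, rescales and stays monotone", {
  ef <- empirical_fdr(c(0.01, 0.02, 0.5), c(0.5, 0.6, 0.7), target = 0.1)
  expect_equal(ef$fdr[1:2], c(0, 0))  # FDR(0.05) = 0/2
  expect_equal(ef$threshold, 0.02)
  # identical null: FDR near 1 everywhere
  set.seed(8)
  p <- runif(2000)
  ef2 <- empirical_fdr(p, p)
  expect_gte(min(ef2$fdr), 0.99)
  # monotone non-decreasing along sorted p-values by construction
  set.seed(9)
  p_real <- runif(500)
  ef3 <- empirical_fdr(p_real, runif(400))
  expect_true(all(diff(ef3$fdr[order(p_real)]) >= 0))
  expect_true(all(ef3$fdr >= 0 & ef3$fdr <= 1))
  expect_error(empirical_fdr(runif(5), numeric(0)), "empty null")
})
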