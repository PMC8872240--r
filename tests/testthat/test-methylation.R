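test_that("an all-C window drives the MLE to the f = 0 boundary", {
  pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE,
                             read_pos = c(0L, 3L), n_C = c(5L, 8L),
                             n_T = c(0L, 0L)), cpg_pos = 10L)
  tr <- estimate_f(pu, mk_profile(0.2), rho = 2, eps = 0.001, ncpg = 25)
  expect_identical(tr$sites$f_hat, 0)
})

test_that("single-position windows match the analytic binomial MLE", {
  # with all observations at one read position and eps = 0 the MLE has the
  # closed form clip((t - du) / (dm - du), 0, 1), t = n_T / (n_C + n_T)
  cases <- list(
    list(n_T = 3L, n_C = 7L, du = 0.1, rho = 4),    # interior: (0.3-0.1)/0.3
    list(n_T = 9L, n_C = 1L, du = 0.2, rho = 2),    # clipped at 1
    list(n_T = 1L, n_C = 40L, du = 0.15, rho = 3),  # clipped at 0
    list(n_T = 10L, n_C = 30L, du = 0.18, rho = 1.5)) # interior maximum
  for (cs in cases) {
    pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = 0L,
                               n_C = cs$n_C, n_T = cs$n_T), cpg_pos = 10L)
    tr <- estimate_f(pu, mk_profile(cs$du), rho = cs$rho, eps = 0, ncpg = 0)
    t_frac <- cs$n_T / (cs$n_C + cs$n_T)
    dm <- min(1, cs$rho * cs$du)
    analytic <- min(max((t_frac - cs$du) / (dm - cs$du), 0), 1)
    expect_lt(abs(tr$sites$f_hat - analytic), 1.1e-4)
  }
})

test_that("mixed-position windows agree with a brute-force grid oracle", {
  set.seed(99)
  for (rep in 1:40) {
    k <- sample(2:8, 1)
    ip <- sort(sample(0:25, k))
    n_T <- rpois(k, 3)
    n_C <- rpois(k, 10)
    if (sum(n_T + n_C) == 0) next
    dh <- runif(26, 0.01, 0.4)
    rho <- runif(1, 1.2, 4)
    eps <- runif(1, 0, 0.01)
    pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = ip,
                               n_C = n_C, n_T = n_T), cpg_pos = 10L)
    tr <- estimate_f(pu, mk_profile(dh), rho = rho, eps = eps, ncpg = 0)
    oracle <- brute_force_f(n_T, n_C, dh[ip + 1], rho, eps)
    expect_lt(abs(tr$sites$f_hat - oracle), 1.1e-4)
  }
})

test_that("f_hat depends only on the pooled counts, not their arrangement", {
  base <- data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = c(0L, 2L),
                     n_C = c(6L, 9L), n_T = c(4L, 2L))
  # split one cell into two rows and reorder: the sufficient statistics and
  # hence the estimate are unchanged
  split <- data.frame(site_pos = 10L, is_cpg = TRUE,
                      read_pos = c(2L, 0L, 0L),
                      n_C = c(9L, 2L, 4L), n_T = c(2L, 3L, 1L))
  prof <- mk_profile(c(0.3, 0.2, 0.1))
  f1 <- estimate_f(mk_pileup(base, 10L), prof, ncpg = 0)$sites$f_hat
  f2 <- estimate_f(mk_pileup(split, 10L), prof, ncpg = 0)$sites$f_hat
  expect_identical(f1, f2)
})

test_that("windows pool the focal CpG with its downstream neighbours only", {
  counts <- data.frame(site_pos = c(10L, 40L), is_cpg = TRUE, read_pos = 0L,
                       n_C = c(10L, 0L), n_T = c(0L, 10L))
  prof <- mk_profile(0.1)
  pu <- mk_pileup(counts, cpg_pos = c(10L, 40L))
  # focal-only estimation separates the two sites
  solo <- estimate_f(pu, prof, rho = 3, eps = 0, ncpg = 0)$sites$f_hat
  expect_equal(solo, c(0, 1), tolerance = 1e-4)
  # with a window, site 10 pools site 40 (downstream), not vice versa
  pooled <- estimate_f(pu, prof, rho = 3, eps = 0, ncpg = 1)$sites$f_hat
  expect_gt(pooled[1], 0.2)
  expect_equal(pooled[2], 1, tolerance = 1e-4)  # truncated at chromosome end
})

test_that("f_hat is missing exactly for focal CpGs without observations", {
  counts <- data.frame(site_pos = 40L, is_cpg = TRUE, read_pos = 0L,
                       n_C = 5L, n_T = 5L)
  pu <- mk_pileup(counts, cpg_pos = c(10L, 40L))
  tr <- estimate_f(pu, mk_profile(0.1), ncpg = 5)
  expect_true(is.na(tr$sites$f_hat[1]))   # no focal observation despite window
  expect_false(is.na(tr$sites$f_hat[2]))
  expect_identical(tr$sites$focal_n, c(0L, 10L))
})

test_that("a flat likelihood (rho = 1) is flagged, not resolved arbitrarily", {
  pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = 0L,
                             n_C = 7L, n_T = 3L), cpg_pos = 10L)
  expect_warning(
    tr <- estimate_f(pu, mk_profile(0.2), rho = 1, eps = 0.001, ncpg = 0),
    "identifiable")
  expect_true(tr$nonidentifiable)
  expect_true(all(is.na(tr$sites$f_hat)))
})

test_that("a degenerate zero-T-probability profile with T observations errors", {
  pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = 0L,
                             n_C = 7L, n_T = 3L), cpg_pos = 10L)
  expect_error(estimate_f(pu, mk_profile(0), rho = 2, eps = 0, ncpg = 0),
               "degenerate")
})

test_that("returned f_hat attains the grid maximum of the log-likelihood", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    ip <- sort(sample(0:25, k))
    n_T <- rpois(k, 2); n_C <- rpois(k, 8)
    if (sum(n_T + n_C) == 0) next
    dh <- runif(26, 0.05, 0.35)
    pu <- mk_pileup(data.frame(site_pos = 10L, is_cpg = TRUE, read_pos = ip,
                               n_C = n_C, n_T = n_T), cpg_pos = 10L)
    tr <- estimate_f(pu, mk_profile(dh), rho = 2.5, eps = 0.002, ncpg = 0)
    ll <- function(f) {
      du <- dh[ip + 1]; dm <- pmin(1, 2.5 * du)
      q <- f * dm + (1 - f) * du
      pT <- q + 0.002 / 3 * (1 - q)
      sum(n_T * log(pT) + n_C * log(1 - pT))
    }
    ll_hat <- ll(tr$sites$f_hat)
    grid_ll <- vapply(seq(0, 1, by = 1e-3), ll, numeric(1))
    expect_gte(ll_hat + 1e-9, max(grid_ll))
  }
})

test_that("recover_parameters_report handles exact and degenerate inputs", {
  truth <- structure(list(levels = c(0.1, 0.5, 0.9), block_len = 1L,
                          ref_name = "chrT"), class = "Methylome")
  tr <- mk_ftrack(c(10L, 40L, 70L), c(0.1, 0.5, 0.9))
  rep0 <- recover_parameters_report(tr, truth)
  expect_identical(rep0$bias, 0)
  expect_identical(rep0$rmse, 0)
  expect_identical(rep0$n_compared, 3L)
  # constant truth: correlation undefined, reported as NA rather than error
  const <- structure(list(levels = c(0.5, 0.5, 0.5), block_len = 1L,
                          ref_name = "chrT"), class = "Methylome")
  rep1 <- recover_parameters_report(tr, const)
  expect_true(is.na(rep1$pearson_r))
})
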