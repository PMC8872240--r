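test_that("downsampling at the current coverage is the identity", {
  ref <- generate_reference(20000, 200, seed = 1)
  meth <- generate_methylome(ref, seed = 2)
  rs <- simulate_reads(ref, meth, damage_model(), mean_cov = 4, seed = 3)
  ds <- downsample_reads(rs, rs$mean_cov, seed = 4)
  expect_identical(ds$reads, rs$reads)
  expect_identical(ds$mean_cov, rs$mean_cov)
})

test_that("thinning keeps a binomial share of reads and cannot up-sample", {
  ref <- mk_ref(paste(rep("ATTA", 2500), collapse = ""))  # 10 kb, no CpG
  rs <- mk_readset(rep(0L, 10000), rep("+", 10000),
                   rep(strrep("A", 30), 10000), ref)
  ds <- downsample_reads(rs, rs$mean_cov / 2, seed = 11)
  kept <- nrow(ds$reads)
  expect_gte(kept, qbinom(0.005, 10000, 0.5))
  expect_lte(kept, qbinom(0.995, 10000, 0.5))
  expect_error(downsample_reads(rs, rs$mean_cov * 2, seed = 1), "up-sample")
})

test_that("thinning is reproducible and nests the observation expansion", {
  ref <- generate_reference(30000, 300, seed = 21)
  meth <- generate_methylome(ref, seed = 22)
  rs <- simulate_reads(ref, meth, damage_model(), mean_cov = 6, seed = 23)
  d1 <- downsample_reads(rs, 2, seed = 24)
  d2 <- downsample_reads(rs, 2, seed = 24)
  expect_identical(d1, d2)
  # the pileup of the thinned ReadSet equals the row-subset of the full
  # expansion used by run_experiment's fast path
  obs <- paleometh:::.expand_observations(rs, ref)
  keep <- logical(nrow(rs$reads))
  keep[attr(d1, "kept_idx")] <- TRUE
  sub <- obs[keep[obs$read_id]]
  fast <- paleometh:::.pileup_from_obs(sub, ref)
  slow <- build_pileup(d1, ref)
  expect_identical(fast$counts, slow$counts)
})

test_that("delta_f compares only jointly defined sites and respects bounds", {
  full <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.2, 0.0, 0.8, 0.5))
  down <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.2, 1.0, NA, 0.4))
  d <- delta_f(down, full)
  expect_identical(attr(d, "n_compared"), 3L)
  expect_equal(as.numeric(d), c(0, 1, -0.1))   # bound attained at +1
  expect_true(all(d >= -1 & d <= 1))
  # identical tracks give all zeros
  z <- delta_f(full, full)
  expect_true(all(z == 0))
  # mismatched windows are refused
  other <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.2, 0, 0.8, 0.5), ncpg = 50L)
  expect_error(delta_f(other, full), "NCPG")
})

test_that("summarize_precision computes the n-1 sample SD and counts", {
  full <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.5, 0.5, 0.5, 0.5), label = 8)
  same <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.5, 0.5, 0.5, 0.5), label = 1)
  tab0 <- summarize_precision(list(same), full)
  expect_identical(tab0$sd_delta_f, 0)
  # hand-computed: sd({-0.1, 0.1}) = 0.1 * sqrt(2) = 0.1414214
  two <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.4, 0.6, NA, NA), label = 3)
  tab1 <- summarize_precision(list(two), full)
  expect_equal(tab1$sd_delta_f, 0.1414214, tolerance = 1e-6)
  expect_identical(tab1$n_compared, 2L)
  expect_identical(tab1$n_noncovered, 2L)
  # one compared site violates the precondition
  one <- mk_ftrack(c(10L, 40L, 70L, 100L), c(0.4, NA, NA, NA), label = 5)
  expect_error(summarize_precision(list(one), full), ">= 2")
})

test_that("fit_trendline recovers exact sqrt-law points and guards degeneracy", {
  lv <- c(1, 3, 5, 10, 15, 20)
  sds <- 0.5 * sqrt(1 / lv - 1 / 24) + 0.01
  fit <- fit_trendline(lv, sds, full_cov = 24)
  expect_equal(unname(fit$params["a"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$params["d"]), 0.01, tolerance = 1e-8)
  expect_gte(fit$r_squared, 0.9999)
  # constant SDs: defined R^2 = 0 with a degenerate flag, no error
  flat <- fit_trendline(lv, rep(0.1, 6), full_cov = 24)
  expect_true(flat$degenerate)
  expect_identical(flat$r_squared, 0)
  expect_error(fit_trendline(c(1, 3), c(0.3, 0.2), 24), ">= 3")
  expect_error(fit_trendline(lv, -sds, 24), "non-negative")
  expect_error(fit_trendline(c(0, 3, 5), c(0.3, 0.2, 0.1), 24), "positive")
})

test_that("alternative trendline forms fit their own generating curves", {
  lv <- c(1, 3, 5, 10, 15, 20)
  pw <- fit_trendline(lv, 0.4 * lv^(-0.5), full_cov = 24, form = "power")
  expect_equal(unname(pw$params), c(0.4, 0.5), tolerance = 1e-4)
  ex <- fit_trendline(lv, 0.3 * exp(-0.2 * lv) + 0.05, full_cov = 24,
                      form = "exponential")
  expect_equal(unname(ex$params), c(0.3, 0.2, 0.05), tolerance = 1e-4)
  expect_gte(ex$r_squared, 0.9999)
})

test_that("recommend_coverage applies the threshold rule and is monotone in factor", {
  tab <- data.frame(coverage_level = c(1, 3, 5, 10, 15, 20),
                    sd_delta_f = c(0.30, 0.20, 0.12, 0.06, 0.04, 0.03),
                    n_compared = 100L, n_noncovered = 0L)
  class(tab) <- c("PrecisionTable", "data.frame")
  rec <- recommend_coverage(tab, full_cov = 24, factor = 2)
  expect_identical(rec$ref_level, 20)
  expect_identical(rec$sd_ref, 0.03)
  expect_identical(rec$threshold, 0.06)
  expect_identical(rec$recommended_level, 10)
  # a huge factor admits the smallest level; factor 1 admits only the ref
  expect_identical(recommend_coverage(tab, 24, factor = 1e6)$recommended_level, 1)
  expect_identical(recommend_coverage(tab, 24, factor = 1)$recommended_level, 20)
  # monotonicity: larger factor never increases the recommendation
  recs <- sapply(c(1, 1.5, 2, 3, 5, 10, 100),
                 function(f) recommend_coverage(tab, 24, factor = f)$recommended_level)
  expect_true(all(diff(recs) <= 0))
})

test_that("experiment configuration validates its ranges", {
  expect_error(experiment_config(grid = numeric(0)), "empty")
  expect_error(experiment_config(grid = c(1, 4)), "subset")
  expect_error(experiment_config(full_cov = 10, grid = c(1, 3, 5, 10)),
               "below full_cov")
  expect_error(experiment_config(n_cpg = 1e6), "n_cpg")
  expect_s3_class(preset_config("SF12-like"), "ExperimentConfig")
  expect_identical(preset_config("SF12-like")$damage$delta_max, 0.15)
  expect_identical(preset_config("ans017-like")$full_cov, 24)
  expect_identical(preset_config("stuttgart-like")$full_cov, 19)
})

test_that("run_experiment is deterministic down to its written artifacts", {
  d1 <- file.path(tempdir(), "exp1")
  d2 <- file.path(tempdir(), "exp2")
  r1 <- run_experiment(small_config(seed = 5, out_dir = d1))
  r2 <- run_experiment(small_config(seed = 5, out_dir = d2))
  for (f in list.files(d1)) {
    if (grepl("tsv$|bedGraph$", f)) {
      expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                       info = f)
    }
  }
  expect_identical(r1$table, r2$table)
  # structural invariants of any seeded experiment
  expect_true(all(r1$table$sd_delta_f >= 0))
  expect_true(all(diff(r1$table$n_noncovered) <= 0))
  for (tr in r1$tracks) {
    d <- delta_f(tr, r1$track_full)
    expect_true(all(d >= -1 & d <= 1))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("nested thinning routes give statistically indistinguishable precision", {
  # 10x -> 5x (two-step) versus 30x -> 5x (one-step): both are Bernoulli
  # thinnings of the same full read set, so SD(Delta f) at 5x should not
  # depend on the route
  sd_two <- sd_one <- numeric(4)
  for (s in 1:4) {
    ref <- generate_reference(60000, 600, seed = 300 + s)
    meth <- generate_methylome(ref, seed = 400 + s)
    rs <- simulate_reads(ref, meth, damage_model(), mean_cov = 30,
                         seed = 500 + s)
    track <- function(reads, label) {
      pu <- build_pileup(reads, ref)
      prof <- estimate_damage_profile(pu)
      estimate_f(mask_mutations(pu, prof), prof, coverage_label = label)
    }
    full <- track(rs, 30)
    r10 <- downsample_reads(rs, 10, seed = 600 + s)
    two <- downsample_reads(r10, 5, seed = 700 + s)
    one <- downsample_reads(rs, 5, seed = 800 + s)
    sd_two[s] <- sd(delta_f(track(two, 5), full))
    sd_one[s] <- sd(delta_f(track(one, 5), full))
  }
  expect_gt(t.test(sd_two, sd_one)$p.value, 0.01)
})
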