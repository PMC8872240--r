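test_that("generate_reference plants exactly the requested CpGs and nothing else", {
  ref <- generate_reference(50000, 500, seed = 7)
  expect_length(ref$cpg_pos, 500)
  expect_false(is.unsorted(ref$cpg_pos, strictly = TRUE))
  # every planted position is a CpG and spacing is non-adjacent
  chars <- strsplit(ref$seq, "", fixed = TRUE)[[1]]
  expect_true(all(chars[ref$cpg_pos + 1] == "C"))
  expect_true(all(chars[ref$cpg_pos + 2] == "G"))
  expect_true(all(diff(ref$cpg_pos) >= 2))
  # the planted list is exhaustive: scanning the sequence finds no other CG
  expect_identical(paleometh:::.find_cpgs(ref$seq), ref$cpg_pos)
  expect_true(all(chars %in% c("A", "C", "G", "T")))
})

test_that("generate_reference handles the empty case and is deterministic", {
  ref0 <- generate_reference(1000, 0, seed = 1)
  expect_identical(nchar(ref0$seq), 1000L)
  expect_length(ref0$cpg_pos, 0)
  expect_length(paleometh:::.find_cpgs(ref0$seq), 0)

  a <- generate_reference(20000, 300, seed = 42)
  b <- generate_reference(20000, 300, seed = 42)
  expect_identical(a, b)
  c <- generate_reference(20000, 300, seed = 43)
  expect_false(identical(a$seq, c$seq))
})

test_that("generate_reference rejects CpG densities that cannot be placed", {
  expect_error(generate_reference(1000, 200, seed = 1), "n_cpg")
  expect_error(generate_reference(500, 10, seed = 1), "length")
})

test_that("generate_methylome respects the Beta mixture in both pure modes", {
  ref <- generate_reference(100000, 5000, seed = 3)
  # all-low mode: Beta(1, 99) has mean 0.01; the mean of 5000 site levels
  # concentrates far below 0.05
  lo <- generate_methylome(ref, p_high = 0, beta_low = c(1, 99),
                           block_len = 1, seed = 4)
  expect_length(lo$levels, 5000)
  expect_true(all(lo$levels >= 0 & lo$levels <= 1))
  expect_lt(mean(lo$levels), 0.05)
  # symmetric all-high mode
  hi <- generate_methylome(ref, p_high = 1, beta_high = c(99, 1),
                           block_len = 1, seed = 4)
  expect_gt(mean(hi$levels), 0.95)
})

test_that("generate_methylome levels are constant within blocks", {
  ref <- generate_reference(20000, 400, seed = 5)
  m <- generate_methylome(ref, block_len = 5, seed = 6)
  blocks <- split(m$levels, rep(seq_len(80), each = 5))
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1L,
                         logical(1))))
})

test_that("simulate_reads: empty and noise-free cases", {
  ref <- generate_reference(5000, 50, seed = 1)
  meth <- generate_methylome(ref, seed = 2)
  expect_identical(nrow(simulate_reads(ref, meth, damage_model(),
                                       mean_cov = 0, seed = 3)$reads), 0L)
  # with all damage and error switched off, reads copy the reference
  quiet <- damage_model(delta_max = 0, delta_bg = 0, eps = 0)
  rs <- simulate_reads(ref, meth, quiet, mean_cov = 3, seed = 3)
  expect_gt(nrow(rs$reads), 0)
  got <- substring(ref$seq, rs$reads$start + 1,
                   rs$reads$start + nchar(rs$reads$bases))
  expect_identical(rs$reads$bases, got)
  expect_true(all(nchar(rs$reads$bases) >= 20 & nchar(rs$reads$bases) <= 150))
  expect_true(all(rs$reads$start >= 0 &
                  rs$reads$start + nchar(rs$reads$bases) <= 5000))
})

test_that("terminal deamination rate is recovered at read position 0", {
  ref <- generate_reference(100000, 1000, seed = 11)
  meth <- generate_methylome(ref, seed = 12)
  meth$levels[] <- 0  # no methylation: every cytosine deaminates at delta_u
  dmg <- damage_model(delta_max = 0.3, decay = 0.5, delta_bg = 0.01, eps = 0)
  rs <- simulate_reads(ref, meth, dmg, mean_cov = 5, seed = 13)
  prof <- estimate_damage_profile(build_pileup(rs, ref))
  n <- prof$n_obs[1]
  phat <- prof$delta_hat[1]
  # 99% binomial CI around the true terminal rate 0.30
  expect_gte(phat, qbinom(0.005, n, 0.3) / n)
  expect_lte(phat, qbinom(0.995, n, 0.3) / n)
})

test_that("realized coverage concentrates around the request", {
  ref <- generate_reference(300000, 3000, seed = 21)
  meth <- generate_methylome(ref, seed = 22)
  rs <- simulate_reads(ref, meth, damage_model(), mean_cov = 5, seed = 23)
  expect_gt(rs$mean_cov / 5, 0.9)
  expect_lt(rs$mean_cov / 5, 1.1)
})

test_that("CpG cytosines carry a T excess over non-CpG cytosines", {
  ref <- generate_reference(200000, 2000, seed = 31)
  meth <- generate_methylome(ref, seed = 32)  # mean methylation well above 0
  rs <- simulate_reads(ref, meth, damage_model(), mean_cov = 8, seed = 33)
  pu <- build_pileup(rs, ref)
  term <- pu$counts[read_pos == 0,
                    .(t_frac = sum(n_T) / sum(n_C + n_T)), by = is_cpg]
  expect_gt(term[is_cpg == TRUE, t_frac], term[is_cpg == FALSE, t_frac])
})

test_that("simulation is byte-identical under a fixed seed and rejects runaway coverage", {
  ref <- generate_reference(10000, 100, seed = 41)
  meth <- generate_methylome(ref, seed = 42)
  a <- simulate_reads(ref, meth, damage_model(), mean_cov = 4, seed = 43)
  b <- simulate_reads(ref, meth, damage_model(), mean_cov = 4, seed = 43)
  expect_identical(a, b)
  expect_error(simulate_reads(ref, meth, damage_model(), mean_cov = 20000,
                              seed = 1), "runaway")
})

test_that("UDG mode excises unmethylated deamination as gaps, keeps 5mC-derived T", {
  ref <- generate_reference(100000, 1000, seed = 51)
  meth <- generate_methylome(ref, seed = 52)
  meth$levels[] <- 0
  udg <- damage_model(delta_max = 0.3, decay = 0.5, delta_bg = 0.01,
                      eps = 0, mode = "UDG")
  rs <- simulate_reads(ref, meth, udg, mean_cov = 3, seed = 53)
  expect_true(any(grepl("-", rs$reads$bases, fixed = TRUE)))
  # unmethylated molecules leave no T signal in a UDG library
  prof <- estimate_damage_profile(build_pileup(rs, ref))
  expect_identical(sum(prof$delta_hat * prof$n_obs, na.rm = TRUE), 0)
  # gaps carry no coverage
  nongap <- sum(nchar(gsub("-", "", rs$reads$bases, fixed = TRUE)))
  expect_equal(rs$mean_cov, nongap / 100000)
})
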