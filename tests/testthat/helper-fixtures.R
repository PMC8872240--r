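# Hand-construction helpers for pileups, profiles, tracks, and read sets, so
# unit tests can exercise single operations on exactly known inputs.

mk_ref <- function(seq, name = "chrT") {
  structure(list(name = name, seq = seq,
                 cpg_pos = paleometh:::.find_cpgs(seq)),
            class = "ReferenceChrom")
}

mk_readset <- function(start, strand, bases, ref) {
  nb <- nchar(gsub("-", "", bases, fixed = TRUE))
  structure(
    list(reads = data.table::data.table(start = as.integer(start),
                                        strand = strand, bases = bases),
         mean_cov = sum(nb) / nchar(ref$seq),
         ref_length = nchar(ref$seq), ref_name = ref$name),
    class = "ReadSet")
}

mk_pileup <- function(counts_df, cpg_pos, i_max = 25L, masked = integer(0)) {
  structure(
    list(counts = data.table::as.data.table(counts_df),
         i_max = as.integer(i_max), cpg_pos = as.integer(cpg_pos),
         masked_pos = as.integer(masked), ref_name = "chrT",
         ref_length = 1000L),
    class = "SitePileup")
}

mk_profile <- function(delta_hat, n_obs = 1000L, i_max = 25L) {
  out <- data.frame(read_pos = 0:i_max,
                    delta_hat = rep_len(delta_hat, i_max + 1L),
                    n_obs = rep_len(as.integer(n_obs), i_max + 1L))
  class(out) <- c("DamageProfile", "data.frame")
  out
}

mk_ftrack <- function(pos, f_hat, focal_n = NULL, ncpg = 25L, label = NA_real_) {
  if (is.null(focal_n)) focal_n <- ifelse(is.na(f_hat), 0L, 10L)
  structure(
    list(sites = data.table::data.table(pos = as.integer(pos), f_hat = f_hat,
                                        focal_n = as.integer(focal_n),
                                        n_obs = as.integer(focal_n),
                                        masked = FALSE),
         ncpg = as.integer(ncpg), coverage_label = label, ref_name = "chrT",
         mode = "non-UDG", rho = 2, eps = 0.001, nonidentifiable = FALSE),
    class = "FTrack")
}

# Independent brute-force maximizer of the windowed log-likelihood on a dense
# grid; deliberately written as a plain loop so it shares no code with
# estimate_f().
brute_force_f <- function(n_T, n_C, du, rho, eps, mode = "non-UDG",
                          step = 1e-4) {
  dm <- pmin(1, rho * du)
  fg <- seq(0, 1, by = step)
  best_ll <- -Inf
  best_f <- NA_real_
  for (f in fg) {
    if (mode == "non-UDG") {
      q <- f * dm + (1 - f) * du
      pT <- q + eps / 3 * (1 - q)
    } else {
      pT <- f * dm + eps / 3
    }
    pT <- pmin(pmax(pT, 1e-300), 1 - 1e-12)
    ll <- sum(n_T * log(pT) + n_C * log(1 - pT))
    if (ll > best_ll + 1e-12) {
      best_ll <- ll
      best_f <- f
    }
  }
  best_f
}

# A small, fast experiment configuration used by unit tests.
small_config <- function(seed = 1, ...) {
  experiment_config(ref_length = 60000, n_cpg = 600, full_cov = 8,
                    grid = c(1, 3, 5), seed = seed, label = "unit-test", ...)
}
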