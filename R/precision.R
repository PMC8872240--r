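#' Down-sample a read set to a target coverage by Bernoulli thinning
#'
#' Each read is kept independently with probability
#' `p = target_cov / mean_cov`, the per-read analogue of down-sampling an
#' alignment to a fraction of its depth. Expected coverage of the result is
#' `target_cov`; reads cannot be up-sampled.
#'
#' @param reads A `ReadSet`.
#' @param target_cov Target fold-coverage, `0 < target_cov <= mean_cov`.
#' @param seed Integer seed.
#'
#' @return A `ReadSet` with the surviving reads and recomputed realized
#'   `mean_cov`. The indices of the kept reads are available as
#'   `attr(x, "kept_idx")`.
#' @export
downsample_reads <- function(reads, target_cov, seed) {
  stopifnot(inherits(reads, "ReadSet"))
  .check_scalar(target_cov, "target_cov", lower = 0)
  if (target_cov <= 0) stop("'target_cov' must be > 0", call. = FALSE)
  if (target_cov > reads$mean_cov) {
    stop(sprintf("cannot up-sample: target %.3gx exceeds current %.3gx",
                 target_cov, reads$mean_cov), call. = FALSE)
  }
  n <- nrow(reads$reads)
  p <- target_cov / reads$mean_cov
  kept <- if (p >= 1) seq_len(n) else {
    .with_seed(seed, which(stats::runif(n) < p))
  }
  out <- reads
  out$reads <- reads$reads[kept]
  nb <- nchar(out$reads$bases)
  # Subtract UDG excision gaps if any are present (gaps carry no coverage).
  if (!isTRUE(all.equal(sum(nchar(reads$reads$bases)),
                        reads$mean_cov * reads$ref_length)) &&
      any(grepl("-", out$reads$bases, fixed = TRUE))) {
    nb <- nchar(gsub("-", "", out$reads$bases, fixed = TRUE))
  }
  out$mean_cov <- sum(nb) / reads$ref_length
  attr(out, "kept_idx") <- kept
  out
}

#' Positional methylation differences between two tracks
#'
#' Computes `Delta f_s = f_c(s) - f_full(s)` over the CpG sites at which both
#' tracks define an estimate; sites missing in either track are excluded.
#' Values lie in `[-1, 1]` by construction.
#'
#' @param track_c `FTrack` from a down-sampled read set.
#' @param track_full `FTrack` from the full read set (same reference and NCPG).
#'
#' @return Numeric vector of differences with attribute `n_compared`.
#' @export
delta_f <- function(track_c, track_full) {
  stopifnot(inherits(track_c, "FTrack"), inherits(track_full, "FTrack"))
  if (!identical(track_c$sites$pos, track_full$sites$pos)) {
    stop("tracks are not over the same CpG sites", call. = FALSE)
  }
  if (track_c$ncpg != track_full$ncpg) {
    stop("tracks were estimated with different NCPG windows", call. = FALSE)
  }
  both <- !is.na(track_c$sites$f_hat) & !is.na(track_full$sites$f_hat)
  d <- track_c$sites$f_hat[both] - track_full$sites$f_hat[both]
  attr(d, "n_compared") <- sum(both)
  d
}

#' Summarize Delta-f dispersion across a coverage grid
#'
#' For each down-sampled track, computes the sample standard deviation
#' (n-1 denominator) of `Delta f` against the full-coverage track, together
#' with the number of compared sites and the number of non-covered focal CpGs
#' (zero observations) at that level.
#'
#' @param tracks Named list of `FTrack`s, one per coverage level; each must
#'   carry its level in `coverage_label`.
#' @param track_full The full-coverage `FTrack`.
#'
#' @return A `PrecisionTable` data.frame with columns `coverage_level`,
#'   `sd_delta_f`, `n_compared`, `n_noncovered`.
#' @export
summarize_precision <- function(tracks, track_full) {
  stopifnot(is.list(tracks), length(tracks) > 0, inherits(track_full, "FTrack"))
  rows <- lapply(tracks, function(tr) {
    stopifnot(inherits(tr, "FTrack"))
    if (is.na(tr$coverage_label)) {
      stop("every track needs a numeric coverage_label", call. = FALSE)
    }
    d <- delta_f(tr, track_full)
    if (attr(d, "n_compared") < 2L) {
      stop(sprintf("level %sx has %d compared site(s); need >= 2",
                   format(tr$coverage_label), attr(d, "n_compared")),
           call. = FALSE)
    }
    if (any(d < -1 | d > 1)) {
      stop("Delta f outside [-1, 1]; estimator returned invalid levels",
           call. = FALSE)
    }
    data.frame(coverage_level = tr$coverage_label,
               sd_delta_f = .sample_sd(d),
               n_compared = attr(d, "n_compared"),
               n_noncovered = sum(tr$sites$focal_n == 0L, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$coverage_level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PrecisionTable", "data.frame")
  out
}

#' Fit a decay trendline to SD(Delta f) versus coverage
#'
#' The default `"sqrt-law"` form,
#' `SD(c) = a * sqrt(1/c - 1/full_cov) + d`, is the sampling-theory shape for
#' the dispersion of a difference between an estimate from a nested subsample
#' at coverage `c` and the full-coverage estimate: the excess variance of the
#' subsample estimator is proportional to `1/c - 1/full_cov`. Alternatives
#' `"power"` (`a * c^-b`) and `"exponential"` (`a * exp(-b c) + d`) are fitted
#' by nonlinear least squares. `r_squared` is computed on the original scale.
#'
#' @param levels Down-sampled coverage levels (all `< full_cov`, positive).
#' @param sds Corresponding SD(Delta f) values (non-negative).
#' @param full_cov Full coverage of the experiment.
#' @param form Trendline family.
#'
#' @return A `TrendFit`: list with `form`, `params`, `r_squared`, `degenerate`
#'   (TRUE when the SDs are constant so that R^2 is undefined and reported as
#'   0), `levels`, `sds`, `fitted`, `full_cov`.
#' @export
fit_trendline <- function(levels, sds, full_cov,
                          form = c("sqrt-law", "power", "exponential")) {
  form <- match.arg(form)
  if (length(levels) != length(sds)) stop("length mismatch", call. = FALSE)
  if (length(levels) < 3L) stop("need >= 3 points to fit a trendline",
                                call. = FALSE)
  if (any(levels <= 0)) stop("coverage levels must be positive", call. = FALSE)
  if (any(sds < 0)) stop("standard deviations must be non-negative",
                         call. = FALSE)
  if (form == "sqrt-law" && any(levels >= full_cov)) {
    stop("sqrt-law requires all levels below full_cov", call. = FALSE)
  }

  ss_tot <- sum((sds - mean(sds))^2)
  degenerate <- ss_tot == 0

  fitfun <- switch(
    form,
    "sqrt-law" = {
      x <- sqrt(1 / levels - 1 / full_cov)
      cf <- stats::coef(stats::lm(sds ~ x))
      a <- unname(cf[2]); d <- unname(cf[1])
      if (is.na(a) || a < 0) { a <- 0; d <- mean(sds) }
      list(params = c(a = a, d = d),
           f = function(cv) a * sqrt(1 / cv - 1 / full_cov) + d)
    },
    "power" = {
      pos <- pmax(sds, 1e-12)
      cf0 <- stats::coef(stats::lm(log(pos) ~ log(levels)))
      start <- list(a = exp(unname(cf0[1])), b = -unname(cf0[2]))
      fit <- tryCatch(
        minpack.lm::nlsLM(sds ~ a * levels^(-b), start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      p <- if (is.null(fit)) unlist(start) else stats::coef(fit)
      list(params = c(a = unname(p["a"]), b = unname(p["b"])),
           f = function(cv) p[["a"]] * cv^(-p[["b"]]))
    },
    "exponential" = {
      start <- list(a = max(sds) - min(sds) + 1e-6,
                    b = 1 / max(mean(levels), 1), d = min(sds))
      fit <- tryCatch(
        minpack.lm::nlsLM(sds ~ a * exp(-b * levels) + d, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      p <- if (is.null(fit)) unlist(start) else stats::coef(fit)
      list(params = c(a = unname(p["a"]), b = unname(p["b"]),
                      d = unname(p["d"])),
           f = function(cv) p[["a"]] * exp(-p[["b"]] * cv) + p[["d"]])
    })

  fitted <- fitfun$f(levels)
  r2 <- if (degenerate) 0 else 1 - sum((sds - fitted)^2) / ss_tot
  structure(
    list(form = form, params = fitfun$params, r_squared = r2,
         degenerate = degenerate, levels = levels, sds = sds,
         fitted = fitted, full_cov = full_cov, predict_fun = fitfun$f),
    class = "TrendFit")
}

#' @export
print.TrendFit <- function(x, ...) {
  cat(sprintf("<TrendFit> %s: %s; R^2 = %.4f%s\n", x$form,
              paste(names(x$params), signif(x$params, 4), sep = "=",
                    collapse = ", "),
              x$r_squared, if (x$degenerate) " (degenerate: constant SDs)" else ""))
  invisible(x)
}

#' @export
predict.TrendFit <- function(object, newlevels = object$levels, ...) {
  object$predict_fun(newlevels)
}

#' Recommend a minimum coverage from the Delta-f precision table
#'
#' Applies the 2x-SD threshold rule: take the SD(Delta f) at the reference
#' level (the highest down-sampled level strictly below the full coverage;
#' Delta f at the full coverage itself is identically zero), multiply it by
#' `factor`, and recommend the smallest grid level whose SD does not exceed
#' that threshold.
#'
#' @param table A `PrecisionTable`.
#' @param full_cov Full coverage of the experiment.
#' @param factor Threshold multiplier (default 2).
#'
#' @return A `CoverageRecommendation`: list with `sd_ref`, `ref_level`,
#'   `threshold`, `factor`, `recommended_level` (NA when no level qualifies),
#'   `full_cov`.
#' @export
recommend_coverage <- function(table, full_cov, factor = 2) {
  stopifnot(inherits(table, "PrecisionTable") || is.data.frame(table))
  if (nrow(table) == 0L) stop("empty precision table", call. = FALSE)
  .check_scalar(factor, "factor", lower = 0)
  tb <- table[order(table$coverage_level), , drop = FALSE]
  below <- tb$coverage_level < full_cov
  if (!any(below)) stop("no level below full_cov in the table", call. = FALSE)
  ref_level <- max(tb$coverage_level[below])
  sd_ref <- tb$sd_delta_f[tb$coverage_level == ref_level][1]
  threshold <- factor * sd_ref
  ok <- tb$coverage_level[tb$sd_delta_f <= threshold]
  structure(
    list(sd_ref = sd_ref, ref_level = ref_level, threshold = threshold,
         factor = factor,
         recommended_level = if (length(ok)) min(ok) else NA_real_,
         full_cov = full_cov),
    class = "CoverageRecommendation")
}

#' @export
print.CoverageRecommendation <- function(x, ...) {
  cat(sprintf(
    "<CoverageRecommendation> threshold %.4g (= %g x SD %.4g at %gx); recommended: %s\n",
    x$threshold, x$factor, x$sd_ref, x$ref_level,
    if (is.na(x$recommended_level)) "none"
    else paste0(format(x$recommended_level), "x")))
  invisible(x)
}

#' Run the full coverage down-sampling experiment
#'
#' End-to-end seeded orchestration: generate a reference chromosome and
#' bimodal methylome, simulate a full-coverage damaged read set, estimate the
#' methylation track at full coverage and at every down-sampled grid level
#' (each level: Bernoulli thinning, pileup, empirical damage profile, variant
#' masking, windowed ML estimation), then summarize SD(Delta f) per level, fit
#' the trendline, and apply the threshold rule.
#'
#' @param config An `ExperimentConfig` from [experiment_config()] or
#'   [preset_config()].
#'
#' @return An `ExperimentResult`: list with `table` (`PrecisionTable`),
#'   `trend` (`TrendFit`), `recommendation` (`CoverageRecommendation`),
#'   `tracks` (list of per-level `FTrack`s), `track_full`, `profile_full`
#'   (full-coverage `DamageProfile`), `ref`, `methylome`, and `config`. When
#'   `config$out_dir` is set, all tables and tracks are also written there.
#' @export
run_experiment <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  dmg <- config$damage

  ref <- generate_reference(config$ref_length, config$n_cpg,
                            seed = .sub_seed(seed, 1L), name = config$ref_name)
  meth <- generate_methylome(ref, p_high = config$p_high,
                             beta_high = config$beta_high,
                             beta_low = config$beta_low,
                             block_len = config$block_len,
                             seed = .sub_seed(seed, 2L))
  reads_full <- simulate_reads(ref, meth, dmg, config$full_cov,
                               fraglen_logmu = config$fraglen_logmu,
                               fraglen_logsigma = config$fraglen_logsigma,
                               seed = .sub_seed(seed, 3L))

  # Expand the full read set once; every down-sampled pileup is a row subset
  # (identical to build_pileup() on the thinned ReadSet, asserted in tests).
  obs_full <- .expand_observations(reads_full, ref, I_MAX)

  track_of <- function(obs, label) {
    pu <- .pileup_from_obs(obs, ref, I_MAX)
    prof <- estimate_damage_profile(pu)
    pu <- mask_mutations(pu, prof,
                         interior_start = config$mask_interior_start,
                         t_frac_threshold = config$mask_t_frac,
                         min_support = config$mask_min_support)
    list(track = estimate_f(pu, prof, rho = config$est_rho,
                            eps = config$est_eps, ncpg = config$ncpg,
                            mode = dmg$mode, coverage_label = label),
         profile = prof)
  }

  full <- track_of(obs_full, config$full_cov)
  # Thin each level out of the next-higher one (composed Bernoulli thinning):
  # the marginal coverage of every level is unchanged, but the levels are
  # nested, as in successive down-sampling of one alignment, so non-covered
  # CpG counts are monotone within one experiment.
  tracks <- list()
  cur <- reads_full
  cur_idx <- seq_len(nrow(reads_full$reads))
  for (k in rev(seq_along(config$grid))) {
    lev <- config$grid[k]
    ds <- downsample_reads(cur, lev, seed = .sub_seed(seed, 100L + k))
    cur_idx <- cur_idx[attr(ds, "kept_idx")]
    cur <- ds
    keep_read <- logical(nrow(reads_full$reads))
    keep_read[cur_idx] <- TRUE
    obs_lev <- obs_full[keep_read[obs_full$read_id]]
    tracks[[paste0(lev, "x")]] <- track_of(obs_lev, lev)$track
  }
  tracks <- rev(tracks)

  table <- summarize_precision(tracks, full$track)
  trend <- fit_trendline(table$coverage_level, table$sd_delta_f,
                         full_cov = config$full_cov, form = config$trend_form)
  rec <- recommend_coverage(table, full_cov = config$full_cov,
                            factor = config$threshold_factor)

  result <- structure(
    list(table = table, trend = trend, recommendation = rec,
         tracks = tracks, track_full = full$track,
         profile_full = full$profile, ref = ref, methylome = meth,
         config = config),
    class = "ExperimentResult")

  if (!is.null(config$out_dir)) write_experiment(result, config$out_dir)
  result
}

#' @export
print.ExperimentResult <- function(x, ...) {
  cat(sprintf("<ExperimentResult> %s: full %gx, grid {%s}, NCPG=%d, seed=%d\n",
              x$config$label, x$config$full_cov,
              paste(x$config$grid, collapse = ","), x$config$ncpg,
              x$config$seed))
  print(x$table)
  print(x$trend)
  print(x$recommendation)
  invisible(x)
}
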