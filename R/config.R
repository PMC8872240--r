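#' Build a validated configuration for the down-sampling experiment
#'
#' Collects every simulator, estimator, and precision-analysis parameter in
#' one validated object. Defaults define the package's reference study
#' conditions: a 0.5-Mb chromosome with 5,000 planted CpGs (a scaled-down
#' stand-in for a real chromosome), a bimodal methylome, non-UDG terminal
#' deamination with 30% terminal rate, NCPG = 25 estimation windows, and the
#' canonical down-sampling grid.
#'
#' @param ref_length Reference length in bases.
#' @param n_cpg Number of planted CpG sites.
#' @param full_cov Full mean fold-coverage of the simulated sample.
#' @param grid Down-sampling coverage grid; must be a subset of
#'   `{1,3,5,10,15,20,25,30}` with every level strictly below `full_cov`.
#' @param ncpg NCPG window parameter (downstream CpGs pooled per focal site).
#' @param damage A `DamageModel` (see [damage_model()]).
#' @param p_high,beta_high,beta_low,block_len Methylome generator parameters
#'   (see [generate_methylome()]).
#' @param fraglen_logmu,fraglen_logsigma Fragment-length distribution.
#' @param est_rho,est_eps Estimator-side assumed delta_m/delta_u ratio and
#'   sequencing error rate.
#' @param mask_interior_start,mask_t_frac,mask_min_support Variant-masking
#'   parameters (see [mask_mutations()]).
#' @param trend_form Trendline family for [fit_trendline()].
#' @param threshold_factor Multiplier of the reference SD in
#'   [recommend_coverage()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @param ref_name Reference/chromosome name.
#' @param label Free-text label for reports.
#' @param out_dir Optional directory; when set, [run_experiment()] writes all
#'   artifacts there.
#'
#' @return An `ExperimentConfig` list.
#' @export
experiment_config <- function(ref_length = 5e5, n_cpg = 5000, full_cov = 24,
                              grid = c(1, 3, 5, 10, 15, 20), ncpg = 25,
                              damage = damage_model(),
                              p_high = 0.75, beta_high = c(8, 2),
                              beta_low = c(1, 9), block_len = 50,
                              fraglen_logmu = log(55), fraglen_logsigma = 0.35,
                              est_rho = 2.0, est_eps = 0.001,
                              mask_interior_start = 10, mask_t_frac = 0.9,
                              mask_min_support = 5,
                              trend_form = "sqrt-law", threshold_factor = 2,
                              seed = 1, ref_name = "chrS",
                              label = "custom", out_dir = NULL) {
  cfg <- structure(
    list(ref_length = ref_length, n_cpg = n_cpg, full_cov = full_cov,
         grid = grid, ncpg = ncpg, damage = damage,
         p_high = p_high, beta_high = beta_high, beta_low = beta_low,
         block_len = block_len, fraglen_logmu = fraglen_logmu,
         fraglen_logsigma = fraglen_logsigma,
         est_rho = est_rho, est_eps = est_eps,
         mask_interior_start = mask_interior_start,
         mask_t_frac = mask_t_frac, mask_min_support = mask_min_support,
         trend_form = trend_form, threshold_factor = threshold_factor,
         seed = as.integer(seed), ref_name = ref_name, label = label,
         out_dir = out_dir),
    class = "ExperimentConfig")
  validate_config(cfg)
}

#' Validate an experiment configuration
#'
#' Checks every range constraint of the pipeline's stages before any stage
#' runs, so a bad configuration fails fast rather than mid-experiment.
#'
#' @param config An `ExperimentConfig`.
#' @return The validated configuration (invisibly usable in a pipe).
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  .check_scalar(config$ref_length, "ref_length", lower = 1000)
  .check_scalar(config$n_cpg, "n_cpg", lower = 0,
                upper = config$ref_length / 10)
  .check_scalar(config$full_cov, "full_cov", lower = 0, upper = 10000)
  if (length(config$grid) == 0L) {
    stop("empty down-sampling grid", call. = FALSE)
  }
  allowed <- c(1, 3, 5, 10, 15, 20, 25, 30)
  if (!all(config$grid %in% allowed)) {
    stop("grid levels must be a subset of {", paste(allowed, collapse = ","),
         "}", call. = FALSE)
  }
  if (any(config$grid >= config$full_cov)) {
    stop("all grid levels must be strictly below full_cov", call. = FALSE)
  }
  if (is.unsorted(config$grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  .check_scalar(config$ncpg, "ncpg", lower = 0)
  stopifnot(inherits(config$damage, "DamageModel"))
  .check_scalar(config$p_high, "p_high", 0, 1)
  if (any(c(config$beta_high, config$beta_low) <= 0)) {
    stop("Beta shape parameters must be > 0", call. = FALSE)
  }
  .check_scalar(config$block_len, "block_len", lower = 1)
  .check_scalar(config$est_rho, "est_rho", lower = 1)
  .check_scalar(config$est_eps, "est_eps", 0, 0.25)
  .check_scalar(config$mask_interior_start, "mask_interior_start",
                lower = 1, upper = I_MAX)
  .check_scalar(config$mask_t_frac, "mask_t_frac", 0.5, 1)
  .check_scalar(config$mask_min_support, "mask_min_support", lower = 1)
  config$trend_form <- match.arg(config$trend_form,
                                 c("sqrt-law", "power", "exponential"))
  .check_scalar(config$threshold_factor, "threshold_factor", lower = 0)
  .check_scalar(config$seed, "seed", lower = -2^31, upper = 2^31 - 1)
  config
}

#' Preset experiment configurations mirroring three ancient genomes
#'
#' Three ready-made configurations emulate the coverage and preservation
#' regimes of typical ancient samples:
#' \describe{
#'   \item{`"ans017-like"`}{full coverage 24x, terminal deamination 0.30 —
#'     a typically preserved sample; grid `{1,3,5,10,15,20}`.}
#'   \item{`"SF12-like"`}{full coverage 38x, terminal deamination 0.15 —
#'     an exceptionally well-preserved (weakly deaminated) sample; grid
#'     `{1,3,5,10,15,20,25,30}`.}
#'   \item{`"stuttgart-like"`}{full coverage 19x, terminal deamination 0.30;
#'     grid `{1,3,5,10,15}` (capped below the sample's own coverage).}
#' }
#'
#' @param preset Preset name.
#' @param seed Master seed.
#' @param ... Further overrides passed to [experiment_config()].
#' @return An `ExperimentConfig`.
#' @export
preset_config <- function(preset = c("ans017-like", "SF12-like",
                                     "stuttgart-like"),
                          seed = 1, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "ans017-like" = list(full_cov = 24, grid = c(1, 3, 5, 10, 15, 20),
                         damage = damage_model(delta_max = 0.30)),
    "SF12-like" = list(full_cov = 38, grid = c(1, 3, 5, 10, 15, 20, 25, 30),
                       damage = damage_model(delta_max = 0.15)),
    "stuttgart-like" = list(full_cov = 19, grid = c(1, 3, 5, 10, 15),
                            damage = damage_model(delta_max = 0.30)))
  args <- utils::modifyList(c(base, list(seed = seed, label = preset)),
                            list(...))
  do.call(experiment_config, args)
}
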