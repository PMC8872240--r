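#' Estimate per-CpG methylation by windowed binomial maximum likelihood
#'
#' For each focal CpG `s`, pools the C/T observations of `s` and its `ncpg`
#' downstream CpG neighbours (window truncated at the chromosome end) and
#' maximizes over the methylation level `f` in `[0, 1]` the binomial
#' log-likelihood of the pooled counts. The per-read-position probability of
#' observing T at a CpG cytosine is, in a non-UDG library,
#'
#'   `p_T(f, i) = q + (eps/3) * (1 - q)` with
#'   `q = f * delta_m(i) + (1 - f) * delta_u(i)`,
#'
#' and in a UDG library (where unmethylated deamination events are excised and
#' never observed) `p_T(f, i) = f * delta_m(i) + eps/3`. Here
#' `delta_u(i)` is taken from the empirical damage profile and
#' `delta_m(i) = min(1, rho * delta_u(i))`. Observing C contributes the
#' complement within the C/T universe. The maximizer is located on a dense
#' grid (step 1e-3) and refined by golden-section search to 1e-6; the
#' log-likelihood is concave in `f`, and ties resolve to the smallest
#' maximizing value.
#'
#' `f_hat` is missing exactly when the focal CpG itself has zero usable
#' observations; variant-masked sites are reported with `masked = TRUE` and
#' missing `f_hat`. When `delta_m(i) = delta_u(i)` at every informative
#' position (e.g. `rho = 1` in a non-UDG library) the likelihood is flat in
#' `f`: the track is returned with all `f_hat` missing, a
#' `nonidentifiable = TRUE` flag, and a warning, rather than an arbitrary
#' interior value.
#'
#' @param pileup A `SitePileup`, normally after [mask_mutations()].
#' @param profile A `DamageProfile` for the same reads.
#' @param rho Assumed ratio `delta_m / delta_u` (>= 1). A fixed configuration
#'   constant, not estimated; see the package vignette for sensitivity notes.
#' @param eps Assumed per-base sequencing error rate.
#' @param ncpg Number of downstream CpGs pooled into each window (the NCPG
#'   parameter; 25 and 50 are the conventional choices).
#' @param mode Library mode, `"non-UDG"` or `"UDG"`.
#' @param coverage_label Optional fold-coverage label stored in the track.
#'
#' @return An `FTrack`: list with `sites` (data.table `pos`, `f_hat`,
#'   `focal_n`, `n_obs`, `masked`), `ncpg`, `coverage_label`, `ref_name`,
#'   `mode`, `rho`, `eps`, `nonidentifiable`.
#' @export
estimate_f <- function(pileup, profile, rho = 2.0, eps = 0.001, ncpg = 25,
                       mode = c("non-UDG", "UDG"), coverage_label = NA_real_) {
  stopifnot(inherits(pileup, "SitePileup"), inherits(profile, "DamageProfile"))
  mode <- match.arg(mode)
  .check_scalar(rho, "rho", lower = 1)
  .check_scalar(eps, "eps", 0, 0.25)
  .check_scalar(ncpg, "ncpg", lower = 0)
  ncpg <- as.integer(ncpg)

  cpg_pos <- pileup$cpg_pos
  n <- length(cpg_pos)
  k <- pileup$i_max + 1L

  mk_track <- function(f_hat, focal_n, n_obs, masked, nonid = FALSE) {
    structure(
      list(sites = data.table::data.table(pos = cpg_pos, f_hat = f_hat,
                                          focal_n = focal_n, n_obs = n_obs,
                                          masked = masked),
           ncpg = ncpg, coverage_label = coverage_label,
           ref_name = pileup$ref_name, mode = mode, rho = rho, eps = eps,
           nonidentifiable = nonid),
      class = "FTrack")
  }
  if (n == 0L) {
    return(mk_track(numeric(0), integer(0), integer(0), logical(0)))
  }

  # Dense per-site count matrices [site x read_pos]; duplicate cells (legal in
  # externally built pileups) are pooled.
  is_cpg <- site_pos <- read_pos <- n_C <- n_T <- NULL
  cc <- pileup$counts[is_cpg == TRUE,
                      list(n_C = sum(n_C), n_T = sum(n_T)),
                      by = list(site_pos, read_pos)]
  NC <- matrix(0, n, k)
  NT <- matrix(0, n, k)
  if (nrow(cc) > 0L) {
    ri <- match(cc$site_pos, cpg_pos)
    if (anyNA(ri)) stop("pileup contains CpG sites unknown to the reference",
                        call. = FALSE)
    NC[cbind(ri, cc$read_pos + 1L)] <- cc$n_C
    NT[cbind(ri, cc$read_pos + 1L)] <- cc$n_T
  }
  masked <- cpg_pos %in% pileup$masked_pos
  focal_n <- as.integer(rowSums(NC + NT))
  focal_n[masked] <- NA_integer_

  # Window pooling (focal + ncpg downstream CpGs) via column-wise cumsums.
  csC <- rbind(0, apply(NC, 2L, cumsum))
  csT <- rbind(0, apply(NT, 2L, cumsum))
  hi <- pmin(seq_len(n) + ncpg, n)
  WNC <- csC[hi + 1L, , drop = FALSE] - csC[seq_len(n), , drop = FALSE]
  WNT <- csT[hi + 1L, , drop = FALSE] - csT[seq_len(n), , drop = FALSE]

  used <- which(colSums(WNC + WNT) > 0)
  if (length(used) == 0L) {
    return(mk_track(NA_real_, focal_n, as.integer(rowSums(WNC + WNT)), masked))
  }
  du <- profile$delta_hat[match(used - 1L, profile$read_pos)]
  if (anyNA(du)) {
    stop("damage profile undefined at read position(s) ",
         paste(used[is.na(du)] - 1L, collapse = ", "),
         " which carry CpG observations", call. = FALSE)
  }
  dm <- pmin(1, rho * du)

  # p_T(f, i) = A_i + B_i * f.
  if (mode == "non-UDG") {
    A <- du + eps / 3 * (1 - du)
    B <- (dm - du) * (1 - eps / 3)
  } else {
    A <- rep(eps / 3, length(used))
    B <- dm
  }

  # Degenerate profile: zero T-probability at a position that has T counts.
  dead <- A == 0 & B == 0
  if (any(dead)) {
    if (any(colSums(WNT[, dead, drop = FALSE]) > 0)) {
      stop("degenerate damage profile: the model assigns zero T-probability ",
           "at read position(s) with T observations", call. = FALSE)
    }
    keep <- !dead        # all-C contributions at p_T = 0 are log(1) = 0
    used <- used[keep]; A <- A[keep]; B <- B[keep]
    if (length(used) == 0L) {
      return(mk_track(NA_real_, focal_n, as.integer(rowSums(WNC + WNT)),
                      masked))
    }
  }

  # Flat likelihood: f enters only through B.
  if (all(B == 0)) {
    warning("methylation level is not identifiable: delta_m equals delta_u ",
            "at every informative read position (rho = 1?)", call. = FALSE)
    return(mk_track(NA_real_, focal_n, as.integer(rowSums(WNC + WNT)),
                    masked, nonid = TRUE))
  }

  WNCu <- WNC[, used, drop = FALSE]
  WNTu <- WNT[, used, drop = FALSE]
  n_obs <- as.integer(rowSums(WNC + WNT))

  clamp <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-12)
  loglik_at <- function(f) {
    # f: one value per site; returns per-site log-likelihood.
    PT <- clamp(f %o% B + matrix(A, n, length(used), byrow = TRUE))
    rowSums(WNTu * log(PT) + WNCu * log1p(-PT))
  }

  # Dense grid, step 1e-3.
  fg <- seq(0, 1, by = 1e-3)
  PTg <- clamp(outer(B, fg) + A)                     # [pos x grid]
  LL <- WNTu %*% log(PTg) + WNCu %*% log1p(-PTg)     # [site x grid]
  jmax <- max.col(LL, ties.method = "first")         # smallest maximizing f
  f0 <- fg[jmax]

  # Golden-section refinement to 1e-6 inside the bracketing grid cells; the
  # log-likelihood is concave (sum of logs of affine functions of f).
  gr <- (sqrt(5) - 1) / 2
  a_v <- pmax(f0 - 1e-3, 0)
  b_v <- pmin(f0 + 1e-3, 1)
  while (length(a_v) > 0 && max(b_v - a_v) > 1e-6) {
    x1 <- b_v - gr * (b_v - a_v)
    x2 <- a_v + gr * (b_v - a_v)
    l1 <- loglik_at(x1)
    l2 <- loglik_at(x2)
    up <- l1 < l2          # strict: ties shrink from the right (smaller f)
    a_v[up] <- x1[up]
    b_v[!up] <- x2[!up]
  }
  f_ref <- (a_v + b_v) / 2
  # Keep whichever of {grid argmax, refined} has higher likelihood; prefer the
  # smaller f on ties so flat stretches resolve deterministically.
  better <- loglik_at(f_ref) > loglik_at(f0) + 1e-12
  f_hat <- ifelse(better, f_ref, f0)

  f_hat[focal_n == 0L | is.na(focal_n)] <- NA_real_
  mk_track(f_hat, focal_n, n_obs, masked)
}

#' @export
print.FTrack <- function(x, ...) {
  cat(sprintf(
    "<FTrack> %s: %d CpGs (%d with f, %d non-covered, %d masked), NCPG=%d, coverage %s\n",
    x$ref_name, nrow(x$sites), sum(!is.na(x$sites$f_hat)),
    sum(x$sites$focal_n == 0L, na.rm = TRUE), sum(x$sites$masked),
    x$ncpg, ifelse(is.na(x$coverage_label), "?",
                   paste0(format(x$coverage_label), "x"))))
  invisible(x)
}

#' Compare an estimated methylation track against the simulated truth
#'
#' @param f_track An `FTrack` estimated from simulated reads.
#' @param truth The `Methylome` the reads were simulated from.
#'
#' @return A list with `bias` (mean of f_hat - m), `rmse`, `pearson_r` (NA when
#'   either vector is constant), and `n_compared` (non-missing focal CpGs).
#' @export
recover_parameters_report <- function(f_track, truth) {
  stopifnot(inherits(f_track, "FTrack"), inherits(truth, "Methylome"))
  if (nrow(f_track$sites) != length(truth$levels)) {
    stop("track and methylome are not over the same reference", call. = FALSE)
  }
  ok <- !is.na(f_track$sites$f_hat)
  f <- f_track$sites$f_hat[ok]
  m <- truth$levels[ok]
  n <- length(f)
  r <- NA_real_
  if (n >= 2 && stats::sd(f) > 0 && stats::sd(m) > 0) {
    r <- stats::cor(f, m)
  }
  structure(
    list(bias = if (n > 0) mean(f - m) else NA_real_,
         rmse = if (n > 0) sqrt(mean((f - m)^2)) else NA_real_,
         pearson_r = r, n_compared = n),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery> n=%d  bias=%+.4f  RMSE=%.4f  r=%s\n",
    x$n_compared, x$bias, x$rmse,
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r))))
  invisible(x)
}
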