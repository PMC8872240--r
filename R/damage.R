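#' @import data.table
NULL

# Expand a ReadSet into one row per usable cytosine observation.
#
# A base informs cytosine deamination only when it sits over a cytosine on the
# read's own strand: forward reads over a reference C, reverse reads over a
# reference G. Reverse-strand observations are complemented into the read
# frame, and G observations over the G of a CpG are folded into the CpG site
# keyed by the position of its C. Observed bases other than C/T (in read
# frame) and gaps are discarded. Returns a data.table with columns
# read_id, site_pos (0-based forward-frame key), is_cpg, read_pos (distance to
# the read's own 5' end, capped at i_max), is_T.
.expand_observations <- function(reads, ref, i_max = I_MAX) {
  tbl <- reads$reads
  if (nrow(tbl) == 0L) {
    return(data.table::data.table(read_id = integer(0), site_pos = integer(0),
                                  is_cpg = logical(0), read_pos = integer(0),
                                  is_T = logical(0)))
  }
  L <- nchar(ref$seq)
  lens <- nchar(tbl$bases)
  rid <- rep.int(seq_len(nrow(tbl)), lens)
  pos1 <- sequence(lens, from = tbl$start + 1L)
  if (any(pos1 < 1L) || any(pos1 > L)) {
    stop("reads fall outside the reference bounds", call. = FALSE)
  }
  ioff <- sequence(lens, from = 0L)
  plus <- tbl$strand[rid] == "+"
  i <- ioff
  i[!plus] <- lens[rid[!plus]] - 1L - ioff[!plus]

  obs_code <- .seq_to_int(paste0(tbl$bases, collapse = ""))
  refcode <- .seq_to_int(ref$seq)[pos1]

  cand <- (plus & refcode == .CODE_C) | (!plus & refcode == .CODE_G)
  w <- which(cand)
  if (length(w) == 0L) {
    return(data.table::data.table(read_id = integer(0), site_pos = integer(0),
                                  is_cpg = logical(0), read_pos = integer(0),
                                  is_T = logical(0)))
  }
  oc <- obs_code[w]
  wp <- plus[w]
  # Read-frame observation: complement reverse-strand bases.
  oc[!wp] <- .complement_int(oc[!wp])
  keep <- oc == .CODE_C | oc == .CODE_T

  cpg_idx <- integer(L)
  if (length(ref$cpg_pos) > 0) cpg_idx[ref$cpg_pos + 1L] <- seq_along(ref$cpg_pos)

  p1 <- pos1[w]
  site_pos <- p1 - 1L                       # default: the site itself, 0-based
  is_cpg <- logical(length(w))
  is_cpg[wp] <- cpg_idx[p1[wp]] > 0L
  # Reverse-strand C sites live on reference G positions; the G of a CpG is
  # folded into the CpG keyed at its C (one position left).
  prev <- p1[!wp] - 1L
  prev_cpg <- cpg_idx[pmax(prev, 1L)] > 0L & prev >= 1L
  is_cpg[!wp] <- prev_cpg
  sp_m <- site_pos[!wp]
  sp_m[prev_cpg] <- sp_m[prev_cpg] - 1L
  site_pos[!wp] <- sp_m

  data.table::data.table(
    read_id = rid[w][keep],
    site_pos = site_pos[keep],
    is_cpg = is_cpg[keep],
    read_pos = pmin(i[w][keep], as.integer(i_max)),
    is_T = (oc == .CODE_T)[keep]
  )
}

# Aggregate an observation table into a SitePileup.
.pileup_from_obs <- function(obs, ref, i_max = I_MAX) {
  n_C <- n_T <- is_T <- site_pos <- is_cpg <- read_pos <- NULL # R CMD check
  counts <- obs[, list(n_C = sum(!is_T), n_T = sum(is_T)),
                by = list(site_pos, is_cpg, read_pos)]
  data.table::setorder(counts, site_pos, read_pos)
  structure(
    list(counts = counts, i_max = as.integer(i_max),
         cpg_pos = ref$cpg_pos, masked_pos = integer(0),
         ref_name = ref$name, ref_length = nchar(ref$seq)),
    class = "SitePileup"
  )
}

#' Build a per-site pileup of cytosine observations
#'
#' Tabulates, for every cytosine site on either strand, how many C and how many
#' T observations it received at each read position `i` (distance from the
#' observing read's own 5' end, capped at `i_max`). Reverse-strand sites
#' (reference G positions) are folded in as complemented observations, and the
#' two strands of a CpG are pooled under the position of the C. Non-C/T bases
#' over cytosine sites are discarded as sequencing error.
#'
#' @param reads A `ReadSet`.
#' @param ref The `ReferenceChrom` the reads were simulated from.
#' @param i_max Read-position cap for the damage stratification.
#'
#' @return A `SitePileup`: list with `counts` (data.table `site_pos`, `is_cpg`,
#'   `read_pos`, `n_C`, `n_T`), `i_max`, `cpg_pos`, `masked_pos`, `ref_name`,
#'   `ref_length`.
#' @export
build_pileup <- function(reads, ref, i_max = I_MAX) {
  stopifnot(inherits(reads, "ReadSet"), inherits(ref, "ReferenceChrom"))
  .pileup_from_obs(.expand_observations(reads, ref, i_max), ref, i_max)
}

#' @export
print.SitePileup <- function(x, ...) {
  cat(sprintf(
    "<SitePileup> %s: %d site/read-position cells, %d CpG sites (%d masked), i_max=%d\n",
    x$ref_name, nrow(x$counts), length(x$cpg_pos), length(x$masked_pos), x$i_max))
  invisible(x)
}

#' Estimate the unmethylated deamination profile from non-CpG cytosines
#'
#' Vertebrate methylation outside the CpG context is negligible, so non-CpG
#' cytosines can be treated as fully unmethylated and their pooled T fraction
#' at each read position estimates the unmethylated deamination rate
#' `delta_u(i) = n_T(i) / (n_C(i) + n_T(i))`. Positions with no supporting
#' observations are reported as missing.
#'
#' @param pileup A `SitePileup` with non-CpG cytosine observations.
#'
#' @return A `DamageProfile`: data.frame with `read_pos` (0..i_max),
#'   `delta_hat` (NA where unsupported), and `n_obs`.
#' @export
estimate_damage_profile <- function(pileup) {
  stopifnot(inherits(pileup, "SitePileup"))
  is_cpg <- read_pos <- n_C <- n_T <- NULL
  nc <- pileup$counts[is_cpg == FALSE,
                      list(n_C = sum(n_C), n_T = sum(n_T)), by = read_pos]
  out <- data.frame(read_pos = 0:pileup$i_max,
                    delta_hat = NA_real_, n_obs = 0L)
  if (nrow(nc) > 0L) {
    j <- match(nc$read_pos, out$read_pos)
    out$n_obs[j] <- nc$n_C + nc$n_T
    out$delta_hat[j] <- nc$n_T / (nc$n_C + nc$n_T)
  }
  if (all(out$n_obs == 0L)) {
    stop("no non-CpG cytosine observations at any read position; ",
         "cannot estimate the deamination profile", call. = FALSE)
  }
  class(out) <- c("DamageProfile", "data.frame")
  out
}

#' Mask CpG sites carrying C>T (or A>G) genotype variants
#'
#' A fixed C>T substitution at a CpG looks like complete deamination and would
#' masquerade as full methylation. Because true deamination is concentrated at
#' fragment termini, interior read positions (`i >= interior_start`) carry
#' almost none of it: a CpG whose interior observations are nearly all T is a
#' genotype variant, not methylation, and is removed from the pileup entirely.
#' Sites with fewer than `min_support` interior observations are retained (no
#' evidence either way).
#'
#' @param pileup A `SitePileup`.
#' @param profile The `DamageProfile` estimated from the same pileup; used to
#'   check that interior damage is in fact low enough for the rule to separate
#'   variants from deamination (a warning is raised otherwise).
#' @param interior_start First read position counted as interior (in
#'   `(0, i_max]`).
#' @param t_frac_threshold Minimum interior T fraction to call a variant (in
#'   `(0.5, 1]`).
#' @param min_support Minimum interior observation count to apply the rule.
#'
#' @return A `SitePileup` with the masked CpG sites' counts removed and their
#'   positions recorded in `masked_pos`.
#' @export
mask_mutations <- function(pileup, profile, interior_start = 10,
                           t_frac_threshold = 0.9, min_support = 5) {
  stopifnot(inherits(pileup, "SitePileup"))
  .check_scalar(interior_start, "interior_start", lower = 1, upper = pileup$i_max)
  .check_scalar(t_frac_threshold, "t_frac_threshold", lower = 0.5, upper = 1)
  if (t_frac_threshold <= 0.5) {
    stop("'t_frac_threshold' must be in (0.5, 1]", call. = FALSE)
  }
  .check_scalar(min_support, "min_support", lower = 1)

  if (inherits(profile, "DamageProfile")) {
    interior <- profile$read_pos >= interior_start & profile$n_obs > 0
    if (any(interior) &&
        mean(profile$delta_hat[interior]) > (1 - t_frac_threshold)) {
      warning("interior deamination is high relative to the masking ",
              "threshold; variant masking may remove damaged sites",
              call. = FALSE)
    }
  }

  is_cpg <- read_pos <- n_C <- n_T <- site_pos <- NULL
  interior_cpg <- pileup$counts[is_cpg == TRUE & read_pos >= interior_start,
                                list(n_C = sum(n_C), n_T = sum(n_T)),
                                by = site_pos]
  bad <- interior_cpg[
    (n_C + n_T) >= min_support & n_T / (n_C + n_T) >= t_frac_threshold,
    site_pos]
  out <- pileup
  if (length(bad) > 0L) {
    out$counts <- pileup$counts[!(is_cpg == TRUE & site_pos %in% bad)]
    out$masked_pos <- sort(union(pileup$masked_pos, bad))
  }
  out
}
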