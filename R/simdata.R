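#' Generate a synthetic reference chromosome with planted CpG sites
#'
#' Builds a random chromosome over A/C/G/T in which the background sequence is
#' free of CG dinucleotides and exactly `n_cpg` CpG sites are planted at
#' uniformly sampled, non-adjacent positions. Because the background is CG-free,
#' the planted coordinate list enumerates every CpG in the sequence, giving the
#' simulation an exhaustive ground-truth site map (a scaled-down stand-in for a
#' real chromosome).
#'
#' @param length Chromosome length in bases (>= 1000).
#' @param n_cpg Number of CpG sites to plant (0 <= n_cpg <= length/10).
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @param name Chromosome name used in FASTA/bedGraph output.
#'
#' @return A `ReferenceChrom` object: list with `name`, `seq` (character
#'   string), and `cpg_pos` (0-based positions of the C of each CpG, strictly
#'   increasing).
#' @export
generate_reference <- function(length, n_cpg, seed, name = "chrS") {
  .check_scalar(length, "length", lower = 1000)
  .check_scalar(n_cpg, "n_cpg", lower = 0, upper = length / 10)
  length <- as.integer(length)
  n_cpg <- as.integer(n_cpg)
  if (n_cpg > 0 && 2L * n_cpg > length) {
    stop("n_cpg too dense: cannot place ", n_cpg,
         " non-adjacent CpGs in ", length, " bases", call. = FALSE)
  }

  .with_seed(seed, {
    codes <- sample(c(.CODE_A, .CODE_C, .CODE_G, .CODE_T), length, replace = TRUE)
    # Remove CG dinucleotides from the background: wherever a CG occurs,
    # resample the G among {A,C,T}; iterate until none remain (a resampled C
    # can create a new CG with the following base).
    repeat {
      cg_at <- which(codes[-length] == .CODE_C & codes[-1L] == .CODE_G)
      if (length(cg_at) == 0L) break
      codes[cg_at + 1L] <- sample(c(.CODE_A, .CODE_C, .CODE_T),
                                  length(cg_at), replace = TRUE)
    }

    cpg_pos <- integer(0)
    if (n_cpg > 0) {
      # Uniform sample of n sorted positions in 1..(length-1) with pairwise gap
      # >= 2, via the standard spacing bijection: draw n distinct values from a
      # contracted range and re-expand.
      y <- sort(sample.int(length - 1L - (n_cpg - 1L), n_cpg))
      p1 <- y + 0:(n_cpg - 1L)           # 1-based position of each C
      codes[p1] <- .CODE_C
      codes[p1 + 1L] <- .CODE_G
      cpg_pos <- p1 - 1L                 # 0-based
    }

    structure(
      list(name = name, seq = .int_to_seq(codes), cpg_pos = as.integer(cpg_pos)),
      class = "ReferenceChrom"
    )
  })
}

#' @export
print.ReferenceChrom <- function(x, ...) {
  cat(sprintf("<ReferenceChrom> %s: %d bp, %d CpG sites\n",
              x$name, nchar(x$seq), length(x$cpg_pos)))
  invisible(x)
}

# Enumerate all CG dinucleotide positions (0-based C positions) in a sequence.
# Used by the FASTA reader and by validity checks.
.find_cpgs <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Generate a bimodal methylome over the CpG sites of a reference
#'
#' Vertebrate CpG methylation is strongly bimodal: most CpGs are highly
#' methylated while CpG-island-like regions are nearly unmethylated, and levels
#' are locally correlated. This generator partitions the CpG sites into
#' consecutive blocks of `block_len` sites; each block draws a single level from
#' `Beta(beta_high)` with probability `p_high`, otherwise from `Beta(beta_low)`,
#' shared by all sites of the block.
#'
#' @param ref A `ReferenceChrom`.
#' @param p_high Probability that a block is in the methylated mode.
#' @param beta_high,beta_low Length-2 shape vectors `(a, b)` of the two Beta
#'   mixture components (defaults give modes near 0.8 and 0.1).
#' @param block_len Block size in CpG count over which the level is constant.
#' @param seed Integer seed.
#'
#' @return A `Methylome`: list with `levels` (one value in `[0,1]` per entry of
#'   `ref$cpg_pos`), `block_len`, and `ref_name`.
#' @export
generate_methylome <- function(ref, p_high = 0.75, beta_high = c(8, 2),
                               beta_low = c(1, 9), block_len = 50, seed = 1) {
  stopifnot(inherits(ref, "ReferenceChrom"))
  .check_scalar(p_high, "p_high", 0, 1)
  .check_scalar(block_len, "block_len", lower = 1)
  if (any(c(beta_high, beta_low) <= 0)) {
    stop("Beta shape parameters must be > 0", call. = FALSE)
  }
  n <- length(ref$cpg_pos)
  block_len <- as.integer(block_len)

  levels <- .with_seed(seed, {
    if (n == 0L) numeric(0) else {
      n_block <- ceiling(n / block_len)
      hi <- stats::runif(n_block) < p_high
      lv <- numeric(n_block)
      lv[hi] <- stats::rbeta(sum(hi), beta_high[1], beta_high[2])
      lv[!hi] <- stats::rbeta(sum(!hi), beta_low[1], beta_low[2])
      rep(lv, each = block_len)[seq_len(n)]
    }
  })

  structure(
    list(levels = levels, block_len = block_len, ref_name = ref$name),
    class = "Methylome"
  )
}

#' Post-mortem deamination model for ancient-DNA simulation
#'
#' Parameterizes position-dependent cytosine deamination in an ancient-DNA
#' library. Unmethylated cytosines deaminate to uracil (read as T) at rate
#' `delta_u(i) = delta_bg + (delta_max - delta_bg) * decay^i`, where `i` is the
#' distance of the base from its read's own 5' end: damage is concentrated at
#' fragment termini and decays geometrically into the interior. Methylated
#' cytosines (5mC) deaminate directly to thymine at the faster rate
#' `delta_m(i) = min(1, rho * delta_u(i))` with `rho >= 1`; this rate excess at
#' CpG sites is the methylation signal the estimator exploits.
#'
#' In `"UDG"` mode (uracil-DNA glycosylase treated library) deaminated
#' unmethylated cytosines are excised and appear as gaps rather than T
#' observations, while 5mC-derived thymines persist.
#'
#' @param delta_max Terminal (i = 0) unmethylated deamination probability.
#' @param decay Per-position geometric decay factor in (0, 1).
#' @param delta_bg Interior background deamination rate.
#' @param rho Rate ratio delta_m / delta_u (>= 1).
#' @param eps Per-base sequencing error rate in `[0, 0.25]`.
#' @param mode `"non-UDG"` (default) or `"UDG"`.
#'
#' @return A `DamageModel` object.
#' @export
damage_model <- function(delta_max = 0.30, decay = 0.30, delta_bg = 0.01,
                         rho = 2.0, eps = 0.001, mode = c("non-UDG", "UDG")) {
  mode <- match.arg(mode)
  .check_scalar(delta_max, "delta_max", 0, 1)
  .check_scalar(decay, "decay", 0, 1)
  if (decay <= 0 || decay >= 1) stop("'decay' must be in (0, 1)", call. = FALSE)
  .check_scalar(delta_bg, "delta_bg", 0, 1)
  if (delta_bg > delta_max) {
    stop("'delta_bg' must not exceed 'delta_max' (terminal damage is maximal)",
         call. = FALSE)
  }
  .check_scalar(rho, "rho", lower = 1)
  .check_scalar(eps, "eps", 0, 0.25)
  structure(
    list(delta_max = delta_max, decay = decay, delta_bg = delta_bg,
         rho = rho, eps = eps, mode = mode),
    class = "DamageModel"
  )
}

#' Unmethylated deamination rate at read position i
#'
#' @param dmg A `DamageModel`.
#' @param i Read-position index (0-based distance to the read's 5' end);
#'   values beyond the damage-table cap are pooled with the cap position.
#' @return Numeric vector of rates in `[0, 1]`, non-increasing in `i`.
#' @export
damage_delta_u <- function(dmg, i) {
  i <- pmin(as.numeric(i), I_MAX)
  dmg$delta_bg + (dmg$delta_max - dmg$delta_bg) * dmg$decay^i
}

#' Methylated (5mC) deamination rate at read position i
#'
#' @inheritParams damage_delta_u
#' @return Numeric vector `min(1, rho * delta_u(i))`.
#' @export
damage_delta_m <- function(dmg, i) {
  pmin(1, dmg$rho * damage_delta_u(dmg, i))
}

#' @export
print.DamageModel <- function(x, ...) {
  cat(sprintf(
    "<DamageModel> %s: delta_u(0)=%.3g, decay=%.3g, background=%.3g, rho=%.3g, eps=%.3g\n",
    x$mode, x$delta_max, x$decay, x$delta_bg, x$rho, x$eps))
  invisible(x)
}

#' Simulate an ancient-DNA read set with deamination damage
#'
#' Draws short fragments from the reference (lognormal length distribution
#' truncated to `[20, 150]` bp, uniform start and strand, Poisson fragment
#' count targeting `mean_cov`), then applies the damage model in each
#' fragment's own strand frame: every cytosine on the fragment strand at
#' distance `i` from that strand's 5' end deaminates with probability
#' `delta_m(i)` if the underlying molecule is methylated at that CpG
#' (methylation state drawn per molecule as Bernoulli of the site level `m_s`)
#' and `delta_u(i)` otherwise, so the marginal conversion probability at a CpG
#' cytosine is `m_s * delta_m(i) + (1 - m_s) * delta_u(i)`. Non-CpG cytosines
#' are treated as unmethylated. Deamination on the forward strand appears as
#' C->T and on the reverse strand as G->A in the forward reference frame. In
#' UDG mode unmethylated deamination removes the base (gap `-` in the stored
#' sequence, no observation) instead of producing a T. Finally an independent
#' sequencing error `eps` substitutes each emitted base uniformly among the
#' three alternatives.
#'
#' @param ref A `ReferenceChrom`.
#' @param meth A `Methylome` over the same reference.
#' @param dmg A `DamageModel`.
#' @param mean_cov Target mean fold-coverage (>= 0; values > 10000 rejected).
#' @param fraglen_logmu,fraglen_logsigma Lognormal fragment-length parameters
#'   (defaults: median 55 bp, typical of ancient-DNA libraries).
#' @param seed Integer seed.
#'
#' @return A `ReadSet`: list with `reads` (data.table of `start` 0-based,
#'   `strand` in `{+,-}`, `bases` forward-frame observed sequence, `-` = gap),
#'   realized `mean_cov`, `ref_length`, and `ref_name`.
#' @export
simulate_reads <- function(ref, meth, dmg, mean_cov,
                           fraglen_logmu = log(55), fraglen_logsigma = 0.35,
                           seed = 1) {
  stopifnot(inherits(ref, "ReferenceChrom"), inherits(meth, "Methylome"),
            inherits(dmg, "DamageModel"))
  .check_scalar(mean_cov, "mean_cov", lower = 0)
  if (mean_cov > 10000) stop("mean_cov > 10000: refusing runaway simulation",
                             call. = FALSE)
  if (length(meth$levels) != length(ref$cpg_pos)) {
    stop("methylome does not match reference CpG count", call. = FALSE)
  }

  L <- nchar(ref$seq)
  empty <- function() structure(
    list(reads = data.table::data.table(start = integer(0),
                                        strand = character(0),
                                        bases = character(0)),
         mean_cov = 0, ref_length = L, ref_name = ref$name),
    class = "ReadSet")
  if (mean_cov == 0) return(empty())

  # Mean of the truncated lognormal (closed form) so the Poisson fragment
  # count hits the requested coverage in expectation.
  a <- 20; b <- 150
  mu <- fraglen_logmu; s <- fraglen_logsigma
  z <- stats::pnorm((log(b) - mu) / s) - stats::pnorm((log(a) - mu) / s)
  m1 <- exp(mu + s^2 / 2) *
    (stats::pnorm((log(b) - mu - s^2) / s) - stats::pnorm((log(a) - mu - s^2) / s))
  mean_len <- m1 / z

  .with_seed(seed, {
    n_frag <- stats::rpois(1L, mean_cov * L / mean_len)
    if (n_frag == 0L) {
      empty()
    } else {
    # Fragment lengths: lognormal, rejection-truncated to [20, 150].
    lens <- round(stats::rlnorm(n_frag, mu, s))
    bad <- which(lens < a | lens > b)
    while (length(bad) > 0L) {
      lens[bad] <- round(stats::rlnorm(length(bad), mu, s))
      bad <- bad[lens[bad] < a | lens[bad] > b]
    }
    lens <- as.integer(lens)
    starts <- as.integer(floor(stats::runif(n_frag) * (L - lens + 1L)))  # 0-based
    strand <- sample(c("+", "-"), n_frag, replace = TRUE)

    # Per-base expansion over all fragments.
    rid <- rep.int(seq_len(n_frag), lens)
    pos1 <- sequence(lens, from = starts + 1L)     # 1-based reference position
    ioff <- sequence(lens, from = 0L)              # offset from read start
    plus <- strand[rid] == "+"
    i <- ioff
    i[!plus] <- lens[rid[!plus]] - 1L - ioff[!plus]  # distance to own 5' end

    refcode <- .seq_to_int(ref$seq)[pos1]
    out <- refcode

    # CpG site index lookup (0 = not a CpG C).
    cpg_idx <- integer(L)
    if (length(ref$cpg_pos) > 0) cpg_idx[ref$cpg_pos + 1L] <- seq_along(ref$cpg_pos)

    # Read-frame cytosines: forward reads over reference C, reverse reads over
    # reference G (the reverse-strand molecule carries a C there).
    cyt <- (plus & refcode == .CODE_C) | (!plus & refcode == .CODE_G)
    w <- which(cyt)
    if (length(w) > 0L) {
      site <- integer(length(w))
      wp <- plus[w]
      site[wp] <- cpg_idx[pos1[w][wp]]
      wm_pos <- pos1[w][!wp] - 1L          # C position of a CpG whose G this is
      sm <- cpg_idx[pmax(wm_pos, 1L)]
      sm[wm_pos < 1L] <- 0L
      site[!wp] <- sm

      m <- numeric(length(w))
      m[site > 0L] <- meth$levels[site[site > 0L]]
      methylated <- stats::runif(length(w)) < m
      du <- damage_delta_u(dmg, i[w])
      dm <- damage_delta_m(dmg, i[w])
      p_deam <- ifelse(methylated, dm, du)
      deam <- stats::runif(length(w)) < p_deam

      conv <- w[deam & methylated]
      conv_u <- w[deam & !methylated]
      if (dmg$mode == "UDG") {
        # 5mC-derived thymines persist; uracils are excised (gap).
        out[conv] <- ifelse(plus[conv], .CODE_T, .CODE_A)
        out[conv_u] <- .CODE_GAP
      } else {
        both <- c(conv, conv_u)
        out[both] <- ifelse(plus[both], .CODE_T, .CODE_A)
      }
    }

    # Sequencing error: each emitted base flips to one of the 3 alternatives.
    if (dmg$eps > 0) {
      emitted <- which(out != .CODE_GAP)
      err <- emitted[stats::runif(length(emitted)) < dmg$eps]
      if (length(err) > 0L) {
        cur <- match(out[err], c(.CODE_A, .CODE_C, .CODE_G, .CODE_T))
        shift <- sample.int(3L, length(err), replace = TRUE)
        new <- (cur - 1L + shift) %% 4L + 1L
        out[err] <- c(.CODE_A, .CODE_C, .CODE_G, .CODE_T)[new]
      }
    }

    big <- .int_to_seq(out)
    ends <- cumsum(lens)
    bases <- substring(big, ends - lens + 1L, ends)
    realized <- sum(out != .CODE_GAP) / L

    structure(
      list(reads = data.table::data.table(start = starts, strand = strand,
                                          bases = bases),
           mean_cov = realized, ref_length = L, ref_name = ref$name),
      class = "ReadSet")
    }
  })
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("<ReadSet> %d reads on %s (%d bp), mean coverage %.2fx\n",
              nrow(x$reads), x$ref_name, x$ref_length, x$mean_cov))
  invisible(x)
}
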