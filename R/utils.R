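# Internal helpers shared across modules.

# Maximum read-position index for damage tables: terminal deamination decays
# geometrically, so positions beyond I_MAX are pooled with position I_MAX.
I_MAX <- 25L

.BASES <- c("A", "C", "G", "T")

# Reproducible RNG scope: every seeded operation runs under a fixed generator
# so outputs are byte-identical across platforms and caller RNG state is
# untouched.
.with_seed <- function(seed, code) {
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

# Derive a stage-specific sub-seed from a master seed; stays inside 32-bit
# integer range for any master seed.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483587) + 1L
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

# Sequence string <-> integer codes (utf8 codepoints); fast bulk conversion.
.seq_to_int <- function(seq) utf8ToInt(seq)
.int_to_seq <- function(codes) intToUtf8(codes)

.CODE_A <- utf8ToInt("A")
.CODE_C <- utf8ToInt("C")
.CODE_G <- utf8ToInt("G")
.CODE_T <- utf8ToInt("T")
.CODE_GAP <- utf8ToInt("-")

# Complement on integer codes (A<->T, C<->G); gaps pass through.
.complement_int <- function(codes) {
  out <- codes
  out[codes == .CODE_A] <- .CODE_T
  out[codes == .CODE_T] <- .CODE_A
  out[codes == .CODE_C] <- .CODE_G
  out[codes == .CODE_G] <- .CODE_C
  out
}

# Sample standard deviation with n-1 denominator (explicit, used for Delta-f).
.sample_sd <- function(x) stats::sd(x)
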