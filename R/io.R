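# TSV dialect used throughout: tab-separated, metadata lines "# key=value",
# a "#"-prefixed column-header line, "." for missing values.

.fmt_num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.17g", x))
}

.write_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
  }
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.double(col)) .fmt_num(col)
      else if (is.logical(col)) as.integer(col)
      else ifelse(is.na(col), ".", as.character(col))
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

.read_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# [A-Za-z_.]+=", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  hdr_idx <- grep("^#[^ ]", lines)
  if (length(hdr_idx) == 0L) stop("malformed TSV: no '#'-prefixed column ",
                                  "header in ", path, call. = FALSE)
  hdr_idx <- hdr_idx[length(hdr_idx)]
  cols <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- as.data.frame(matrix(character(0), 0, length(cols)),
                        stringsAsFactors = FALSE)
    names(df) <- cols
    return(list(meta = meta, data = df))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols))) {
    stop(sprintf("malformed line %d in %s: %d fields, expected %d",
                 hdr_idx + which(nf != length(cols))[1],
                 path, nf[nf != length(cols)][1], length(cols)),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = length(cols), byrow = TRUE)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  df[df == "."] <- NA
  list(meta = meta, data = df)
}

.meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

# ---- reference ----

#' Write a reference chromosome to FASTA
#' @param ref A `ReferenceChrom`.
#' @param path Output file.
#' @export
write_reference_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "ReferenceChrom"))
  x <- Biostrings::DNAStringSet(stats::setNames(ref$seq, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a reference chromosome from FASTA
#'
#' The CpG coordinate list is reconstructed by enumerating every CG
#' dinucleotide in the sequence (exhaustive for references generated by
#' [generate_reference()], whose background is CG-free).
#'
#' @param path FASTA file with a single sequence.
#' @return A `ReferenceChrom`.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("expected exactly one sequence in ", path,
                            call. = FALSE)
  seq <- as.character(x[[1]])
  structure(list(name = sub("\\s.*$", "", names(x)[1]), seq = seq,
                 cpg_pos = .find_cpgs(seq)),
            class = "ReferenceChrom")
}

# ---- methylome ----

#' Write a methylome to TSV (pos, level)
#' @param meth A `Methylome`.
#' @param ref The matching `ReferenceChrom`.
#' @param path Output file.
#' @export
write_methylome_tsv <- function(meth, ref, path) {
  stopifnot(inherits(meth, "Methylome"), inherits(ref, "ReferenceChrom"))
  .write_tsv(data.frame(pos = ref$cpg_pos, level = meth$levels), path,
             meta = list(ref = meth$ref_name, block_len = meth$block_len))
}

#' Read a methylome TSV
#' @param path File written by [write_methylome_tsv()].
#' @return A `Methylome` (positions available as `attr(x, "pos")`).
#' @export
read_methylome_tsv <- function(path) {
  r <- .read_tsv(path)
  out <- structure(
    list(levels = as.numeric(r$data$level),
         block_len = as.integer(.meta_num(r$meta, "block_len", 1)),
         ref_name = r$meta$ref %||% NA_character_),
    class = "Methylome")
  attr(out, "pos") <- as.integer(r$data$pos)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reads ----

#' Write a read set to TSV (start, strand, bases)
#' @param reads A `ReadSet`.
#' @param path Output file.
#' @export
write_reads_tsv <- function(reads, path) {
  stopifnot(inherits(reads, "ReadSet"))
  .write_tsv(as.data.frame(reads$reads), path,
             meta = list(ref = reads$ref_name,
                         ref_length = reads$ref_length,
                         mean_cov = sprintf("%.17g", reads$mean_cov)))
}

#' Read a read-set TSV
#' @param path File written by [write_reads_tsv()].
#' @return A `ReadSet`.
#' @export
read_reads_tsv <- function(path) {
  r <- .read_tsv(path)
  structure(
    list(reads = data.table::data.table(
           start = as.integer(r$data$start),
           strand = as.character(r$data$strand),
           bases = as.character(r$data$bases)),
         mean_cov = .meta_num(r$meta, "mean_cov", 0),
         ref_length = as.integer(.meta_num(r$meta, "ref_length")),
         ref_name = r$meta$ref %||% NA_character_),
    class = "ReadSet")
}

#' Write a read set as minimal SAM (interoperability convenience)
#'
#' Emits an unsorted single-reference SAM with MAPQ 60 and CIGAR `M`/`D`
#' operations (UDG excision gaps become deletions). Reverse-strand reads carry
#' flag 16; sequences are stored in the forward reference frame, as in SAM.
#'
#' @param reads A `ReadSet`.
#' @param path Output file (.sam).
#' @export
write_reads_sam <- function(reads, path) {
  stopifnot(inherits(reads, "ReadSet"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", reads$ref_name, reads$ref_length)),
             con)
  tbl <- reads$reads
  if (nrow(tbl) > 0) {
    cigar <- vapply(tbl$bases, function(b) {
      r <- rle(strsplit(b, "", fixed = TRUE)[[1]] == "-")
      paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
    }, character(1), USE.NAMES = FALSE)
    seqs <- gsub("-", "", tbl$bases, fixed = TRUE)
    writeLines(sprintf("read%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                       seq_len(nrow(tbl)),
                       ifelse(tbl$strand == "-", 16L, 0L),
                       reads$ref_name, tbl$start + 1L, cigar, seqs), con)
  }
  invisible(path)
}

#' Read a minimal SAM file into a ReadSet
#'
#' Accepts single-reference SAM with `M`/`D` CIGAR operations only; deletions
#' are re-inserted as `-` gaps so coordinates round-trip.
#'
#' @param path SAM file.
#' @return A `ReadSet` (mean coverage recomputed from the alignments).
#' @export
read_reads_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")][1]
  if (is.na(sq)) stop("SAM file lacks an @SQ header line", call. = FALSE)
  ref_name <- sub("^.*SN:([^\t]+).*$", "\\1", sq)
  ref_length <- as.integer(sub("^.*LN:([0-9]+).*$", "\\1", sq))
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    reads <- data.table::data.table(start = integer(0), strand = character(0),
                                    bases = character(0))
    return(structure(list(reads = reads, mean_cov = 0,
                          ref_length = ref_length, ref_name = ref_name),
                     class = "ReadSet"))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 11L)
  if (length(bad)) {
    stop("malformed SAM line ", length(hdr) + bad[1], call. = FALSE)
  }
  flag <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  pos <- vapply(parts, function(p) as.integer(p[4]), integer(1))
  cigar <- vapply(parts, function(p) p[6], character(1))
  seqs <- vapply(parts, function(p) p[10], character(1))
  bases <- mapply(function(cg, sq) {
    ops_len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MD]", cg))[[1]]
    if (length(ops) != length(ops_len)) {
      stop("unsupported CIGAR: ", cg, call. = FALSE)
    }
    out <- character(0)
    off <- 0L
    for (j in seq_along(ops)) {
      if (ops[j] == "M") {
        out <- c(out, substring(sq, off + 1L, off + ops_len[j]))
        off <- off + ops_len[j]
      } else {
        out <- c(out, strrep("-", ops_len[j]))
      }
    }
    paste0(out, collapse = "")
  }, cigar, seqs, USE.NAMES = FALSE)
  aligned <- sum(nchar(gsub("-", "", bases, fixed = TRUE)))
  structure(
    list(reads = data.table::data.table(
           start = pos - 1L,
           strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
           bases = bases),
         mean_cov = aligned / ref_length,
         ref_length = ref_length, ref_name = ref_name),
    class = "ReadSet")
}

# ---- pileup ----

#' Write a site pileup to TSV
#' @param pileup A `SitePileup`.
#' @param path Output file.
#' @export
write_pileup_tsv <- function(pileup, path) {
  stopifnot(inherits(pileup, "SitePileup"))
  .write_tsv(as.data.frame(pileup$counts), path,
             meta = list(ref = pileup$ref_name,
                         ref_length = pileup$ref_length,
                         i_max = pileup$i_max,
                         cpg_pos = paste(pileup$cpg_pos, collapse = ","),
                         masked_pos = paste(pileup$masked_pos, collapse = ",")))
}

#' Read a site-pileup TSV (bit-exact round trip)
#' @param path File written by [write_pileup_tsv()].
#' @return A `SitePileup`.
#' @export
read_pileup_tsv <- function(path) {
  r <- .read_tsv(path)
  need <- c("site_pos", "is_cpg", "read_pos", "n_C", "n_T")
  if (!all(need %in% names(r$data))) {
    stop("pileup TSV lacks required columns: ",
         paste(setdiff(need, names(r$data)), collapse = ", "), call. = FALSE)
  }
  parse_pos <- function(s) {
    if (is.null(s) || !nzchar(s)) integer(0) else
      as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  }
  counts <- data.table::data.table(
    site_pos = as.integer(r$data$site_pos),
    is_cpg = as.integer(r$data$is_cpg) > 0L,
    read_pos = as.integer(r$data$read_pos),
    n_C = as.integer(r$data$n_C),
    n_T = as.integer(r$data$n_T))
  structure(
    list(counts = counts,
         i_max = as.integer(.meta_num(r$meta, "i_max", I_MAX)),
         cpg_pos = parse_pos(r$meta$cpg_pos),
         masked_pos = parse_pos(r$meta$masked_pos),
         ref_name = r$meta$ref %||% NA_character_,
         ref_length = as.integer(.meta_num(r$meta, "ref_length"))),
    class = "SitePileup")
}

# ---- damage profile ----

#' Write a damage profile to TSV
#' @param profile A `DamageProfile`.
#' @param path Output file.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "DamageProfile"))
  .write_tsv(as.data.frame(profile), path)
}

#' Read a damage-profile TSV
#' @param path File written by [write_profile_tsv()].
#' @return A `DamageProfile`.
#' @export
read_profile_tsv <- function(path) {
  r <- .read_tsv(path)
  out <- data.frame(read_pos = as.integer(r$data$read_pos),
                    delta_hat = as.numeric(r$data$delta_hat),
                    n_obs = as.integer(r$data$n_obs))
  class(out) <- c("DamageProfile", "data.frame")
  out
}

# ---- f track ----

#' Write a methylation track to TSV with full per-site metadata
#' @param track An `FTrack`.
#' @param path Output file.
#' @export
write_ftrack_tsv <- function(track, path) {
  stopifnot(inherits(track, "FTrack"))
  .write_tsv(as.data.frame(track$sites), path,
             meta = list(ref = track$ref_name, ncpg = track$ncpg,
                         coverage_label = .fmt_num(track$coverage_label),
                         mode = track$mode,
                         rho = sprintf("%.17g", track$rho),
                         eps = sprintf("%.17g", track$eps),
                         nonidentifiable = as.integer(track$nonidentifiable)))
}

#' Read a methylation-track TSV
#' @param path File written by [write_ftrack_tsv()].
#' @return An `FTrack` with identical in-memory values.
#' @export
read_ftrack_tsv <- function(path) {
  r <- .read_tsv(path)
  structure(
    list(sites = data.table::data.table(
           pos = as.integer(r$data$pos),
           f_hat = as.numeric(r$data$f_hat),
           focal_n = as.integer(r$data$focal_n),
           n_obs = as.integer(r$data$n_obs),
           masked = as.integer(r$data$masked) > 0L),
         ncpg = as.integer(.meta_num(r$meta, "ncpg")),
         coverage_label = .meta_num(r$meta, "coverage_label"),
         ref_name = r$meta$ref %||% NA_character_,
         mode = r$meta$mode %||% "non-UDG",
         rho = .meta_num(r$meta, "rho", 2),
         eps = .meta_num(r$meta, "eps", 0.001),
         nonidentifiable = .meta_num(r$meta, "nonidentifiable", 0) > 0),
    class = "FTrack")
}

#' Write a methylation track as bedGraph
#'
#' UCSC bedGraph, 0-based half-open: one line `chrom start start+2 f_hat` per
#' CpG with a defined estimate (the two-base interval covers the CpG
#' dinucleotide).
#'
#' @param track An `FTrack`.
#' @param path Output file.
#' @export
write_ftrack_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "FTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf(
    "track type=bedGraph name=\"f_%s\" description=\"CpG methylation estimate f (NCPG=%d)\"",
    track$ref_name, track$ncpg), con)
  ok <- !is.na(track$sites$f_hat)
  if (any(ok)) {
    writeLines(sprintf("%s\t%d\t%d\t%.6g", track$ref_name,
                       track$sites$pos[ok], track$sites$pos[ok] + 2L,
                       track$sites$f_hat[ok]), con)
  }
  invisible(path)
}

# ---- experiment outputs ----

#' Write all artifacts of an experiment result to a directory
#'
#' Emits the reference FASTA, methylome TSV, full-coverage damage profile,
#' per-level and full methylation tracks (TSV + bedGraph), the precision
#' table, the trendline fit, and the coverage recommendation.
#'
#' @param result An `ExperimentResult`.
#' @param dir Output directory (created if needed).
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "ExperimentResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  write_reference_fasta(result$ref, p("reference.fasta"))
  write_methylome_tsv(result$methylome, result$ref, p("methylome.tsv"))
  write_profile_tsv(result$profile_full, p("damage_profile_full.tsv"))
  write_ftrack_tsv(result$track_full, p("ftrack_full.tsv"))
  write_ftrack_bedgraph(result$track_full, p("ftrack_full.bedGraph"))
  for (nm in names(result$tracks)) {
    write_ftrack_tsv(result$tracks[[nm]], p("ftrack_", nm, ".tsv"))
    write_ftrack_bedgraph(result$tracks[[nm]], p("ftrack_", nm, ".bedGraph"))
  }
  .write_tsv(as.data.frame(result$table), p("precision.tsv"),
             meta = list(full_cov = result$config$full_cov,
                         ncpg = result$config$ncpg,
                         seed = result$config$seed,
                         label = result$config$label))
  tf <- result$trend
  .write_tsv(data.frame(param = names(tf$params), value = unname(tf$params)),
             p("trendfit.tsv"),
             meta = list(form = tf$form,
                         r_squared = sprintf("%.17g", tf$r_squared),
                         degenerate = as.integer(tf$degenerate)))
  rec <- result$recommendation
  .write_tsv(data.frame(
    sd_ref = rec$sd_ref, ref_level = rec$ref_level,
    threshold = rec$threshold, factor = rec$factor,
    recommended_level = rec$recommended_level, full_cov = rec$full_cov),
    p("recommendation.tsv"))
  invisible(dir)
}

#' Read a precision table written by [write_experiment()]
#' @param path `precision.tsv` file.
#' @return A `PrecisionTable`.
#' @export
read_precision_tsv <- function(path) {
  r <- .read_tsv(path)
  out <- data.frame(coverage_level = as.numeric(r$data$coverage_level),
                    sd_delta_f = as.numeric(r$data$sd_delta_f),
                    n_compared = as.integer(r$data$n_compared),
                    n_noncovered = as.integer(r$data$n_noncovered))
  class(out) <- c("PrecisionTable", "data.frame")
  attr(out, "full_cov") <- .meta_num(r$meta, "full_cov")
  out
}
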