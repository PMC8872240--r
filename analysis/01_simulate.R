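#!/usr/bin/env Rscript

# Step 1 — simulate a typically preserved ancient sample.
#
# Builds the reference study dataset: a 0.5-Mb chromosome with 5,000 planted
# CpGs, a bimodal methylome, and a 24x non-UDG read set with 30% terminal
# deamination (the "ans017-like" regime). Writes the ground truth and the
# reads under results/sim/ for the later steps.

suppressPackageStartupMessages(library(paleometh))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- preset_config("ans017-like", seed = 1)
ref <- generate_reference(cfg$ref_length, cfg$n_cpg, seed = 101, name = "chrS")
meth <- generate_methylome(ref, p_high = cfg$p_high, beta_high = cfg$beta_high,
                           beta_low = cfg$beta_low, block_len = cfg$block_len,
                           seed = 102)
reads <- simulate_reads(ref, meth, cfg$damage, mean_cov = cfg$full_cov,
                        seed = 103)

write_reference_fasta(ref, file.path(out, "reference.fasta"))
write_methylome_tsv(meth, ref, file.path(out, "methylome.tsv"))
write_reads_tsv(reads, file.path(out, "reads.tsv"))
write_reads_sam(reads, file.path(out, "reads.sam"))

cat(sprintf("reference: %d bp, %d CpGs (density 1 per %.0f bp)\n",
            nchar(ref$seq), length(ref$cpg_pos),
            nchar(ref$seq) / length(ref$cpg_pos)))
cat(sprintf("methylome: mean m = %.3f, %.0f%% of CpGs above 0.5\n",
            mean(meth$levels), 100 * mean(meth$levels > 0.5)))
cat(sprintf("reads: %d fragments, realized coverage %.2fx (requested %gx)\n",
            nrow(reads$reads), reads$mean_cov, cfg$full_cov))
cat(sprintf("wrote FASTA/TSV/SAM under %s\n", out))
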