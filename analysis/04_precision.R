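#!/usr/bin/env Rscript

# Step 4 — the coverage down-sampling experiment.
#
# For each of the three sample presets, thins the full read set across the
# coverage grid, estimates f at every level, computes SD(Delta f) against the
# full-coverage track, fits the sqrt-law trendline, and applies the 2x-SD
# threshold rule. Also fits the alternative trendline families for comparison
# and draws the non-covered-CpG and SD-decay figures.

suppressPackageStartupMessages(library(paleometh))

out <- "results/precision"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

presets <- c("ans017-like", "SF12-like", "stuttgart-like")
all_tabs <- list()

for (p in presets) {
  cat("\n==== ", p, " ====\n", sep = "")
  res <- run_experiment(preset_config(p, seed = 1,
                                      out_dir = file.path(out, p)))
  print(res$table)
  print(res$recommendation)
  cat("trendline R^2 by family:\n")
  for (fm in c("sqrt-law", "power", "exponential")) {
    ft <- fit_trendline(res$table$coverage_level, res$table$sd_delta_f,
                        full_cov = res$config$full_cov, form = fm)
    cat(sprintf("  %-12s R^2 = %.4f\n", fm, ft$r_squared))
  }
  tab <- res$table
  tab$preset <- p
  tab$full_cov <- res$config$full_cov
  all_tabs[[p]] <- tab
}

tabs <- do.call(rbind, all_tabs)
write.table(tabs, file.path(out, "precision_all_presets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nwrote %s\n", file.path(out, "precision_all_presets.tsv")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  g1 <- ggplot(tabs, aes(coverage_level, n_noncovered + 1, colour = preset)) +
    geom_line() + geom_point() + scale_y_log10() +
    labs(x = "down-sampled coverage (x)", y = "non-covered CpGs + 1 (log)",
         title = "Non-covered CpG positions vs coverage") +
    theme_minimal()
  ggsave(file.path(out, "noncovered_vs_coverage.pdf"), g1,
         width = 6, height = 4)
  g2 <- ggplot(tabs, aes(coverage_level, sd_delta_f, colour = preset)) +
    geom_point() + geom_line(linetype = "dotted") +
    labs(x = "down-sampled coverage (x)", y = "SD(Delta f)",
         title = "Precision of f vs coverage, with 2x-SD thresholds") +
    theme_minimal()
  ggsave(file.path(out, "sd_deltaf_vs_coverage.pdf"), g2,
         width = 6, height = 4)
  cat("wrote figures under", out, "\n")
}
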