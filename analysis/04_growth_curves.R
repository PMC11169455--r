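#!/usr/bin/env Rscript
# Step 4: growth-curve analysis on synthetic OD600 data emulating a yeast
# complementation experiment: a wild type, a slow-growing deletion mutant
# carrying an empty vector, and the mutant rescued by the candidate gene.
# Rates are estimated per replicate from the exponential phase and compared
# by one-way ANOVA with Tukey's post-hoc test.
# Writes: results/growth_rates.tsv, results/growth_comparison.tsv.
library(thiamsim)
dir.create("results", showWarnings = FALSE)

curves <- make_growth_curves(
  list(WT_EV = c(rate = 0.40, n = 4),
       mutant_EV = c(rate = 0.15, n = 4),
       mutant_rescued = c(rate = 0.38, n = 4)),
  noise_sigma = 0.01, seed = 20240612)
est <- estimate_growth_rates(curves)
write.table(est, "results/growth_rates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cg <- compare_groups(split(est$rate, est$label))
write.table(cg$tukey, "results/growth_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Estimated rates (per h): %s\n",
            paste(sprintf("%s %.3f", names(cg$group_means), cg$group_means),
                  collapse = ", ")))
cat(sprintf("One-way ANOVA: F = %.1f, p = %.3g\n", cg$anova$F, cg$anova$p))
cat("Tukey HSD:\n")
print(cg$tukey, row.names = FALSE)
cat(sprintf("\nRescue restores growth to near the wild-type rate (%.3f vs %.3f per h), while the empty-vector mutant grows far slower (%.3f per h).\n",
            cg$group_means[["mutant_rescued"]], cg$group_means[["WT_EV"]],
            cg$group_means[["mutant_EV"]]))
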