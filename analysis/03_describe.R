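#!/usr/bin/env Rscript
# Stage 3 -- baseline characteristics of the synthetic cohort, compared
# between subjects with and without the primary outcome (Wilcoxon for
# continuous variables, Fisher's exact for binaries), and by marker
# median group.

library(hrcart)

co <- read_cohort("results/cohort.csv")
bt <- baseline_table(co, "event")
write.csv(bt, "results/baseline_by_outcome.csv", row.names = FALSE)
cat("baseline comparison by outcome (head):\n")
print(bt[, c("variable", "type", "n_group1", "n_group0", "test", "p_value")],
      digits = 3)

co$mir_low <- as.numeric(median_split(co$mir133a) == "low")
bt2 <- baseline_table(co, "mir_low",
                      variables = c("event", "age", "log_ntprobnp",
                                    "diabetes", "sixmwd"))
write.csv(bt2, "results/baseline_by_marker_median.csv", row.names = FALSE)
cat("\nevent proportion below vs above the marker median:\n")
ev <- bt2[bt2$variable == "event", ]
cat(sprintf("  %.1f%% vs %.1f%% (Fisher p = %.3g)\n",
            ev$pct_group1, ev$pct_group0, ev$p_value))
cat(sprintf("marker vs peptide Spearman rho = %.3f\n",
            spearman_rho(co$mir133a, co$ntprobnp)))
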