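#!/usr/bin/env Rscript
# Stage 2 -- miRNA discovery arithmetic on a simulated screening run:
# RT-qPCR relative quantification against the miR-486-5p reference,
# log transform, then the >= 1.25-fold / p < 0.1 screening criteria and
# the 80% detection filter used at technical validation.

library(hrcart)
dir.create("results", showWarnings = FALSE)
set.seed(20302)

n_per_group <- 10
mirnas <- c("miR-133a-3p", "miR-501-3p", "miR-106b-3p", "null-A", "null-B")
shift <- c(1 / 1.5, 1 / 1.4, 1 / 1.3, 1, 1)  # case/control mean ratios

# N0 values in arbitrary fluorescence units; reference miR-486-5p per sample
n0_ref <- rlnorm(2 * n_per_group, 2, 0.3)
rq <- sapply(seq_along(mirnas), function(k) {
  n0 <- c(rlnorm(n_per_group, log(shift[k]), 0.25),   # cases
          rlnorm(n_per_group, 0, 0.25)) * n0_ref      # controls
  relative_quantity(n0, n0_ref)
})
colnames(rq) <- mirnas
group <- rep(c("case", "control"), each = n_per_group)

cands <- screen_candidates(rq, group, fc_threshold = 1.25, p_threshold = 0.1)
write.csv(cands, "results/screen_candidates.csv", row.names = FALSE)
cat("screening results (fold change on linear RQ, Wilcoxon p):\n")
print(cands, digits = 3)
cat(sprintf("selected: %s\n",
            paste(cands$transcript[cands$passes], collapse = ", ")))

# detection filter at validation: all assays detected in every sample here
det <- matrix(TRUE, nrow(rq), ncol(rq), dimnames = dimnames(rq))
cat("retained by 80% detection filter:",
    paste(detection_filter(det, 0.8), collapse = ", "), "\n")

# marker median split of the biological-validation cohort
co <- read_cohort("results/cohort.csv")
ms <- median_split(co$mir133a)
cat(sprintf("median split of miR-133a-3p: %d low / %d high (median %.3f)\n",
            sum(ms == "low"), sum(ms == "high"), attr(ms, "median")))
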