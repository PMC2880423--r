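#!/usr/bin/env Rscript

# Cohort-comparison tests for the published training/validation breast-cancer
# tables. The training set (n = 130) and validation set (n = 100) should be
# exchangeable for modeling to transfer; these tests quantify that, and the
# pCR-by-ER-status table shows the strong confounding that makes pCR within
# ER-negative cases the hard endpoint.

suppressMessages(library(aucbench))
dir.create("results", showWarnings = FALSE)

tables <- list(
  pcr_by_cohort   = list(m = matrix(c(33, 97, 15, 85), 2, byrow = TRUE),
                         yates = FALSE),
  er_by_cohort    = list(m = matrix(c(80, 60, 50, 40), 2, byrow = TRUE),
                         yates = FALSE),
  nodal_by_cohort = list(m = matrix(c(39, 27, 60, 47, 14, 13, 17, 13), 4,
                                    byrow = TRUE), yates = FALSE),
  pcr_by_er_training = list(m = matrix(c(27, 23, 6, 74), 2, byrow = TRUE),
                            yates = TRUE)
)

rows <- lapply(names(tables), function(nm) {
  t <- tables[[nm]]
  res <- chi_square_test(t$m, yates = t$yates)
  data.frame(comparison = nm, n = sum(t$m), statistic = res$statistic,
             df = res$df, p_value = res$p_value, yates = t$yates)
})
out <- do.call(rbind, rows)
write.table(out, "results/cohort_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(out, digits = 4)
pcr <- tables$pcr_by_er_training$m
cat(sprintf("\npCR rate: %.1f%% in ER-negative vs %.1f%% in ER-positive training cases\n",
            100 * pcr[1, 1] / sum(pcr[1, ]), 100 * pcr[2, 1] / sum(pcr[2, ])))
cat("The cohorts are balanced on outcome and ER status (p > 0.05),\n",
    "while pCR is strongly associated with ER status (p ~ 1e-8).\n")
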