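#!/usr/bin/env Rscript

# Generates the three synthetic difficulty tiers (easy / moderate / hard) and
# records their ground truth. Raw matrices go to scratch/ (they are large and
# fully reproducible from the seed); results/ receives the world summary.

suppressMessages(library(aucbench))
seed <- 20260928L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/worlds", recursive = TRUE, showWarnings = FALSE)

profs <- preset_profiles()
summ <- lapply(names(profs), function(nm) {
  g <- generate_dataset(profs[[nm]], seed = child_seed(seed, nm))
  write_expression_tsv(g$train,
                       file.path("scratch/worlds", paste0(nm, "_train.tsv")),
                       file.path("scratch/worlds", paste0(nm, "_train_labels.tsv")))
  write_expression_tsv(g$validation,
                       file.path("scratch/worlds", paste0(nm, "_validation.tsv")),
                       file.path("scratch/worlds", paste0(nm, "_validation_labels.tsv")))
  jsonlite::write_json(
    list(informative = g$truth$informative_feature_ids,
         delta = g$truth$delta, bayes_auc = g$truth$bayes_auc),
    file.path("scratch/worlds", paste0(nm, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  data.frame(tier = nm,
             n_train = nrow(g$train$values),
             n_validation = nrow(g$validation$values),
             p = ncol(g$train$values),
             n_informative = length(g$truth$delta),
             prevalence = profs[[nm]]$prevalence,
             max_delta = max(c(0, g$truth$delta)),
             bayes_auc = g$truth$bayes_auc)
})
summ <- do.call(rbind, summ)
write.table(summ, "results/world_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summ, digits = 4)
cat("\nMatrices written under scratch/worlds/ (regenerate with this seed).\n")
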