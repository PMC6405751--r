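#!/usr/bin/env Rscript
# Step 2: rarefaction, the whole-dataset singleton filter, and per-sample
# diversity indices. The generated table is already at uniform depth, so
# rarefaction here is the identity on every column -- the step documents the
# preprocessing a real survey table would undergo and its drop accounting.

suppressPackageStartupMessages(library(occnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

tab <- read_abundance_table("results/abundance.tsv")
cfg <- read_config("results/config.yaml")

rar <- rarefy(tab, depth = cfg$rarefaction_depth, seed = seed)
dropped <- attr(rar, "dropped")
cat(sprintf("rarefied to %d reads/sample: %d samples kept, %d dropped\n",
            cfg$rarefaction_depth, ncol(rar), nrow(dropped)))
if (nrow(dropped)) print(dropped)

filt <- filter_singletons(rar)
cat(sprintf("singleton filter removed %d of %d taxa\n",
            length(attr(filt, "removed")), nrow(rar)))
write_abundance_table(filt, "results/abundance_preprocessed.tsv")

div <- diversity_indices(filt)
write.csv(div, "results/diversity.csv", row.names = FALSE)
md <- read_metadata("results/metadata.tsv")
div$group <- md$group[match(div$sample_id, md$sample_id)]
means <- aggregate(cbind(N0, H, E) ~ group, div, mean)
cat("group mean diversity (N0 = richness, H = Shannon, E = evenness):\n")
print(means, digits = 3)
cat("wrote results/abundance_preprocessed.tsv, results/diversity.csv\n")
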