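#!/usr/bin/env Rscript
# Step 1: generate the synthetic four-group study with planted network
# structure (the stand-in for a rarefied genus-by-sample survey table) and
# write the inputs every later step consumes.

suppressPackageStartupMessages(library(occnet))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L
dir.create("results", showWarnings = FALSE)

study <- default_study_spec()
s <- generate_study(study, seed = seed)

write_abundance_table(s$table, "results/abundance.tsv")
write_metadata(s$metadata, "results/metadata.tsv")
truth_edges <- do.call(rbind, lapply(names(s$truth), function(g) {
  cbind(group = g, s$truth[[g]]$edges)
}))
write.table(truth_edges, "results/truth_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hubs <- data.frame(group = names(s$truth),
                   hub = vapply(s$truth, `[[`, character(1), "hub"))
write.table(hubs, "results/truth_hubs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cfg <- pipeline_config(k_subsample = 30, n_replicates = 20, rng_seed = seed)
write_config(cfg, "results/config.yaml")

cat(sprintf("generated %d taxa x %d samples (seed %d)\n",
            nrow(s$table), ncol(s$table), seed))
for (g in names(s$truth)) {
  e <- s$truth[[g]]$edges
  cat(sprintf("  %-10s %3d planted edges (%d positive, %d negative), hub %s\n",
              g, nrow(e), sum(e$sign == "positive"), sum(e$sign == "negative"),
              s$truth[[g]]$hub))
}
cat("wrote results/abundance.tsv, metadata.tsv, truth_edges.tsv, truth_hubs.tsv, config.yaml\n")
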