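#!/usr/bin/env Rscript
# Spearman screen of every feature against both specific volumes, on the
# simulated panel, and derivation of the scoring weights. Also derives the
# weights implied by the packaged published correlation table for
# comparison: the selection rule (significant in both recipes, aggregation
# and extension families only) picks 12 parameters there, with a maximum
# attainable score of about 113.5.

library(glutenscore)

features <- read.csv("results/features.csv", stringsAsFactors = FALSE)
records <- read.csv("results/panel_samples.csv", stringsAsFactors = FALSE)

ct <- correlation_table(features, records)
w <- select_scored_parameters(ct)
cat("Synthetic panel:", nrow(w), "parameters pass the screen\n")
print(w, n = nrow(w))

pub <- select_scored_parameters(reference_correlations())
cat("\nPublished table:", nrow(pub), "parameters pass the same rule:\n")
cat(paste(pub$parameter, collapse = ", "), "\n")
cat(sprintf("PMT weight %.3f (direction %+d); maximum attainable score %.2f\n",
            pub$weight[pub$parameter == "PMT"],
            pub$direction[pub$parameter == "PMT"], 20 * sum(pub$weight)))

dir.create("results", showWarnings = FALSE)
write.csv(ct, "results/correlations.csv", row.names = FALSE)
write.csv(w, "results/weights_synthetic.csv", row.names = FALSE)
write.csv(pub, "results/weights_published.csv", row.names = FALSE)
cat("Wrote results/correlations.csv and the two weight tables\n")
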