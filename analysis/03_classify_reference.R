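#!/usr/bin/env Rscript
# Classify the packaged 46-sample reference panel into quality classes by
# hierarchical clustering of its two microbaking specific volumes, and
# compare against the published class labels.

library(glutenscore)

vols <- reference_volumes()
sp <- spearman_cor(vols$volume_A_ml_per_g, vols$volume_B_ml_per_g)
cat(sprintf("Between-recipe Spearman correlation: %.3f (p = %.2g)\n",
            sp$r, sp$p))

cl <- cluster_quality(vols)
cat("Cluster sizes:",
    paste(names(cl$counts), as.integer(cl$counts), sep = "=", collapse = ", "),
    "\n")
print(cl$means)

matches <- sum(as.character(cl$labels) == vols$quality_class)
cat(sprintf("Labels agree with the published classes for %d of %d samples\n",
            matches, nrow(vols)))

out <- vols
out$assigned_class <- as.character(cl$labels)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/reference_classes.csv", row.names = FALSE)
cat("Wrote results/reference_classes.csv\n")
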