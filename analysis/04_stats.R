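#!/usr/bin/env Rscript
# Stage 4: group comparison and symptom correlations.
#
# Pooled-variance t tests on every community measure (no multiplicity
# correction, mirroring the reference analysis), then Spearman rank
# correlations between the measures significant at the 1% level and the
# clinical scales, restricted to the patient group.

suppressPackageStartupMessages(library(aecnet))

out <- "results/stats"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read.delim("results/graph/counts.tsv")
scores <- read_scores("results/data/scores.tsv")

rebuild <- function(sub, bn, d) {
  # reassemble a community_edge_counts from the long table
  rows <- counts[counts$subject == sub & counts$band == bn &
                   counts$density == d, ]
  mv <- stats::setNames(rows$count, rows$measure)
  intra <- mv[paste0("intra:", community_names())]
  inter <- mv[paste0("inter:", community_pair_names())]
  structure(list(intra = stats::setNames(as.integer(intra),
                                         community_names()),
                 inter = stats::setNames(as.integer(inter),
                                         community_pair_names()),
                 unassigned_touching = 0L,
                 total_edges = sum(intra) + sum(inter),
                 band = band_spec(bn), density = d),
            class = "community_edge_counts")
}

bands <- unique(counts$band)
subjects <- scores$subject_id
comp_all <- list()
for (bn in bands) {
  cl <- lapply(subjects, rebuild, bn = bn, d = 0.15)
  comp_all[[bn]] <- edgewise_group_comparison(cl, scores$group)
}
comp <- do.call(rbind, comp_all)
write.table(comp, file.path(out, "group_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sig01 <- comp[!comp$undefined & comp$sig01, ]
cat(sprintf("%d of %d measures significant at 5%%, %d at 1%%\n",
            sum(comp$sig05, na.rm = TRUE), sum(!comp$undefined),
            nrow(sig01)))
cat("strongest group differences (t = HC - BD):\n")
top <- comp[order(-abs(comp$t)), ][1:5, c("band", "measure", "t", "p")]
print(top, row.names = FALSE)

measures <- if (nrow(sig01)) unique(sig01$measure) else
  comp$measure[which.max(abs(comp$t))]
cors <- list()
for (bn in bands) {
  cl <- lapply(subjects, rebuild, bn = bn, d = 0.15)
  sc <- symptom_correlations(cl, scores, measures, strict = FALSE)
  sc$band <- bn
  cors[[bn]] <- sc
}
cors <- do.call(rbind, cors)
write.table(cors, file.path(out, "symptom_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwithin-patient symptom correlations for those measures:\n")
print(cors[order(-abs(cors$rho)), ][1:6, ], row.names = FALSE)
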