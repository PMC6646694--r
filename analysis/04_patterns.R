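#!/usr/bin/env Rscript
# Classify the bundled table of 33 significant edges into the three
# connectivity-change patterns, annotate each edge with its network pair,
# and summarise component composition. Writes results/04_patterns/.

suppressMessages(library(fcnbs))

out <- "results/04_patterns"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

t2 <- read_edge_table()
t2$pattern <- classify_edge(t2$mean_patient, t2$mean_control)
t2 <- annotate_between_within(t2, default_partition())

counts <- count_patterns(t2)
cat("pattern counts over", nrow(t2), "edges:\n")
print(counts)
cr <- component_regions(t2)
cat("distinct regions:", length(cr$regions), "\n")
cat("highest-degree regions:\n")
print(head(sort(cr$degree, decreasing = TRUE), 5))
cat("network pairs:\n")
print(table(paste(pmin(t2$network_a, t2$network_b),
                  pmax(t2$network_a, t2$network_b), sep = " | ")))
cat("between-network edges:", sum(t2$scope == "between"), "of", nrow(t2), "\n")

write.table(t2, file.path(out, "edges_classified.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(pattern = names(counts), count = as.integer(counts)),
            file.path(out, "pattern_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
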