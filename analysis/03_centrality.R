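#!/usr/bin/env Rscript

# Stage 3: centrality of the estimated network.
#
# Strength (total absolute edge weight), closeness (inverse summed
# shortest-path distance, distances 1/|w|) and betweenness (fraction of
# shortest paths through the node), raw and min-max scaled so that 1
# marks the most central node.

suppressPackageStartupMessages(library(painnet))

tab <- read_cohort_csv("results/cohort.csv")
flt <- complete_case_filter(tab)
net <- select_network(mixed_matrix(flt$table))$network

cent <- centrality_table(net)
print(cent, digits = 3)

for (index in c("strength", "closeness", "betweenness")) {
  ord <- order(-cent[[index]])
  cat(sprintf("%-12s top: %s (%.3f), then %s (%.3f)\n", index,
              cent$node[ord[1]], cent[[index]][ord[1]],
              cent$node[ord[2]], cent[[index]][ord[2]]))
}

write_centrality_csv(cent, "results/centrality.csv")
cat("Wrote results/centrality.csv\n")
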