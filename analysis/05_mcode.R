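#!/usr/bin/env Rscript
# MCODE molecular complex detection on the first-order network: vertex
# weighting by core-clustering coefficient x highest core number, greedy
# expansion at the default 0.2 vertex weight percentage, haircut on.
suppressPackageStartupMessages(library(seednet))

net_json <- jsonlite::read_json("results/net_first_order.json",
                                simplifyVector = TRUE)
net <- ppi_network(net_json$edges, nodes = net_json$nodes)

cx <- mcode_complexes(net, mcode_params())
tab <- if (length(cx)) {
  do.call(rbind, lapply(seq_along(cx), function(i) {
    data.frame(complex_id = i, score = round(cx[[i]]$score, 3),
               size = length(cx[[i]]$members), seed_node = cx[[i]]$seed_node,
               members = paste(cx[[i]]$members, collapse = ","))
  }))
} else data.frame()
print(tab)
write.table(tab, "results/complexes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d complex(es) detected; top score %.2f",
                length(cx), if (length(cx)) cx[[1]]$score else NA))
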