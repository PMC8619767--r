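#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a two-community weighted interaction
# network (20 + 20 nodes, p_in 0.30, p_out 0.02) with 10 designated seeds per
# community and 2 planted bridge nodes, plus a gene-set collection with 3
# planted enriched terms among 50 decoys. Everything downstream reads these
# files, so the whole workflow runs without any database download.
suppressPackageStartupMessages(library(seednet))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(rng_seed = 17)
sim <- generate_network(spec)
coll <- generate_genesets(sim$truth, rng_seed = 17)

write.table(sim$network$edges, file.path(out, "edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sim$truth$seed_sets[[1]]$members, file.path(out, "seeds_block1.txt"))
writeLines(sim$truth$seed_sets[[2]]$members, file.path(out, "seeds_block2.txt"))
writeLines(c(sim$truth$seed_sets[[1]]$members,
             sim$truth$seed_sets[[2]]$members), file.path(out, "seeds_all.txt"))
write_gmt(coll, file.path(out, "sets.gmt"))
write_report(list(block_of = as.list(sim$truth$block_of),
                  bridges = sim$truth$bridges,
                  planted_terms = attr(coll, "planted_terms")),
             file.path(out, "truth.json"), "json")

message(sprintf("simulated network: %d nodes, %d edges; bridges: %s",
                n_nodes(sim$network), n_edges(sim$network),
                paste(sim$truth$bridges, collapse = ", ")))
message(sprintf("gene sets: %d planted + %d decoys over a %d-gene universe",
                3, 50, coll$universe_size))
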