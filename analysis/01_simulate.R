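#!/usr/bin/env Rscript

# Build the default study scenario: a 50-kb ancestral genome with dense
# gene annotation, 100 mutations dominated by SNPs/small indels, five
# planted proto-gene events (one also expressed in the 34-condition
# library), and 2+2 replicated RNA-seq read evidence. All downstream
# drivers regenerate this scenario deterministically from the same seed;
# this script additionally writes every artifact as plain text.

library(protoscan)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

cfg <- sim_config(seed = seed)
sc <- simulate_scenario(cfg)

message("scenario: ", sc$genome$length, " bp genome, ",
        nrow(sc$mutations), " mutations (",
        sum(sc$mutations$class %in% c("SNP", "INDEL")), " SNP/indel, ",
        sum(sc$mutations$type == "MOB"), " IS insertions, ",
        sum(sc$mutations$class == "DEL"), " large deletions), ",
        nrow(sc$truth), " planted proto-genes of which ",
        sum(sc$truth$condition_expressed), " condition-expressed")
message("evolved genome: ", sc$evolved$map$ev_length, " bp")

out <- file.path("results", "data")
write_scenario(sc, out)
message("wrote scenario artifacts to ", out)
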