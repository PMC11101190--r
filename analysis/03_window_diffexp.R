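#!/usr/bin/env Rscript

# Window-level differential transcription, evolved clone vs ancestor:
# NB Wald test per retained window with BH adjustment, flagging windows
# whose transcription increased significantly (adjusted p < 0.05,
# positive fold change) — the genome-wide signal the candidate cascade
# then ties to individual mutations.

library(protoscan)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
sc <- simulate_scenario(sim_config(seed = seed))
dir.create("results/diffexp", recursive = TRUE, showWarnings = FALSE)

ws <- partition_windows(sc$genome$length, sc$config$window_size)
ws <- filter_windows(ws, list(clone1 = sc$evolved$map),
                     sc$genome$annotations)
ws <- categorize_windows(ws, sc$genome$annotations)

feats <- data.frame(id = ws$windows$id, start = ws$windows$start,
                    end = ws$windows$end, strand = ws$windows$strand)
m <- ws$lifted[match(feats$id, ws$lifted$window_id), ]
evo_feats <- data.frame(id = feats$id, start = m$ev_start, end = m$ev_end,
                        strand = feats$strand)
read_sets <- c(sc$reads$ancestor, sc$reads$evolved)
fbys <- c(replicate(length(sc$reads$ancestor), feats, simplify = FALSE),
          replicate(length(sc$reads$evolved), evo_feats, simplify = FALSE))
names(fbys) <- names(read_sets)
cm <- count_matrix(feats, read_sets, features_by_sample = fbys)

groups <- rep(c("ancestor", "evolved"),
              c(length(sc$reads$ancestor), length(sc$reads$evolved)))
sf <- estimate_size_factors(cm$counts)
disp <- estimate_dispersion(cm$counts, sf, groups)
de <- nb_wald_test(cm$counts, sf, disp, groups)
de$category <- ws$windows$category[match(de$feature, ws$windows$id)]

up <- !is.na(de$padj) & de$padj < 0.05 & de$log2FC > 0
message(sum(up), " of ", sum(de$status == "tested"),
        " tested windows significantly up in the evolved clone (",
        sum(up & de$category != "annotated"), " non-genic)")
sig_ng <- de[up & de$category != "annotated", ]
if (nrow(sig_ng) > 0) {
  near_truth <- vapply(sig_ng$feature, function(id) {
    w <- ws$windows[ws$windows$id == id, ]
    any(sc$truth$strand == w$strand &
          pmax(sc$truth$start, w$start) < pmin(sc$truth$end, w$end))
  }, logical(1))
  message(sum(near_truth), " of those overlap a planted proto-gene region")
}

write.table(de, "results/diffexp/window_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/diffexp/window_de.tsv")
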