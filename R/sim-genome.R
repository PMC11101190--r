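#' Generate a synthetic ancestral genome
#'
#' Places `gene_count` non-overlapping genes (random strand, lengths and
#' intergenic gaps drawn from the configured ranges) on a random nucleotide
#' sequence, annotates at least one repeat region inside an intergenic gap,
#' and records the intergenic gaps themselves. The genome is linear: no
#' annotation or window ever wraps the origin. Deterministic for a fixed
#' seed.
#'
#' @param config A [sim_config()].
#' @return A `genome_record`: list with `name`, `seq` (character), `length`,
#'   `annotations` (data.frame with 0-based half-open `start`/`end`,
#'   `strand`, `type` in gene/repeat, `name`), `gaps` (intergenic
#'   intervals) and `elements` (named character of IS-element sequences).
#' @export
generate_ancestor <- function(config) {
  set.seed(stage_seed(config$seed, "genome"))
  L <- config$genome_length

  # sequential placement guarantees genes are disjoint (stronger than the
  # same-strand requirement, and realistic for small intergenic gaps)
  starts <- integer(config$gene_count)
  ends <- integer(config$gene_count)
  pos <- 0L
  for (i in seq_len(config$gene_count)) {
    gap <- sample(config$intergenic_gap_range[1]:config$intergenic_gap_range[2], 1)
    len <- sample(config$gene_length_range[1]:config$gene_length_range[2], 1)
    starts[i] <- pos + gap
    ends[i] <- starts[i] + len
    if (ends[i] > L) {
      stop("gene placement failure: ", config$gene_count, " genes of ",
           config$gene_length_range[1], "-", config$gene_length_range[2],
           " bp do not fit in ", L, " bp (stuck at gene ", i, ")")
    }
    pos <- ends[i]
  }
  strands <- sample(c("+", "-"), config$gene_count, replace = TRUE)
  genes <- data.frame(
    name = sprintf("gene%03d", seq_len(config$gene_count)),
    start = starts, end = ends, strand = strands, type = "gene",
    stringsAsFactors = FALSE)

  # intergenic gaps (0-based half-open), including the leading/trailing ones
  gap_start <- c(0L, ends)
  gap_end <- c(starts, L)
  gaps <- data.frame(start = gap_start, end = gap_end)
  gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]

  # at least one annotated repeat, placed in the widest interior gap
  rep_len <- 150L
  wide <- gaps[gaps$end - gaps$start >= rep_len + 20L, , drop = FALSE]
  if (nrow(wide) == 0) {
    # fall back: shrink the repeat to fit the widest gap
    wide <- gaps[which.max(gaps$end - gaps$start), , drop = FALSE]
    rep_len <- max(10L, as.integer((wide$end - wide$start) / 2))
  }
  widest <- wide[which.max(wide$end - wide$start), ]
  rep_start <- widest$start + 10L
  repeats <- data.frame(
    name = "repeat001",
    start = rep_start, end = rep_start + rep_len,
    strand = "+", type = "repeat", stringsAsFactors = FALSE)

  ann <- rbind(genes, repeats)
  ann <- ann[order(ann$start), c("name", "start", "end", "strand", "type")]
  rownames(ann) <- NULL

  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  elements <- setNames(
    paste(sample(c("A", "C", "G", "T"), config$is_element_length,
                 replace = TRUE), collapse = ""),
    config$is_element_name)

  structure(list(name = "ancestor", seq = seq, length = L,
                 annotations = ann, gaps = gaps, elements = elements),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$name, ":", x$length, "bp,",
      sum(x$annotations$type == "gene"), "genes,",
      sum(x$annotations$type == "repeat"), "repeat(s)\n")
  invisible(x)
}
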