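#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write annotations or regions as BED6
#'
#' 0-based half-open, strand in column 6; the name column carries
#' `name|type` when a `type` column is present.
#'
#' @param df data.frame with `start`, `end`, `strand` and `name` (or `id`).
#' @param path Output path.
#' @param chrom Chromosome label.
#' @export
write_bed6 <- function(df, path, chrom = "ancestor") {
  nm <- df$name %||% df$id
  if (!is.null(df$type)) nm <- paste(nm, df$type, sep = "|")
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = nm, score = 0L, strand = df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-base coverage as bedGraph (one file per strand)
#'
#' @param cov A list with `plus`/`minus` numeric vectors
#'   ([coverage_from_reads()]).
#' @param prefix Output path prefix; `_plus.bedgraph`/`_minus.bedgraph`
#'   are appended.
#' @param chrom Chromosome label.
#' @export
write_bedgraph <- function(cov, prefix, chrom = "ancestor") {
  for (s in c("plus", "minus")) {
    r <- rle(cov[[s]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    df <- data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
                     value = r$values[keep])
    write.table(df, paste0(prefix, "_", s, ".bedgraph"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Write a count matrix as TSV (feature_id, length, one column per sample)
#' @param cm A `count_matrix` (or matrix plus `lengths`).
#' @param path Output path.
#' @param lengths Feature lengths when `cm` is a bare matrix.
#' @export
write_counts_tsv <- function(cm, path, lengths = NULL) {
  if (inherits(cm, "count_matrix")) {
    lengths <- cm$lengths
    cm <- cm$counts
  }
  df <- data.frame(feature_id = rownames(cm), length = lengths, cm,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every artifact of a simulated scenario to a directory
#'
#' Emits the ancestor and evolved genome FASTA, the IS-element FASTA, the
#' annotation BED6, the mutation list as simplified GenomeDiff, read
#' intervals as BED6 per sample, per-strand bedGraph coverage per sample,
#' the condition-library counts, the planted-truth table, and the config
#' as YAML.
#'
#' @param scenario A `protoscan_scenario`.
#' @param dir Output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(c(ancestor = scenario$genome$seq), file.path(dir, "ancestor.fasta"))
  write_fasta(c(evolved = scenario$evolved$seq), file.path(dir, "evolved.fasta"))
  write_fasta(scenario$genome$elements, file.path(dir, "elements.fasta"))
  write_bed6(scenario$genome$annotations, file.path(dir, "annotations.bed"))
  write_genomediff(scenario$mutations, file.path(dir, "mutations.gd"))
  write_sim_config(scenario$config, file.path(dir, "config.yaml"))
  write.table(scenario$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (grp in names(scenario$reads)) {
    for (s in names(scenario$reads[[grp]])) {
      r <- scenario$reads[[grp]][[s]]
      r$id <- sprintf("read%06d", seq_len(nrow(r)))
      chrom <- if (startsWith(grp, "evolved")) "evolved" else "ancestor"
      write_bed6(r, file.path(dir, paste0(s, ".reads.bed")), chrom = chrom)
      gl <- if (chrom == "evolved") scenario$evolved$map$ev_length else
        scenario$genome$length
      write_bedgraph(coverage_from_reads(r, gl),
                     file.path(dir, paste0(s, ".cov")), chrom = chrom)
    }
  }
  write_counts_tsv(scenario$condition$counts,
                   file.path(dir, "condition_counts.tsv"),
                   lengths = scenario$model$features$length)
  invisible(dir)
}
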