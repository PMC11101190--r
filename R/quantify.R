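#' Count strand-aware read intervals over features (nonunique-all)
#'
#' A read increments every same-strand feature it overlaps by at least
#' 1 bp, so a read spanning the junction of two adjacent features adds one
#' count to each (the htseq-count "nonunique-all" convention). Reads
#' overlapping no feature are tallied as unassigned.
#'
#' @param features data.frame with `id`, `start`, `end` (0-based
#'   half-open), `strand`; coordinates must be in the same genome as the
#'   reads.
#' @param reads data.frame with `start`, `end`, `strand`.
#' @param genome_length Optional; when given, reads outside `[0,
#'   genome_length)` raise an error naming the offending read.
#' @return Integer vector of counts named by feature id, with attribute
#'   `unassigned`.
#' @export
count_reads <- function(features, reads, genome_length = NULL) {
  if (!is.null(genome_length) && nrow(reads) > 0) {
    bad <- which(reads$start < 0 | reads$end > genome_length)
    if (length(bad)) {
      stop("read ", bad[1], " at [", reads$start[bad[1]], ",",
           reads$end[bad[1]], ") lies outside the genome (",
           genome_length, " bp)")
    }
  }
  counts <- setNames(integer(nrow(features)), features$id)
  if (nrow(reads) == 0 || nrow(features) == 0) {
    attr(counts, "unassigned") <- nrow(reads)
    return(counts)
  }
  fg <- GenomicRanges::GRanges("g", as_iranges(features$start, features$end),
                               strand = features$strand)
  rg <- GenomicRanges::GRanges("g", as_iranges(reads$start, reads$end),
                               strand = reads$strand)
  counts[] <- GenomicRanges::countOverlaps(fg, rg, minoverlap = 1,
                                           ignore.strand = FALSE)
  assigned <- GenomicRanges::countOverlaps(rg, fg, minoverlap = 1,
                                           ignore.strand = FALSE) > 0
  attr(counts, "unassigned") <- sum(!assigned)
  counts
}

#' Build a count matrix over features for several samples
#'
#' @param features As in [count_reads()]; may differ per sample (e.g.
#'   lifted clone coordinates) by passing a list in `features_by_sample`.
#' @param read_sets Named list of read data.frames, one per sample.
#' @param features_by_sample Optional named list of per-sample feature
#'   frames (same ids and order as `features`).
#' @param genome_length Optional per-sample length check (scalar or named).
#' @return A `count_matrix`: list with `counts` (features x samples),
#'   `lengths` (ancestral feature lengths) and `samples` (ids).
#' @export
count_matrix <- function(features, read_sets, features_by_sample = NULL,
                         genome_length = NULL) {
  mat <- sapply(names(read_sets), function(s) {
    f <- if (!is.null(features_by_sample)) features_by_sample[[s]] else features
    gl <- if (length(genome_length) > 1) genome_length[[s]] else genome_length
    count_reads(f, read_sets[[s]], gl)
  })
  mat <- matrix(as.integer(mat), nrow = nrow(features),
                dimnames = list(features$id, names(read_sets)))
  structure(list(counts = mat,
                 lengths = setNames(features$end - features$start,
                                    features$id),
                 samples = names(read_sets)),
            class = "count_matrix")
}

#' Normalised read count: counts divided by feature length (bp)
#'
#' @param counts Matrix of counts (features x samples) or a `count_matrix`.
#' @param lengths Feature lengths in bp (ignored for a `count_matrix`).
#' @return Matrix of NRC values.
#' @export
compute_nrc <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  stopifnot(all(lengths >= 1))
  counts / lengths
}

#' Transcripts per million from NRC values
#'
#' `TPM[f, s] = NRC[f, s] / sum_f NRC[f, s] * 1e6`, so every sample column
#' sums to one million. All-zero columns are left at zero with a warning.
#' The normalisation universe is whatever feature set the NRC matrix was
#' built over; window-survey and candidate-detection universes are never
#' mixed.
#'
#' @param nrc NRC matrix from [compute_nrc()].
#' @return TPM matrix.
#' @export
compute_tpm <- function(nrc) {
  cs <- colSums(nrc)
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero sample column(s) left at zero: ",
            paste(colnames(nrc)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  sweep(nrc, 2, cs, "/") * 1e6
}

#' Average TPM over replicate columns within groups
#'
#' @param tpm TPM matrix.
#' @param groups Character vector of group labels, one per column.
#' @return Matrix features x groups of mean TPM.
#' @export
mean_tpm <- function(tpm, groups) {
  stopifnot(length(groups) == ncol(tpm))
  sapply(unique(groups), function(g) {
    rowMeans(tpm[, groups == g, drop = FALSE])
  })
}

#' Tally windows whose mean TPM exceeds each cutoff
#'
#' Comparisons are strict (`>`), so a window sitting exactly at a cutoff is
#' not counted. Non-genic windows are split by gene adjacency.
#'
#' @param mean_tpm_vec Named per-window mean TPM (one group).
#' @param ws A categorised `window_set` whose ids match the names.
#' @param cutoffs Numeric TPM cutoffs (default the relaxed 1 and the
#'   stringent 5).
#' @return data.frame with one row per cutoff x category x adjacency.
#' @export
tally_expressed_windows <- function(mean_tpm_vec, ws, cutoffs = c(1, 5)) {
  w <- ws$windows
  stopifnot(!is.null(w$category))
  tpm <- mean_tpm_vec[w$id]
  out <- list()
  for (ct in cutoffs) {
    pass <- tpm > ct
    for (cat in c("annotated", "antisense", "intergenic")) {
      sel <- w$category == cat
      if (cat == "annotated") {
        out[[length(out) + 1L]] <- data.frame(
          cutoff = ct, category = cat, adjacency = NA_character_,
          n = sum(pass & sel))
      } else {
        for (adj in c(TRUE, FALSE)) {
          out[[length(out) + 1L]] <- data.frame(
            cutoff = ct, category = cat,
            adjacency = if (adj) "gene_adjacent" else "isolated",
            n = sum(pass & sel & w$gene_adjacent %in% adj))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Per-base coverage from read intervals
#'
#' @param reads data.frame with `start`, `end`, `strand`.
#' @param genome_length Genome length in bp.
#' @return List with numeric vectors `plus` and `minus` of per-base depth.
#' @export
coverage_from_reads <- function(reads, genome_length) {
  cov1 <- function(r) {
    if (nrow(r) == 0) return(numeric(genome_length))
    as.numeric(IRanges::coverage(as_iranges(r$start, r$end),
                                 width = genome_length))
  }
  list(plus = cov1(reads[reads$strand == "+", , drop = FALSE]),
       minus = cov1(reads[reads$strand == "-", , drop = FALSE]))
}
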