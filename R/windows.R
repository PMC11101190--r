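#' Partition a genome into fixed-width strand-aware windows
#'
#' Tiles `[0, window_size * floor(L / window_size))` contiguously on both
#' strands; the terminal partial window is dropped. The tiling step equals
#' the window size by default (the window counts this pipeline mirrors are
#' only consistent with tiling, not a 1-bp slide), but a smaller step can
#' be configured.
#'
#' @param genome_length Genome length in bp.
#' @param window_size Window width in bp (default 400).
#' @param step Tiling step in bp (default `window_size`).
#' @return A `window_set`: list with `windows` (data.frame `id`, `start`,
#'   `end`, `strand`), `window_size`, `genome_length`, and (after
#'   filtering/categorisation) `dropped`, `lifted`, and category columns.
#' @export
partition_windows <- function(genome_length, window_size = 400,
                              step = window_size) {
  if (window_size < 1) stop("window_size must be >= 1")
  if (window_size > genome_length) {
    stop("window_size (", window_size, ") exceeds genome length (",
         genome_length, ")")
  }
  starts <- seq(0L, genome_length - window_size, by = step)
  per_strand <- data.frame(start = as.integer(starts),
                           end = as.integer(starts + window_size))
  w <- rbind(cbind(per_strand, strand = "+"),
             cbind(per_strand, strand = "-"))
  w$id <- sprintf("w%s%05d", ifelse(w$strand == "+", "p", "m"),
                  w$start %/% step + 1L)
  w <- w[, c("id", "start", "end", "strand")]
  rownames(w) <- NULL
  structure(list(windows = w, window_size = window_size,
                 genome_length = genome_length,
                 dropped = NULL, lifted = NULL),
            class = "window_set")
}

#' Filter windows against evolved clones and IS/repeat annotations
#'
#' Drops every window that, in any clone, is wholly deleted, or carries a
#' net insertion/deletion larger than `max_indel` bp (default 10), and
#' every window overlapping an annotated IS element or repeat region by at
#' least 1 bp on either strand. Each dropped window records its first
#' triggering reason and clone. The historical "mapped more than once"
#' aligner filter has no analogue under exact liftover without duplication
#' events and is logged as a no-op. Survivors carry lifted coordinates for
#' every clone.
#'
#' @param ws A `window_set`.
#' @param clone_maps Named list of `coord_map`, one per clone.
#' @param annotations Annotation data.frame; rows with `type` in
#'   `is_types` trigger the repeat/IS overlap drop.
#' @param max_indel Largest tolerated net indel inside a window (bp).
#' @param is_types Annotation types treated as IS/repeat.
#' @return The filtered `window_set` with `dropped` and `lifted` tables.
#' @export
filter_windows <- function(ws, clone_maps, annotations,
                           max_indel = 10, is_types = c("repeat", "IS")) {
  w <- ws$windows
  drop_reason <- rep(NA_character_, nrow(w))
  drop_clone <- rep(NA_character_, nrow(w))

  # IS/repeat overlap (>= 1 bp, either strand), checked on the ancestor
  isr <- annotations[annotations$type %in% is_types, , drop = FALSE]
  if (nrow(isr) > 0) {
    ov <- overlaps_any(w$start, w$end, isr$start, isr$end, minoverlap = 1)
    drop_reason[ov] <- "is-overlap"
    drop_clone[ov] <- "ancestor"
  }
  message("window filter: 'mapped more than once' is a no-op under exact ",
          "liftover (no duplication events are supported)")

  lifted <- list()
  for (clone in names(clone_maps)) {
    lf <- lift_intervals(clone_maps[[clone]],
                         w[, c("start", "end"), drop = FALSE])
    lf$window_id <- w$id
    lf$clone <- clone
    lifted[[clone]] <- lf
    gone <- lf$status == "deleted"
    big <- !gone & lf$indel > max_indel
    new_drop <- is.na(drop_reason) & (gone | big)
    drop_reason[new_drop & gone] <- "deleted"
    drop_reason[new_drop & big] <- sprintf("indel>%dbp", max_indel)
    drop_clone[new_drop] <- clone
  }

  keep <- is.na(drop_reason)
  lifted_all <- do.call(rbind, lifted)
  ws$dropped <- data.frame(id = w$id[!keep], reason = drop_reason[!keep],
                           clone = drop_clone[!keep],
                           stringsAsFactors = FALSE)
  ws$lifted <- lifted_all[lifted_all$window_id %in% w$id[keep], , drop = FALSE]
  ws$windows <- w[keep, , drop = FALSE]
  rownames(ws$windows) <- NULL
  ws
}

#' Categorise windows as annotated, antisense, or intergenic
#'
#' A window is `annotated` when it overlaps a same-strand coding gene by
#' strictly more than `genic_overlap` bp (ties at exactly 10 bp stay
#' non-genic); otherwise `antisense` when it overlaps a coding gene on the
#' opposite strand by at least 1 bp (RNA genes do not create antisense
#' status); otherwise `intergenic`. Non-genic windows additionally get a
#' `gene_adjacent` flag when they overlap (>= 1 bp) the `upstream` bp
#' before the start codon or the `downstream` bp after the stop codon of a
#' same-strand gene, modelling transcription initiation before the start
#' and readthrough after the stop. Gene extents are the coding sequence.
#'
#' @param ws A `window_set`.
#' @param annotations Annotation data.frame with `start`, `end`, `strand`,
#'   `type` ("gene" rows are used).
#' @param genic_overlap Strict same-strand overlap threshold (bp).
#' @param upstream,downstream Flank widths (bp) for gene adjacency.
#' @return The `window_set` with `category` and `gene_adjacent` columns.
#' @export
categorize_windows <- function(ws, annotations, genic_overlap = 10,
                               upstream = 300, downstream = 100) {
  w <- ws$windows
  genes <- annotations[annotations$type == "gene", , drop = FALSE]
  if (nrow(genes) > 0 && !all(genes$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in gene annotations: ",
         paste(setdiff(genes$strand, c("+", "-")), collapse = ","))
  }
  if (nrow(w) > 0 && !all(w$strand %in% c("+", "-"))) {
    stop("unknown strand symbol in windows")
  }

  category <- rep("intergenic", nrow(w))
  for (s in c("+", "-")) {
    ssg <- genes[genes$strand == s, , drop = FALSE]
    osg <- genes[genes$strand != s, , drop = FALSE]
    ww <- which(w$strand == s)
    if (length(ww) == 0) next
    same_ov <- max_pair_overlap(w$start[ww], w$end[ww], ssg$start, ssg$end)
    anti_ov <- max_pair_overlap(w$start[ww], w$end[ww], osg$start, osg$end)
    category[ww][same_ov > genic_overlap] <- "annotated"
    category[ww][same_ov <= genic_overlap & anti_ov >= 1] <- "antisense"
  }

  # gene-adjacency flanks (strand-aware, clipped to the genome)
  gene_adjacent <- rep(NA, nrow(w))
  nong <- which(category != "annotated")
  if (length(nong) > 0 && nrow(genes) > 0) {
    up_start <- ifelse(genes$strand == "+", genes$start - upstream, genes$end)
    up_end <- ifelse(genes$strand == "+", genes$start, genes$end + upstream)
    dn_start <- ifelse(genes$strand == "+", genes$end, genes$start - downstream)
    dn_end <- ifelse(genes$strand == "+", genes$end + downstream, genes$start)
    fl <- data.frame(start = pmax(0L, c(up_start, dn_start)),
                     end = pmin(ws$genome_length, c(up_end, dn_end)),
                     strand = c(genes$strand, genes$strand))
    fl <- fl[fl$end > fl$start, , drop = FALSE]
    adj <- logical(length(nong))
    for (s in c("+", "-")) {
      fls <- fl[fl$strand == s, , drop = FALSE]
      sel <- w$strand[nong] == s
      if (any(sel) && nrow(fls) > 0) {
        adj[sel] <- overlaps_any(w$start[nong][sel], w$end[nong][sel],
                                 fls$start, fls$end, minoverlap = 1)
      }
    }
    gene_adjacent[nong] <- adj
  } else if (length(nong) > 0) {
    gene_adjacent[nong] <- FALSE
  }

  ws$windows$category <- category
  ws$windows$gene_adjacent <- gene_adjacent
  ws
}

#' Per-category tallies of a window set
#' @param ws A categorised `window_set`.
#' @return Named integer vector over total/annotated/antisense/intergenic.
#' @export
window_tally <- function(ws) {
  cat_counts <- table(factor(ws$windows$category,
                             levels = c("annotated", "antisense", "intergenic")))
  c(total = nrow(ws$windows),
    setNames(as.integer(cat_counts), names(cat_counts)))
}

# interval helpers on 0-based half-open coordinates, via IRanges
as_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)  # convert to 1-based closed
}

overlaps_any <- function(qs, qe, ss, se, minoverlap = 1) {
  if (length(ss) == 0 || length(qs) == 0) return(rep(FALSE, length(qs)))
  IRanges::overlapsAny(as_iranges(qs, qe), as_iranges(ss, se),
                       minoverlap = minoverlap)
}

# largest single-subject overlap (bp) of each query with any subject
max_pair_overlap <- function(qs, qe, ss, se) {
  out <- numeric(length(qs))
  if (length(ss) == 0 || length(qs) == 0) return(out)
  q <- as_iranges(qs, qe); s <- as_iranges(ss, se)
  hits <- IRanges::findOverlaps(q, s, minoverlap = 1)
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ow <- pmin(qe[qh], se[sh]) - pmax(qs[qh], ss[sh])
  agg <- tapply(ow, qh, max)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set>", nrow(x$windows), "windows of", x$window_size, "bp")
  if (!is.null(x$windows$category)) {
    tb <- table(x$windows$category)
    cat(" (", paste(names(tb), tb, sep = "=", collapse = ", "), ")", sep = "")
  }
  if (!is.null(x$dropped)) cat(";", nrow(x$dropped), "dropped")
  cat("\n")
  invisible(x)
}
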