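#' Extract candidate regions immediately downstream of mutations
#'
#' For every mutation, 100- and 200-bp regions are taken starting at the
#' first base after the mutation's footprint in the evolved genome,
#' extending in the reading direction of each strand. MOB insertions yield
#' regions only on the strand read outward from the element's
#' promoter-bearing end (one region per length); all other mutation types
#' yield regions on both strands. "Immediately downstream" of a deletion
#' is the first base after the evolved junction; of a MOB, the first base
#' after the element including the target-site duplication; of a SNP or
#' insertion, the first base after the variant. Regions running off a
#' genome end are truncated and flagged.
#'
#' @param mutations A `mutation_set`.
#' @param map The clone's `coord_map`.
#' @param genome_length Ancestral genome length (bp).
#' @param lengths Extraction lengths in bp (default 100 and 200).
#' @param clone Clone label carried into the output.
#' @return data.frame of candidate regions: `region_id`, `mutation_id`,
#'   `mutation_type`, `clone`, `strand`, `length`, `anc_start`, `anc_end`
#'   (0-based half-open ancestral), `ev_start`, `ev_end`, `lift_status`,
#'   `truncated`.
#' @export
extract_downstream_regions <- function(mutations, map, genome_length,
                                       lengths = c(100, 200),
                                       clone = "clone1") {
  fp <- mutation_footprints(mutations)
  rows <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    strands <- if (m$type == "MOB") m$strand else c("+", "-")
    for (s in strands) for (len in lengths) {
      reg <- downstream_region(fp[i, ], s, len)
      trunc <- reg$start < 0 || reg$end > genome_length
      st <- max(0L, reg$start)
      en <- min(genome_length, reg$end)
      if (en <= st) next
      lf <- lift_interval(map, st, en)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = paste0(m$id, "_", len,
                           if (s == "+") "p" else "m"),
        mutation_id = m$id, mutation_type = m$type, clone = clone,
        strand = s, length = len, anc_start = st, anc_end = en,
        ev_start = lf$start, ev_end = lf$end, lift_status = lf$status,
        truncated = trunc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(), mutation_id = character(),
               mutation_type = character(), clone = character(),
               strand = character(), length = integer(),
               anc_start = integer(), anc_end = integer(),
               ev_start = integer(), ev_end = integer(),
               lift_status = character(), truncated = logical())
  rownames(out) <- NULL
  out
}

#' Exclude candidates with >10-bp same-strand annotated overlap
#'
#' A region overlapping any annotated RNA gene, protein-coding gene,
#' pseudogene or repeat region by strictly more than `max_overlap` bp on
#' the same strand is excluded; a 10-bp overlap is retained (the boundary
#' goes to retention).
#'
#' @param regions From [extract_downstream_regions()].
#' @param annotations Annotation data.frame; rows with `type` in
#'   `exclude_types` participate.
#' @param max_overlap Strict threshold in bp (default 10).
#' @param exclude_types Annotation types that trigger exclusion.
#' @return `regions` with `overlap_verdict` ("retained"/"excluded") and
#'   `overlap_detail` columns.
#' @export
filter_candidate_overlaps <- function(regions, annotations, max_overlap = 10,
                                      exclude_types = c("gene", "rna",
                                                        "pseudogene", "repeat")) {
  ann <- annotations[annotations$type %in% exclude_types, , drop = FALSE]
  verdict <- rep("retained", nrow(regions))
  detail <- rep(NA_character_, nrow(regions))
  for (s in c("+", "-")) {
    a <- ann[ann$strand == s, , drop = FALSE]
    sel <- which(regions$strand == s)
    if (length(sel) == 0 || nrow(a) == 0) next
    ov <- max_pair_overlap(regions$anc_start[sel], regions$anc_end[sel],
                           a$start, a$end)
    bad <- ov > max_overlap
    verdict[sel][bad] <- "excluded"
    detail[sel][bad] <- sprintf("same-strand overlap %d bp > %d",
                                as.integer(ov[bad]), max_overlap)
  }
  regions$overlap_verdict <- verdict
  regions$overlap_detail <- detail
  regions
}

#' Deduplicate significant regions and drop opposite-strand repeat overlaps
#'
#' Regions appearing more than once (identical ancestral coordinates and
#' strand) keep only the first occurrence in genome order. When adjacent
#' mutations count the same transcription gain twice — distinct candidates
#' overlapping on the same strand — only the candidate with the strongest
#' evidence (smallest adjusted p, ties to genome order) is kept; rows
#' without a `padj` column, or not flagged `carried`, do not participate
#' in that collapse. Regions overlapping a repeat region on the opposite
#' strand by >= 1 bp are removed.
#'
#' @param regions Candidate data.frame (typically the significant subset).
#' @param annotations Annotation data.frame (`type == "repeat"` rows used).
#' @return `regions` with `dedup_verdict` and `dedup_detail` columns.
#' @export
dedup_candidates <- function(regions, annotations) {
  verdict <- rep("retained", nrow(regions))
  detail <- rep(NA_character_, nrow(regions))
  o <- order(regions$anc_start, regions$anc_end, regions$strand)
  key <- paste(regions$anc_start, regions$anc_end, regions$strand)
  dup <- duplicated(key[o])
  verdict[o][dup] <- "excluded"
  detail[o][dup] <- "duplicate region (kept first in genome order)"

  # adjacent-mutation double counts: same-strand overlapping candidates
  active <- which(verdict == "retained" &
                    (regions$carried %||% rep(TRUE, nrow(regions))))
  if (!is.null(regions$padj) && length(active) > 1) {
    # raw p breaks BH-adjusted ties; stronger fold change breaks the rest
    pr <- order(regions$pvalue[active] %||% regions$padj[active],
                -(regions$log2FC[active] %||% 0),
                regions$anc_start[active], na.last = TRUE)
    for (i in seq_along(pr)) {
      a <- active[pr[i]]
      if (verdict[a] != "retained") next
      for (j in seq_along(pr)) {
        if (j <= i) next
        b <- active[pr[j]]
        if (verdict[b] != "retained") next
        if (regions$strand[a] == regions$strand[b] &&
            max(regions$anc_start[a], regions$anc_start[b]) <
              min(regions$anc_end[a], regions$anc_end[b])) {
          verdict[b] <- "excluded"
          detail[b] <- paste0("adjacent mutation counted twice (overlaps ",
                              regions$region_id[a], ")")
        }
      }
    }
  }

  reps <- annotations[annotations$type %in% c("repeat", "IS"), , drop = FALSE]
  for (s in c("+", "-")) {
    opp <- reps[reps$strand != s, , drop = FALSE]
    sel <- which(regions$strand == s & verdict == "retained")
    if (length(sel) == 0 || nrow(opp) == 0) next
    hit <- overlaps_any(regions$anc_start[sel], regions$anc_end[sel],
                        opp$start, opp$end)
    verdict[sel][hit] <- "excluded"
    detail[sel][hit] <- "opposite-strand repeat overlap"
  }
  regions$dedup_verdict <- verdict
  regions$dedup_detail <- detail
  regions
}

#' Quantitative ancestral-silence verdict for a region
#'
#' Replaces visual inspection of coverage plots with a reproducible rule.
#' A region is `silent` when its mean per-base coverage is below
#' `t_silent` in every ancestral replicate and there is no
#' replicate-consistent contiguous run of at least `run_len` bp with
#' coverage >= `run_cov` reads (a qualifying run must appear in every
#' replicate: localized pileups seen in a single replicate of a
#' near-empty region are sampling noise, whereas genuine low-level
#' transcription reproduces across replicates); `expressed` when any
#' replicate's mean reaches `t_expr`; `ambiguous` otherwise. By default `t_silent` is 0.1x the ancestral
#' per-base genome-wide median (floored at 1 read) and `t_expr` is 1.0x
#' that median.
#'
#' @param start,end 0-based half-open ancestral interval.
#' @param strand Region strand ("+"/"-").
#' @param coverage_reps List (one per ancestral replicate) of coverage
#'   lists as returned by [coverage_from_reads()].
#' @param t_silent,t_expr Absolute thresholds; derived from the
#'   genome-wide median when NULL.
#' @param run_len,run_cov Contiguous-run rule parameters.
#' @return List: `verdict`, `mean_coverage` (per replicate), `t_silent`,
#'   `t_expr`.
#' @export
ancestral_silence_check <- function(start, end, strand, coverage_reps,
                                    t_silent = NULL, t_expr = NULL,
                                    run_len = 25, run_cov = 3) {
  if (length(coverage_reps) == 0) stop("no ancestral coverage supplied")
  if (is.null(t_silent) || is.null(t_expr)) {
    allcov <- unlist(lapply(coverage_reps, function(r) c(r$plus, r$minus)))
    med <- median(allcov)
    if (is.null(t_silent)) t_silent <- max(0.1 * med, 1)
    if (is.null(t_expr)) t_expr <- max(1.0 * med, 1)
  }
  track <- if (strand == "+") "plus" else "minus"
  means <- numeric(length(coverage_reps))
  run_in_rep <- logical(length(coverage_reps))
  for (i in seq_along(coverage_reps)) {
    cov <- coverage_reps[[i]][[track]][(start + 1):end]
    means[i] <- mean(cov)
    r <- rle(cov >= run_cov)
    run_in_rep[i] <- any(r$values & r$lengths >= run_len)
  }
  has_run <- all(run_in_rep)
  verdict <- if (all(means < t_silent) && !has_run) "silent"
             else if (any(means >= t_expr)) "expressed"
             else "ambiguous"
  list(verdict = verdict, mean_coverage = means,
       t_silent = t_silent, t_expr = t_expr)
}

#' Cross-condition exclusion screen
#'
#' A region is `seen` when it gathers at least `min_reads` reads in at
#' least one condition of the ancestral expression library (per-condition
#' rule; counts are never pooled across conditions), `unseen` otherwise.
#'
#' @param condition_counts Integer vector of region read counts, one per
#'   condition.
#' @param min_reads Visibility floor (default 3 reads).
#' @return "seen" or "unseen".
#' @export
cross_condition_filter <- function(condition_counts, min_reads = 3) {
  if (any(condition_counts >= min_reads)) "seen" else "unseen"
}

#' Classify the mutational cause of a transcription gain
#'
#' MOB insertions are promoter recruitment by the element's outward-facing
#' promoter. Large deletions (>= `large_del_threshold` bp) that leave an
#' annotated same-strand gene within `promoter_window` bp upstream of the
#' new junction are deletion-mediated translocations to an existing
#' promoter. SNPs and small indels remain promoter-status-unknown.
#'
#' @param mutation One `mutation_set` row.
#' @param region_strand Strand of the gained transcription.
#' @param annotations Annotation data.frame (`type == "gene"` rows used).
#' @param large_del_threshold Minimum size (bp) for the translocation
#'   class (default 1000).
#' @param promoter_window Maximum gap (bp) between the upstream gene and
#'   the junction (default 500).
#' @return A cause label.
#' @export
classify_cause <- function(mutation, region_strand, annotations,
                           large_del_threshold = 1000,
                           promoter_window = 500) {
  if (mutation$type == "MOB") return("promoter in insertion sequence")
  if (mutation$type == "DEL" && !is.na(mutation$size) &&
      mutation$size >= large_del_threshold) {
    genes <- annotations[annotations$type == "gene", , drop = FALSE]
    fp_start <- mutation$position - 1
    fp_end <- fp_start + mutation$size
    found <- if (region_strand == "+") {
      any(genes$strand == "+" & genes$end <= fp_start &
            fp_start - genes$end <= promoter_window)
    } else {
      any(genes$strand == "-" & genes$start >= fp_end &
            genes$start - fp_end <= promoter_window)
    }
    if (found) return("translocation to existing promoter")
    return("unknown (no upstream promoter identified)")
  }
  "point mutation or small indel (promoter status unknown)"
}

#' Find open reading frames on the transcribed strand
#'
#' Scans all three frames of the given (already strand-oriented)
#' nucleotide sequence for ORFs running from an ATG/GTG/TTG start codon to
#' the next in-frame stop codon (stop included in the length). Only ORFs
#' strictly longer than `min_len` bp are reported; one maximal ORF (the
#' earliest start after the previous in-frame stop) is reported per stop
#' codon, and the longest is flagged.
#'
#' @param sequence Nucleotide string on the transcribed strand.
#' @param min_len Strict lower bound on ORF length in bp (default 30).
#' @return data.frame `start`, `end` (0-based half-open in `sequence`),
#'   `frame` (0-2), `length`, `longest`.
#' @export
find_orfs <- function(sequence, min_len = 30) {
  n <- nchar(sequence)
  starts_codons <- c("ATG", "GTG", "TTG")
  stop_codons <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    cod <- substring(sequence, frame + 3 * (seq_len(ncod) - 1) + 1,
                     frame + 3 * seq_len(ncod))
    open_at <- NA_integer_  # codon index of the earliest start since last stop
    for (ci in seq_len(ncod)) {
      if (cod[ci] %in% stop_codons) {
        if (!is.na(open_at)) {
          len <- (ci - open_at + 1) * 3
          if (len > min_len) {
            s0 <- frame + (open_at - 1) * 3
            rows[[length(rows) + 1L]] <- data.frame(
              start = s0, end = s0 + len, frame = frame, length = len)
          }
        }
        open_at <- NA_integer_
      } else if (is.na(open_at) && cod[ci] %in% starts_codons) {
        open_at <- ci
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), frame = integer(),
               length = integer())
  out$longest <- if (nrow(out)) out$length == max(out$length) else logical(0)
  rownames(out) <- NULL
  out
}

#' Scan for ORFs around a proto-gene mutation
#'
#' Extracts the evolved-genome window from `upstream` bp before to
#' `downstream` bp after the start of the gained region, orients it to the
#' transcribed strand, and runs [find_orfs()].
#'
#' @param evolved_seq Evolved genome sequence.
#' @param ev_anchor Evolved 0-based coordinate of the first downstream
#'   base (the region start on "+", the region end on "-").
#' @param strand Transcribed strand.
#' @param upstream,downstream Window extents in bp (defaults 200/500).
#' @param min_len Passed to [find_orfs()].
#' @return As [find_orfs()], on the oriented window.
#' @export
orf_scan_region <- function(evolved_seq, ev_anchor, strand,
                            upstream = 200, downstream = 500, min_len = 30) {
  L <- nchar(evolved_seq)
  if (strand == "+") {
    a <- max(0, ev_anchor - upstream); b <- min(L, ev_anchor + downstream)
    win <- substr(evolved_seq, a + 1, b)
  } else {
    a <- max(0, ev_anchor - downstream); b <- min(L, ev_anchor + upstream)
    win <- revcomp(substr(evolved_seq, a + 1, b))
  }
  find_orfs(win, min_len = min_len)
}
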