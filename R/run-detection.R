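#' Run the full proto-gene detection cascade on a scenario
#'
#' Executes extract -> annotated-overlap filter -> NB Wald differential
#' transcription test on the combined candidate+gene transcriptome ->
#' dedup -> ancestral-silence screen -> cross-condition screen -> cause
#' classification -> ORF scan, keeping a per-candidate filter trail. For
#' each mutation and strand, the 100- and 200-bp variants are both tested
#' and the candidate is carried forward when either is significant
#' (`strict_both_lengths = TRUE` requires both); the 200-bp variant
#' represents the candidate downstream when significant, otherwise the
#' 100-bp one. The same cascade runs on Ribo-seq evidence with
#' `assay = "ribo"`.
#'
#' @param scenario A `protoscan_scenario` (or an equivalent list with
#'   `genome`, `mutations`, `evolved`, `reads`, `condition`).
#' @param assay "rna" or "ribo".
#' @param de_alpha BH-adjusted significance threshold (default 0.05).
#' @param strict_both_lengths Require both extraction lengths significant?
#' @param min_reads_condition Condition-screen visibility floor (reads).
#' @param lengths Extraction lengths (bp).
#' @param max_overlap Strict same-strand annotated-overlap threshold (bp).
#' @param large_del_threshold,promoter_window See [classify_cause()].
#' @param run_len,run_cov See [ancestral_silence_check()].
#' @param orf_min_len See [find_orfs()].
#' @return A `protogene_detection`: list with `report` (one row per
#'   proto-gene), `candidates` (every extracted region with its verdicts),
#'   `de` (the full DE table), `trail` (long filter log), `mutations`,
#'   and `params`.
#' @export
run_detection <- function(scenario, assay = c("rna", "ribo"),
                          de_alpha = 0.05, strict_both_lengths = FALSE,
                          min_reads_condition = 3, lengths = c(100, 200),
                          max_overlap = 10, large_del_threshold = 1000,
                          promoter_window = 500, run_len = 25, run_cov = 3,
                          orf_min_len = 30) {
  assay <- match.arg(assay)
  g <- scenario$genome
  map <- scenario$evolved$map
  anc_key <- if (assay == "rna") "ancestor" else "ancestor_ribo"
  evo_key <- if (assay == "rna") "evolved" else "evolved_ribo"
  if (is.null(scenario$reads[[evo_key]])) {
    stop("scenario carries no ", assay, " read evidence (stage: input)")
  }

  trail <- list()
  note <- function(ids, stage, verdict, detail = NA_character_) {
    if (length(ids) == 0) return(invisible())
    trail[[length(trail) + 1L]] <<- data.frame(
      region_id = ids, stage = stage, verdict = verdict, detail = detail,
      stringsAsFactors = FALSE)
  }

  ## 1. extraction
  regions <- extract_downstream_regions(scenario$mutations, map, g$length,
                                        lengths = lengths)
  note(regions$region_id, "extract", "extracted",
       paste0(regions$length, "bp ", regions$strand))
  gone <- regions$lift_status == "deleted" | is.na(regions$ev_start)
  note(regions$region_id[gone], "liftover", "excluded", "deleted in clone")

  ## 2. annotated-overlap filter (ancestral coordinates)
  regions <- filter_candidate_overlaps(regions, g$annotations,
                                       max_overlap = max_overlap)
  exc <- regions$overlap_verdict == "excluded"
  note(regions$region_id[exc], "overlap_filter", "excluded",
       regions$overlap_detail[exc])
  note(regions$region_id[!exc & !gone], "overlap_filter", "retained")

  tested <- regions[!gone & !exc, , drop = FALSE]
  if (nrow(tested) == 0) {
    return(empty_detection(regions, do.call(rbind, trail), scenario))
  }

  ## 3. combined transcriptome: candidate regions + annotated genes
  genes <- g$annotations[g$annotations$type == "gene", , drop = FALSE]
  glift <- lift_intervals(map, data.frame(start = genes$start,
                                          end = genes$end))
  gkeep <- glift$status != "deleted"
  anc_feats <- rbind(
    data.frame(id = tested$region_id, start = tested$anc_start,
               end = tested$anc_end, strand = tested$strand),
    data.frame(id = genes$name[gkeep], start = genes$start[gkeep],
               end = genes$end[gkeep], strand = genes$strand[gkeep]))
  ev_feats <- rbind(
    data.frame(id = tested$region_id, start = tested$ev_start,
               end = tested$ev_end, strand = tested$strand),
    data.frame(id = genes$name[gkeep], start = glift$ev_start[gkeep],
               end = glift$ev_end[gkeep], strand = genes$strand[gkeep]))

  anc_reads <- scenario$reads[[anc_key]]
  evo_reads <- scenario$reads[[evo_key]]
  read_sets <- c(anc_reads, evo_reads)
  fbys <- c(replicate(length(anc_reads), anc_feats, simplify = FALSE),
            replicate(length(evo_reads), ev_feats, simplify = FALSE))
  names(fbys) <- names(read_sets)
  cm <- count_matrix(anc_feats, read_sets, features_by_sample = fbys)

  groups <- c(rep("ancestor", length(anc_reads)),
              rep("evolved", length(evo_reads)))
  sf <- estimate_size_factors(cm$counts)
  disp <- estimate_dispersion(cm$counts, sf, groups)
  de <- nb_wald_test(cm$counts, sf, disp, groups)

  idx <- match(tested$region_id, de$feature)
  tested$log2FC <- de$log2FC[idx]
  tested$pvalue <- de$pvalue[idx]
  tested$padj <- de$padj[idx]
  tested$de_status <- de$status[idx]
  tested$significant <- !is.na(tested$padj) & tested$padj < de_alpha &
    tested$log2FC > 0 & tested$de_status == "tested"
  note(tested$region_id, "de_test",
       ifelse(tested$significant, "significant", "not-significant"),
       sprintf("log2FC=%.2f padj=%.3g", tested$log2FC, tested$padj))

  ## 4. silence + condition evidence for every tested region
  cov_reps <- lapply(anc_reads, coverage_from_reads,
                     genome_length = g$length)
  allcov <- unlist(lapply(cov_reps, function(r) c(r$plus, r$minus)))
  med <- median(allcov)
  t_silent <- max(0.1 * med, 1)
  t_expr <- max(1.0 * med, 1)
  tested$silence <- vapply(seq_len(nrow(tested)), function(i) {
    ancestral_silence_check(tested$anc_start[i], tested$anc_end[i],
                            tested$strand[i], cov_reps,
                            t_silent = t_silent, t_expr = t_expr,
                            run_len = run_len, run_cov = run_cov)$verdict
  }, character(1))

  cond_counts <- sapply(scenario$condition$reads, function(r) {
    count_reads(data.frame(id = tested$region_id, start = tested$anc_start,
                           end = tested$anc_end, strand = tested$strand), r)
  })
  cond_counts <- matrix(cond_counts, nrow = nrow(tested),
                        dimnames = list(tested$region_id,
                                        names(scenario$condition$reads)))
  tested$condition <- apply(cond_counts, 1, cross_condition_filter,
                            min_reads = min_reads_condition)

  ## 5. per mutation x strand: carry if either (or both) length significant
  key <- paste(tested$mutation_id, tested$strand)
  cand_rows <- list()
  for (k in unique(key)) {
    sub <- tested[key == k, , drop = FALSE]
    sig <- sub$significant
    carried <- if (strict_both_lengths) all(sig) && length(sig) == length(lengths)
               else any(sig)
    rep_row <- if (any(sig)) sub[which.max(sub$length * sig), , drop = FALSE]
               else sub[which.max(sub$length), , drop = FALSE]
    rep_row$carried <- carried
    cand_rows[[k]] <- rep_row
  }
  cands <- do.call(rbind, cand_rows)
  rownames(cands) <- NULL

  ## 6. dedup among carried candidates
  cands <- dedup_candidates(cands, g$annotations)
  dd <- cands$carried & cands$dedup_verdict == "excluded"
  note(cands$region_id[dd], "dedup", "excluded", cands$dedup_detail[dd])

  ## 7. final cascade verdict
  status <- character(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    c_i <- cands[i, ]
    status[i] <- if (!c_i$carried) "excluded: not significant"
      else if (c_i$dedup_verdict == "excluded")
        paste0("excluded: ", c_i$dedup_detail)
      else if (c_i$silence != "silent")
        paste0("excluded: ancestral transcription (", c_i$silence, ")")
      else if (c_i$condition == "seen") "excluded: seen in condition library"
      else "proto-gene"
  }
  cands$final_status <- status
  note(cands$region_id, "final", cands$final_status)

  ## 8. report: cause classification + ORF scan for proto-genes
  pg <- cands[cands$final_status == "proto-gene", , drop = FALSE]
  report <- NULL
  if (nrow(pg) > 0) {
    rows <- list()
    for (i in seq_len(nrow(pg))) {
      p <- pg[i, ]
      m <- scenario$mutations[scenario$mutations$id == p$mutation_id, ]
      cause <- classify_cause(m, p$strand, g$annotations,
                              large_del_threshold = large_del_threshold,
                              promoter_window = promoter_window)
      anchor <- if (p$strand == "+") p$ev_start else p$ev_end
      orfs <- orf_scan_region(scenario$evolved$seq, anchor, p$strand,
                              min_len = orf_min_len)
      rows[[i]] <- data.frame(
        proto_gene_id = paste0("pg_", p$mutation_id, "_",
                               if (p$strand == "+") "p" else "m"),
        clone = p$clone, mutation_id = p$mutation_id,
        start_position_ancestral = p$anc_start + 1L,  # 1-based, report style
        mutation_type = p$mutation_type, strand = p$strand,
        region_length = p$length, cause = cause,
        log2FC = p$log2FC, padj = p$padj,
        orf_count = nrow(orfs),
        orf_longest_bp = if (nrow(orfs)) max(orfs$length) else 0L,
        k12_catalog = NA_character_,  # placeholder for a user-supplied verdict
        stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, rows)
  } else {
    report <- data.frame(proto_gene_id = character(), clone = character(),
                         mutation_id = character(),
                         start_position_ancestral = integer(),
                         mutation_type = character(), strand = character(),
                         region_length = integer(), cause = character(),
                         log2FC = numeric(), padj = numeric(),
                         orf_count = integer(), orf_longest_bp = integer(),
                         k12_catalog = character())
  }

  structure(list(report = report, candidates = cands, regions = regions,
                 tested = tested, de = de, trail = do.call(rbind, trail),
                 condition_counts = cond_counts,
                 mutations = scenario$mutations,
                 params = list(assay = assay, de_alpha = de_alpha,
                               strict_both_lengths = strict_both_lengths,
                               min_reads_condition = min_reads_condition,
                               lengths = lengths, max_overlap = max_overlap,
                               t_silent = t_silent, t_expr = t_expr)),
            class = "protogene_detection")
}

empty_detection <- function(regions, trail, scenario) {
  structure(list(report = data.frame(), candidates = data.frame(),
                 regions = regions, tested = data.frame(),
                 de = data.frame(), trail = trail,
                 condition_counts = matrix(0L, 0, 0),
                 mutations = scenario$mutations, params = list()),
            class = "protogene_detection")
}

#' @export
print.protogene_detection <- function(x, ...) {
  cat("<protogene_detection>", nrow(x$report), "proto-gene(s) from",
      length(unique(x$regions$mutation_id)), "mutations;",
      sum(x$tested$significant %||% FALSE), "significant tested region(s)\n")
  invisible(x)
}

#' Survey downstream regions of every insertion of a named IS element
#'
#' For each MOB insertion of `element`, reports whether its
#' promoter-downstream region gained transcription (either extraction
#' length significant) and whether it was ancestrally silent, with summary
#' counts of the total, the significant, and the significant-and-silent
#' regions.
#'
#' @param detection A `protogene_detection`.
#' @param element Element name (default "IS150").
#' @return List with `table` (one row per insertion) and `summary`
#'   (named counts).
#' @export
survey_is_downstream <- function(detection, element = "IS150") {
  muts <- detection$mutations
  mob <- muts[muts$type == "MOB" & muts$element == element, , drop = FALSE]
  empty <- data.frame(mutation_id = character(), strand = character(),
                      significant = logical(), silence = character())
  if (nrow(mob) == 0) {
    return(list(table = empty,
                summary = c(total = 0L, significant = 0L,
                            significant_and_silent = 0L)))
  }
  tested <- detection$tested
  rows <- list()
  for (i in seq_len(nrow(mob))) {
    sub <- tested[tested$mutation_id == mob$id[i], , drop = FALSE]
    if (nrow(sub) == 0) next
    rep_row <- sub[which.max(sub$length), ]
    rows[[length(rows) + 1L]] <- data.frame(
      mutation_id = mob$id[i], strand = mob$strand[i],
      significant = any(sub$significant), silence = rep_row$silence,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else empty
  list(table = tab,
       summary = c(total = nrow(mob),
                   significant = sum(tab$significant),
                   significant_and_silent = sum(tab$significant &
                                                  tab$silence == "silent")))
}

#' Compare a detection report against the planted truth table
#'
#' Recovery is scored at the region level: a planted event counts as
#' recovered when some reported proto-gene's region overlaps the planted
#' region (>= 1 bp, same strand), and a reported proto-gene counts as a
#' false discovery when its region overlaps no planted region. Region
#' overlap, not mutation identity, is the right unit because two adjacent
#' upstream mutations of the same gained transcript are indistinguishable
#' from read evidence alone (the detection cascade deduplicates them to a
#' single report). Sensitivity is computed over planted events that are
#' not condition-expressed (a condition-expressed plant is correctly
#' excluded by the cross-condition screen); the false-discovery
#' proportion over all reported proto-genes.
#'
#' @param detection A `protogene_detection`.
#' @param truth The scenario's truth table.
#' @return List: `sensitivity`, `fdp`, `n_reported`, `n_eligible`,
#'   `recovered` (logical per eligible truth row), plus
#'   `condition_excluded` ids among reported-or-excluded plants.
#' @export
evaluate_detection <- function(detection, truth) {
  cand <- detection$candidates
  rep_cand <- cand[cand$final_status == "proto-gene", , drop = FALSE]
  hit <- function(tr, rr) {  # same-strand >= 1 bp region overlap
    tr$strand == rr$strand &
      pmax(tr$start, rr$anc_start) < pmin(tr$end, rr$anc_end)
  }
  eligible <- !truth$condition_expressed
  recovered <- vapply(which(eligible), function(i) {
    nrow(rep_cand) > 0 && any(hit(truth[i, ], rep_cand))
  }, logical(1))
  fp <- vapply(seq_len(nrow(rep_cand)), function(j) {
    !any(truth$strand == rep_cand$strand[j] &
           pmax(truth$start, rep_cand$anc_start[j]) <
             pmin(truth$end, rep_cand$anc_end[j]))
  }, logical(1))
  seen_cand <- cand[cand$final_status ==
                      "excluded: seen in condition library", , drop = FALSE]
  cond_exc <- truth$mutation_id[truth$condition_expressed &
    vapply(seq_len(nrow(truth)), function(i) {
      nrow(seen_cand) > 0 && any(hit(truth[i, ], seen_cand))
    }, logical(1))]
  list(sensitivity = if (any(eligible)) mean(recovered) else NA_real_,
       fdp = if (length(fp)) mean(fp) else 0,
       n_reported = nrow(detection$report),
       n_eligible = sum(eligible),
       recovered = recovered,
       condition_excluded = cond_exc)
}
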