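#' Build the per-feature expression model for a synthetic genome
#'
#' The model assigns a mean TPM to every feature in each sample group.
#' Features are the annotated genes (log-normal variation around
#' `baseline_genic_tpm`, identical in ancestor and evolved groups) plus
#' non-genic tiles covering, on each strand, the complement of same-strand
#' genes at `baseline_nongenic_tpm` — a low-but-nonzero background
#' modelling stochastic transcription. A per-feature
#' translation-efficiency factor links Ribo-seq means to transcription
#' means (genes get the configured factor; the non-genic background gets a
#' tenth of it, reflecting that ribosomes rarely engage spurious
#' transcripts).
#'
#' @param genome A `genome_record`.
#' @param config A [sim_config()].
#' @param tile_width Width of non-genic background tiles (bp).
#' @return An `expression_model`: list with `features` (data.frame `id`,
#'   `start`, `end`, `strand`, `type`, `length`), `means` (features x
#'   groups ancestor/evolved), `te` (translation-efficiency factors) and
#'   `cond_read_mean` (per-feature mean reads per condition-library
#'   sample; NA means "derive from the ancestor mean").
#' @export
build_expression_model <- function(genome, config, tile_width = 400) {
  set.seed(stage_seed(config$seed, "model"))
  genes <- genome$annotations[genome$annotations$type == "gene", , drop = FALSE]
  feats <- list(data.frame(id = genes$name, start = genes$start,
                           end = genes$end, strand = genes$strand,
                           type = "gene", stringsAsFactors = FALSE))
  for (s in c("+", "-")) {
    g <- genes[genes$strand == s, , drop = FALSE]
    comp <- interval_complement(g$start, g$end, genome$length)
    tiles <- chop_intervals(comp, tile_width)
    tiles <- tiles[tiles$end - tiles$start >= 20, , drop = FALSE]
    if (nrow(tiles) > 0) {
      feats[[length(feats) + 1L]] <- data.frame(
        id = sprintf("bg%s%04d", if (s == "+") "p" else "m",
                     seq_len(nrow(tiles))),
        start = tiles$start, end = tiles$end, strand = s, type = "background",
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  features$length <- features$end - features$start
  rownames(features) <- NULL

  gene_tpm <- config$baseline_genic_tpm *
    rlnorm(sum(features$type == "gene"), 0, 0.8)
  tpm <- ifelse(features$type == "gene", NA_real_, config$baseline_nongenic_tpm)
  tpm[features$type == "gene"] <- gene_tpm
  means <- cbind(ancestor = tpm, evolved = tpm)
  rownames(means) <- features$id

  te <- ifelse(features$type == "gene", config$translation_efficiency,
               config$translation_efficiency * 0.1)
  structure(list(features = features, means = means,
                 te = setNames(te, features$id),
                 cond_read_mean = setNames(rep(NA_real_, nrow(features)),
                                           features$id)),
            class = "expression_model")
}

interval_complement <- function(starts, ends, L) {
  if (length(starts) == 0) return(data.frame(start = 0L, end = L))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  gs <- c(0L, ends); ge <- c(starts, L)
  out <- data.frame(start = gs, end = ge)
  out[out$end > out$start, , drop = FALSE]
}

chop_intervals <- function(iv, width) {
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    st <- seq(iv$start[i], iv$end[i] - 1, by = width)
    rows[[i]] <- data.frame(start = st, end = pmin(st + width, iv$end[i]))
  }
  do.call(rbind, rows)
}

#' Plant proto-gene events into an expression model
#'
#' Chooses `planted_protogene_count` mutations whose downstream region (of
#' `plant_region_length` bp, on the element strand for MOB records and a
#' random eligible strand otherwise) is ancestrally silent — at most 10 bp
#' same-strand overlap with genes, no repeat overlap on either strand, and
#' no other mutation footprint inside — and raises the evolved-group mean
#' of that region from the near-zero ancestral background by
#' `planted_fold_change`. For MOB events only the promoter-side strand is
#' raised. A configurable number of planted regions is additionally given
#' expression in the condition library, to exercise the cross-condition
#' exclusion filter. With `planted_fold_change = 1` the model is unchanged
#' except for bookkeeping.
#'
#' @param mutations A `mutation_set`.
#' @param model An `expression_model`.
#' @param genome The `genome_record` the mutations refer to.
#' @param config A [sim_config()].
#' @return List with the updated `model` and `truth` (data.frame
#'   `plant_id`, `mutation_id`, `start`, `end`, `strand`, `fold`,
#'   `condition_expressed`).
#' @export
plant_protogenes <- function(mutations, model, genome, config) {
  set.seed(stage_seed(config$seed, "plant"))
  n_want <- config$planted_protogene_count
  if (n_want == 0) {
    return(list(model = model,
                truth = data.frame(plant_id = character(),
                                   mutation_id = character(),
                                   start = integer(), end = integer(),
                                   strand = character(), fold = numeric(),
                                   condition_expressed = logical())))
  }
  len <- config$plant_region_length
  fp <- mutation_footprints(mutations)
  genes <- genome$annotations[genome$annotations$type == "gene", , drop = FALSE]
  reps <- genome$annotations[genome$annotations$type %in% c("repeat", "IS"), ,
                             drop = FALSE]

  eligible <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    f <- fp[i, ]
    strands <- if (m$type == "MOB") m$strand else sample(c("+", "-"))
    for (s in strands) {
      reg <- downstream_region(f, s, len)
      if (reg$start < 0 || reg$end > genome$length) next
      ssg <- genes[genes$strand == s, , drop = FALSE]
      if (max_pair_overlap(reg$start, reg$end, ssg$start, ssg$end) > 10) next
      if (nrow(reps) > 0 &&
          overlaps_any(reg$start, reg$end, reps$start, reps$end)) next
      others <- fp[-i, , drop = FALSE]
      if (nrow(others) > 0 &&
          any(pmax(others$fp_start, reg$start) <
                pmin(others$fp_end, reg$end))) next
      eligible[[length(eligible) + 1L]] <- data.frame(
        mutation_id = m$id, start = reg$start, end = reg$end, strand = s,
        stringsAsFactors = FALSE)
      break  # one strand per mutation
    }
  }
  eligible <- do.call(rbind, eligible)
  # drop mutations whose region overlaps an earlier pick (same strand)
  if (!is.null(eligible)) {
    keep <- rep(TRUE, nrow(eligible))
    for (i in seq_len(nrow(eligible))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(eligible)) > i &
                       eligible$strand == eligible$strand[i] &
                       pmax(eligible$start, eligible$start[i]) <
                         pmin(eligible$end, eligible$end[i]))
      keep[later] <- FALSE
    }
    eligible <- eligible[keep, , drop = FALSE]
  }
  n_have <- if (is.null(eligible)) 0L else nrow(eligible)
  if (n_have < n_want) {
    stop("cannot plant ", n_want, " proto-genes: only ", n_have,
         " mutations have an eligible silent downstream region")
  }
  picks <- eligible[sample.int(n_have, n_want), , drop = FALSE]
  picks <- picks[order(picks$start), , drop = FALSE]

  # the planted feature supersedes the local stochastic background: zero
  # out background tiles under a planted region so its ancestral mean is
  # the configured near-zero baseline, not twice it
  bg <- model$features$type == "background"
  for (i in seq_len(nrow(picks))) {
    under <- bg & model$features$strand == picks$strand[i] &
      pmax(model$features$start, picks$start[i]) <
        pmin(model$features$end, picks$end[i])
    model$means[under, ] <- 0
  }

  anc <- config$baseline_nongenic_tpm
  add <- data.frame(id = sprintf("plant%02d_%s", seq_len(n_want),
                                 picks$mutation_id),
                    start = picks$start, end = picks$end,
                    strand = picks$strand, type = "planted",
                    stringsAsFactors = FALSE)
  add$length <- add$end - add$start
  model$features <- rbind(model$features, add)
  model$means <- rbind(model$means,
                       matrix(c(rep(anc, n_want),
                                rep(anc * config$planted_fold_change, n_want)),
                              ncol = 2, dimnames = list(add$id,
                                                        c("ancestor", "evolved"))))
  model$te <- c(model$te, setNames(rep(0, n_want), add$id))
  cond <- setNames(rep(0, n_want), add$id)
  n_cond <- min(config$condition_expressed_count, n_want)
  cond_idx <- if (n_cond > 0) sample.int(n_want, n_cond) else integer(0)
  cond[cond_idx] <- config$condition_expressed_mean
  model$cond_read_mean <- c(model$cond_read_mean, cond)

  truth <- data.frame(plant_id = add$id, mutation_id = picks$mutation_id,
                      start = add$start, end = add$end, strand = add$strand,
                      fold = config$planted_fold_change,
                      condition_expressed = seq_len(n_want) %in% cond_idx,
                      stringsAsFactors = FALSE)
  list(model = model, truth = truth)
}

# downstream region of a mutation footprint in ancestral 0-based
# coordinates: first base after the footprint for '+', the `len` bases
# before it (read leftward) for '-'
downstream_region <- function(fp_row, strand, len) {
  if (strand == "+") {
    list(start = fp_row$fp_end, end = fp_row$fp_end + len)
  } else {
    list(start = fp_row$fp_start - len, end = fp_row$fp_start)
  }
}
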