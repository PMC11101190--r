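#' Simulate NB read counts and read intervals for one sample group
#'
#' Expected counts follow the model's TPM means: feature f in group g
#' receives `library_size * tpm[f,g] * length[f] / sum(tpm[,g] * length)`
#' expected reads, and counts are drawn NB2 (`var = mu + alpha mu^2`);
#' `dispersion = 0` gives the Poisson limit. Each counted read is
#' materialised as a strand-aware interval placed uniformly inside its
#' feature, so per-base coverage and count matrices describe the same read
#' mass. For Ribo-seq samples the means are multiplied by the per-feature
#' translation-efficiency factor before normalisation.
#'
#' @param model An `expression_model`.
#' @param config A [sim_config()].
#' @param group "ancestor" or "evolved".
#' @param n_samples Number of replicate samples.
#' @param assay "rna" or "ribo".
#' @param seed Seed for this draw.
#' @param prefix Sample-name prefix.
#' @return List with `counts` (features x samples) and `reads` (named list
#'   of data.frames `start`, `end`, `strand` in ancestral coordinates).
#' @export
simulate_counts <- function(model, config, group = "ancestor",
                            n_samples = config$replicates, assay = "rna",
                            seed = stage_seed(config$seed, "counts"),
                            prefix = paste0(substr(group, 1, 3), "_", assay)) {
  if (config$dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  f <- model$features
  stopifnot(all(f$length > 0))
  tpm <- model$means[, group]
  if (assay == "ribo") tpm <- tpm * model$te
  w <- tpm * f$length
  lam <- if (sum(w) > 0) w / sum(w) * config$library_size else w
  counts <- matrix(0L, nrow(f), n_samples,
                   dimnames = list(f$id, paste0(prefix, "_", seq_len(n_samples))))
  reads <- list()
  for (j in seq_len(n_samples)) {
    k <- draw_nb(lam, config$dispersion)
    counts[, j] <- k
    reads[[colnames(counts)[j]]] <- place_reads(f, k, config$read_length)
  }
  list(counts = counts, reads = reads)
}

draw_nb <- function(mu, alpha) {
  if (alpha < 1e-12) rpois(length(mu), mu) else
    rnbinom(length(mu), mu = mu, size = 1 / alpha)
}

place_reads <- function(features, k, read_length) {
  idx <- rep(seq_len(nrow(features)), k)
  if (length(idx) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  fs <- features$start[idx]
  fe <- features$end[idx]
  rl <- pmin(read_length, fe - fs)
  start <- fs + floor(runif(length(idx)) * (fe - fs - rl + 1))
  data.frame(start = as.integer(start), end = as.integer(start + rl),
             strand = features$strand[idx], stringsAsFactors = FALSE)
}

#' Simulate the ancestral-genotype condition expression library
#'
#' One sample per environmental condition (default 34), all with the
#' ancestor genotype. Features with an explicit `cond_read_mean` (planted
#' regions: 0, or `condition_expressed_mean` for the configured
#' condition-expressed subset) receive that absolute mean read count per
#' condition; all other features scale their ancestor TPM to
#' `condition_library_size` reads.
#'
#' @param model An `expression_model`.
#' @param config A [sim_config()].
#' @return List with `counts` (features x conditions) and `reads` (list of
#'   read data.frames per condition, ancestral coordinates).
#' @export
simulate_condition_library <- function(model, config) {
  set.seed(stage_seed(config$seed, "conditions"))
  f <- model$features
  w <- model$means[, "ancestor"] * f$length
  lam <- if (sum(w) > 0) w / sum(w) * config$condition_library_size else w
  fixed <- !is.na(model$cond_read_mean)
  lam[fixed] <- model$cond_read_mean[fixed]
  cn <- sprintf("cond%02d", seq_len(config$condition_count))
  counts <- matrix(0L, nrow(f), config$condition_count,
                   dimnames = list(f$id, cn))
  reads <- list()
  for (j in seq_len(config$condition_count)) {
    k <- draw_nb(lam, config$dispersion)
    counts[, j] <- k
    reads[[cn[j]]] <- place_reads(f, k, config$read_length)
  }
  list(counts = counts, reads = reads)
}

# vectorised ancestral -> evolved position mapping (0-based positions);
# returns NA for deleted positions
map_positions <- function(map, pos) {
  seg <- map$segments[order(map$segments$anc_start), , drop = FALSE]
  idx <- findInterval(pos, seg$anc_start)
  idx[idx < 1] <- NA
  out <- rep(NA_real_, length(pos))
  ok <- !is.na(idx) & pos < seg$anc_end[idx] & seg$status[idx] == "mapped"
  out[ok] <- pos[ok] - seg$anc_start[idx[ok]] + seg$ev_start[idx[ok]]
  out
}

# lift read intervals from ancestral to evolved coordinates; reads whose
# first or last base is deleted are dropped (coverage and counts are
# recomputed from the surviving read set, so mass stays consistent)
lift_reads <- function(map, reads) {
  if (nrow(reads) == 0) return(reads)
  s <- map_positions(map, reads$start)
  e <- map_positions(map, reads$end - 1L)
  keep <- !is.na(s) & !is.na(e) & e >= s
  data.frame(start = as.integer(s[keep]), end = as.integer(e[keep] + 1),
             strand = reads$strand[keep], stringsAsFactors = FALSE)
}

#' Simulate a complete study scenario with planted ground truth
#'
#' Runs the full generator chain: ancestral genome and annotations,
#' mutation set, evolved clone sequence plus coordinate map, expression
#' model with planted proto-gene events, replicated RNA-seq (and
#' optionally Ribo-seq) read evidence for the ancestor and the evolved
#' clone, and the ancestral-genotype condition library. Evolved-sample
#' reads are generated against the evolved expression means in ancestral
#' coordinates and lifted exactly onto the evolved genome. Identical
#' config and seed give identical output.
#'
#' @param config A [sim_config()].
#' @return A `protoscan_scenario`: list with `config`, `genome`,
#'   `mutations`, `evolved` (`seq`, `map`), `model`, `truth`, `reads`
#'   (named lists `ancestor`, `evolved`, and `ancestor_ribo`,
#'   `evolved_ribo` when enabled; evolved reads are in evolved
#'   coordinates) and `condition` (`counts`, `reads`).
#' @export
simulate_scenario <- function(config) {
  genome <- generate_ancestor(config)
  mutations <- sample_mutations(genome, config)
  evolved <- apply_mutations(genome, mutations)
  model <- build_expression_model(genome, config)
  planted <- plant_protogenes(mutations, model, genome, config)
  model <- planted$model

  anc <- simulate_counts(model, config, "ancestor",
                         seed = stage_seed(config$seed, "counts"))
  evo <- simulate_counts(model, config, "evolved",
                         seed = stage_seed(config$seed, "counts") + 1L)
  evo_reads <- lapply(evo$reads, function(r) lift_reads(evolved$map, r))

  reads <- list(ancestor = anc$reads, evolved = evo_reads)
  if (isTRUE(config$simulate_ribo)) {
    anc_r <- simulate_counts(model, config, "ancestor", assay = "ribo",
                             seed = stage_seed(config$seed, "ribo"))
    evo_r <- simulate_counts(model, config, "evolved", assay = "ribo",
                             seed = stage_seed(config$seed, "ribo") + 1L)
    reads$ancestor_ribo <- anc_r$reads
    reads$evolved_ribo <- lapply(evo_r$reads,
                                 function(r) lift_reads(evolved$map, r))
  }

  condition <- simulate_condition_library(model, config)

  structure(list(config = config, genome = genome, mutations = mutations,
                 evolved = evolved, model = model, truth = planted$truth,
                 reads = reads, condition = condition),
            class = "protoscan_scenario")
}

#' @export
print.protoscan_scenario <- function(x, ...) {
  cat("<protoscan_scenario>", x$genome$length, "bp genome,",
      nrow(x$mutations), "mutations,", nrow(x$truth), "planted event(s),",
      length(x$reads$ancestor), "+", length(x$reads$evolved),
      "RNA samples,", ncol(x$condition$counts), "conditions\n")
  invisible(x)
}
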