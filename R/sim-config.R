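#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the study conditions the pipeline is built for: a compact
#' bacterial genome fragment with dense gene annotation and small intergenic
#' gaps, a mutation spectrum in which SNPs and small indels carry over 95%
#' of the mass with rarer mobile-element (IS) insertions and large
#' deletions, negative-binomial read counts with 2 replicates per group, a
#' 1,443-bp IS element with an outward-facing promoter, and a 34-condition
#' expression library of the ancestral genotype used for the
#' cross-condition exclusion screen.
#'
#' @param genome_length Ancestral genome length in bp.
#' @param gene_count Number of protein-coding genes to place.
#' @param gene_length_range Length range (bp) genes are drawn from.
#' @param intergenic_gap_range Range (bp) of gaps between consecutive genes.
#' @param mutation_count Number of mutations per evolved clone.
#' @param class_weights Named proportions over mutation classes
#'   `SNP`, `INDEL` (small insertion/deletion, 1-10 bp), `MOB`
#'   (IS-element insertion) and `DEL` (large deletion). Must sum to 1;
#'   the default puts 0.957 on SNP+INDEL.
#' @param is_element_length Length (bp) of the mobile IS element (1,443 bp,
#'   an IS150-like element carrying an outward-facing promoter).
#' @param is_element_name Name of the IS element.
#' @param planted_protogene_count Number of mutations whose downstream
#'   region is given a transcription gain (the planted ground truth).
#' @param planted_fold_change Fold increase of the evolved-group mean over
#'   the near-zero ancestral mean for planted regions (dimensionless, >= 1).
#' @param baseline_genic_tpm Mean TPM of annotated genes (log-normal
#'   variation is applied around it).
#' @param baseline_nongenic_tpm Low-but-nonzero TPM of non-genic positions,
#'   modelling stochastic background transcription.
#' @param dispersion Negative-binomial dispersion alpha in the NB2
#'   parameterisation `var = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param library_size Reads per RNA-seq/Ribo-seq sample.
#' @param condition_library_size Reads per condition-library sample.
#' @param replicates Replicates per group (>= 2; the evolved-vs-ancestor
#'   comparisons use 2, time-series style designs use 3).
#' @param condition_count Number of environmental conditions in the
#'   ancestral expression library (default 34).
#' @param condition_expressed_count How many planted regions are also
#'   expressed in the condition library (to exercise the exclusion filter).
#' @param condition_expressed_mean Mean read count, per condition, of a
#'   condition-expressed planted region.
#' @param read_length Length (bp) of simulated read intervals.
#' @param plant_region_length Length (bp) of the planted downstream region.
#' @param small_indel_range Size range (bp) of small insertions/deletions.
#' @param large_del_range Size range (bp) of large deletions.
#' @param tsd_size Target-site duplication (bp) of MOB insertions.
#' @param window_size Window width (bp) for the window transcriptome.
#' @param translation_efficiency Ribo-seq mean = RNA mean x this factor,
#'   applied to all features.
#' @param simulate_ribo Also generate Ribo-seq evidence?
#' @param seed Master seed; per-stage streams are derived from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(genome_length = 50000,
                       gene_count = 40,
                       gene_length_range = c(400, 1200),
                       intergenic_gap_range = c(50, 400),
                       mutation_count = 100,
                       class_weights = c(SNP = 0.807, INDEL = 0.15,
                                         MOB = 0.03, DEL = 0.013),
                       is_element_length = 1443,
                       is_element_name = "IS150",
                       planted_protogene_count = 5,
                       planted_fold_change = 50,
                       baseline_genic_tpm = 20,
                       baseline_nongenic_tpm = 0.02,
                       dispersion = 0.1,
                       library_size = 3e5,
                       condition_library_size = 2e4,
                       replicates = 2,
                       condition_count = 34,
                       condition_expressed_count = 1,
                       condition_expressed_mean = 30,
                       read_length = 30,
                       plant_region_length = 200,
                       small_indel_range = c(1, 10),
                       large_del_range = c(1000, 8000),
                       tsd_size = 3,
                       window_size = 400,
                       translation_efficiency = 1,
                       simulate_ribo = FALSE,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_length >= 1, cfg$gene_count >= 1,
            length(cfg$gene_length_range) == 2,
            length(cfg$intergenic_gap_range) == 2,
            cfg$mutation_count >= 0,
            cfg$is_element_length >= 1,
            cfg$planted_fold_change >= 1,
            cfg$dispersion >= 0,
            cfg$replicates >= 2,
            cfg$condition_count >= 1,
            cfg$tsd_size >= 0)
  if (is.null(names(cfg$class_weights)) ||
      !setequal(names(cfg$class_weights), c("SNP", "INDEL", "MOB", "DEL"))) {
    stop("class_weights must be named SNP, INDEL, MOB, DEL")
  }
  if (abs(sum(cfg$class_weights) - 1) > 1e-8) {
    stop("class_weights must sum to 1 (got ", sum(cfg$class_weights), ")")
  }
  if (any(cfg$class_weights < 0)) stop("class_weights must be non-negative")
  if (cfg$planted_protogene_count > cfg$mutation_count) {
    stop("planted_protogene_count exceeds mutation_count")
  }
  if (cfg$genome_length < 10 * max(cfg$gene_length_range)) {
    stop("genome_length must be at least 10x the maximum gene length")
  }
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$class_weights <- as.list(out$class_weights)  # keep names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$class_weights <- unlist(raw$class_weights)
  do.call(sim_config, raw)
}
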