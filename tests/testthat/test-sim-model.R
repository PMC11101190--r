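test_that("the expression model covers genes and non-genic background", {
  cfg <- sim_config(seed = 1)
  g <- generate_ancestor(cfg)
  mo <- build_expression_model(g, cfg)
  expect_setequal(unique(mo$features$type), c("gene", "background"))
  expect_true(all(mo$means >= 0))
  expect_true(all(mo$features$length > 0))
  # genes express orders of magnitude above the non-genic background
  gm <- mo$means[mo$features$type == "gene", "ancestor"]
  bm <- mo$means[mo$features$type == "background", "ancestor"]
  expect_gt(min(gm) / max(bm), 10)
})

test_that("planting raises the evolved mean by the configured fold", {
  cfg <- sim_config(seed = 2, baseline_nongenic_tpm = 0.1,
                    planted_fold_change = 50, planted_protogene_count = 5)
  g <- generate_ancestor(cfg)
  m <- sample_mutations(g, cfg)
  res <- plant_protogenes(m, build_expression_model(g, cfg), g, cfg)
  pl <- res$model$features$type == "planted"
  expect_equal(sum(pl), 5)
  expect_equal(unname(res$model$means[pl, "ancestor"]), rep(0.1, 5))
  expect_equal(unname(res$model$means[pl, "evolved"]), rep(5.0, 5))
  # truth-table completeness: each planted region in exactly one record
  expect_equal(nrow(res$truth), 5)
  expect_equal(anyDuplicated(res$truth[, c("start", "end", "strand")]), 0)
  expect_true(all(res$truth$mutation_id %in% m$id))
})

test_that("fold change 1 leaves planted means at the ancestral level", {
  cfg <- sim_config(seed = 3, planted_fold_change = 1)
  g <- generate_ancestor(cfg)
  m <- sample_mutations(g, cfg)
  res <- plant_protogenes(m, build_expression_model(g, cfg), g, cfg)
  pl <- res$model$features$type == "planted"
  expect_equal(res$model$means[pl, "evolved"], res$model$means[pl, "ancestor"])
})

test_that("a planted MOB raises only the promoter-side strand", {
  cfg <- sim_config(seed = 4, mutation_count = 30, planted_protogene_count = 8,
                    class_weights = c(SNP = 0.2, INDEL = 0.1, MOB = 0.6,
                                      DEL = 0.1))
  g <- generate_ancestor(cfg)
  m <- sample_mutations(g, cfg)
  before <- build_expression_model(g, cfg)
  res <- plant_protogenes(m, before, g, cfg)
  mobs <- res$truth[res$truth$mutation_id %in% m$id[m$type == "MOB"], ]
  expect_gt(nrow(mobs), 0)
  for (i in seq_len(nrow(mobs))) {
    mut <- m[m$id == mobs$mutation_id[i], ]
    expect_equal(mobs$strand[i], mut$strand)
    # the opposite strand carries no planted feature over this span
    f <- res$model$features
    opp <- f$type == "planted" & f$strand != mobs$strand[i] &
      pmax(f$start, mobs$start[i]) < pmin(f$end, mobs$end[i])
    expect_false(any(opp))
  }
  # opposite-strand background means are untouched by planting
  f <- res$model$features
  ob <- f$type == "background" & f$strand != mobs$strand[1] &
    pmax(f$start, mobs$start[1]) < pmin(f$end, mobs$end[1])
  if (any(ob)) {
    expect_equal(res$model$means[which(ob), ],
                 before$means[rownames(res$model$means)[which(ob)], ,
                              drop = FALSE][, ] ,
                 ignore_attr = TRUE)
  }
})

test_that("planting fails loudly when too few mutations are eligible", {
  cfg <- sim_config(seed = 5, mutation_count = 2, planted_protogene_count = 2,
                    genome_length = 30000, gene_count = 3,
                    gene_length_range = c(2500, 3000),
                    intergenic_gap_range = c(5000, 8000))
  g <- generate_ancestor(cfg)
  m <- sample_mutations(g, cfg)
  cfg2 <- cfg; cfg2$planted_protogene_count <- 50
  cfg2$mutation_count <- 50
  expect_error(plant_protogenes(m, build_expression_model(g, cfg), g, cfg2),
               "eligible")
})

test_that("counts follow the NB moments and the Poisson limit", {
  cfg <- sim_config(seed = 6)
  # synthetic single-feature universe keeps the moment algebra exact
  mo <- structure(list(
    features = data.frame(id = sprintf("f%05d", 1:10000), start = 0,
                          end = 200, strand = "+", type = "gene",
                          length = 200),
    means = matrix(1, 10000, 2,
                   dimnames = list(sprintf("f%05d", 1:10000),
                                   c("ancestor", "evolved"))),
    te = setNames(rep(1, 10000), sprintf("f%05d", 1:10000)),
    cond_read_mean = setNames(rep(NA_real_, 10000),
                              sprintf("f%05d", 1:10000))),
    class = "expression_model")
  cfg$library_size <- 10000 * 20  # mean 20 per feature
  cfg$dispersion <- 0.1
  sim <- simulate_counts(mo, cfg, "ancestor", n_samples = 2, seed = 11)
  k <- as.vector(sim$counts)
  expect_equal(mean(k), 20, tolerance = 0.02)
  expect_equal(var(k) / mean(k), 1 + 0.1 * 20, tolerance = 0.1)
  # Poisson limit
  cfg$dispersion <- 0
  simp <- simulate_counts(mo, cfg, "ancestor", n_samples = 2, seed = 12)
  kp <- as.vector(simp$counts)
  expect_equal(var(kp) / mean(kp), 1, tolerance = 0.05)
  # zero-mean features draw zero counts in all replicates
  mo$means[1:100, ] <- 0
  simz <- simulate_counts(mo, cfg, "ancestor", n_samples = 3, seed = 13)
  expect_true(all(simz$counts[1:100, ] == 0))
  cfg_bad <- cfg; cfg_bad$dispersion <- -1
  expect_error(simulate_counts(mo, cfg_bad), "dispersion")
})

test_that("reads land inside their features and carry the count mass", {
  cfg <- sim_config(seed = 7)
  g <- generate_ancestor(cfg)
  mo <- build_expression_model(g, cfg)
  sim <- simulate_counts(mo, cfg, "ancestor", n_samples = 1, seed = 21)
  r <- sim$reads[[1]]
  expect_equal(nrow(r), sum(sim$counts[, 1]))
  expect_true(all(r$start >= 0 & r$end <= g$length & r$end > r$start))
  cov <- coverage_from_reads(r, g$length)
  expect_equal(sum(cov$plus) + sum(cov$minus), sum(r$end - r$start))
})

test_that("the condition library has one column per condition", {
  cfg <- sim_config(seed = 8, condition_count = 34,
                    condition_expressed_count = 0)
  g <- generate_ancestor(cfg)
  m <- sample_mutations(g, cfg)
  res <- plant_protogenes(m, build_expression_model(g, cfg), g, cfg)
  lib <- simulate_condition_library(res$model, cfg)
  expect_equal(ncol(lib$counts), 34)
  # with no condition-expressed plants, planted regions stay at zero
  pl <- res$model$features$type == "planted"
  expect_true(all(lib$counts[pl, ] == 0))
})

test_that("identical config and seed reproduce the whole scenario", {
  cfg <- sim_config(seed = 9)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$genome$seq, s2$genome$seq)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$condition$counts, s2$condition$counts)
})
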