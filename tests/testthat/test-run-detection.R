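scenario_cache <- new.env()
get_scenario <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(scenario_cache[[key]])) {
    scenario_cache[[key]] <- simulate_scenario(sim_config(seed = seed))
  }
  scenario_cache[[key]]
}

test_that("the cascade recovers planted proto-genes on the default scenario", {
  sc <- get_scenario(1)
  det <- run_detection(sc)
  ev <- evaluate_detection(det, sc$truth)
  expect_gte(ev$sensitivity, 0.75)
  expect_lte(ev$fdp, 0.25)
  expect_gt(nrow(det$report), 0)
  # every reported proto-gene traces to a known upstream mutation
  expect_true(all(det$report$mutation_id %in% sc$mutations$id))
})

test_that("re-running with the same seed reproduces the report", {
  sc <- get_scenario(1)
  d1 <- run_detection(sc)
  d2 <- run_detection(sc)
  expect_identical(d1$report, d2$report)
  expect_identical(d1$candidates, d2$candidates)
})

test_that("the filter trail covers every extracted region", {
  sc <- get_scenario(1)
  det <- run_detection(sc)
  extracted <- det$trail[det$trail$stage == "extract", ]
  expect_setequal(extracted$region_id, det$regions$region_id)
  # every candidate carries exactly one final verdict
  fin <- det$trail[det$trail$stage == "final", ]
  expect_equal(anyDuplicated(fin$region_id), 0)
  expect_setequal(fin$region_id, det$candidates$region_id)
  # excluded candidates name exactly one deciding filter
  exc <- det$candidates[det$candidates$final_status != "proto-gene", ]
  expect_true(all(grepl("^excluded: ", exc$final_status)))
})

test_that("a zero-plant scenario stays at a type-I-consistent report size", {
  cfg <- sim_config(seed = 30, planted_protogene_count = 0,
                    condition_expressed_count = 0)
  sc <- simulate_scenario(cfg)
  det <- run_detection(sc)
  # with ~400 null regions and BH at 0.05, discoveries should be rare
  expect_lte(nrow(det$report), 3)
})

test_that("tightening thresholds never adds proto-genes", {
  sc <- get_scenario(2)
  base <- run_detection(sc)
  tighter <- run_detection(sc, de_alpha = 0.01)
  expect_true(all(tighter$report$mutation_id %in% base$report$mutation_id))
  stricter <- run_detection(sc, strict_both_lengths = TRUE)
  expect_true(all(stricter$report$mutation_id %in% base$report$mutation_id))
  lower_floor <- run_detection(sc, min_reads_condition = 1)
  expect_true(all(lower_floor$report$mutation_id %in%
                    base$report$mutation_id))
})

test_that("the IS survey tallies significant and silent downstream regions", {
  cfg <- sim_config(seed = 31, mutation_count = 50,
                    planted_protogene_count = 10,
                    condition_expressed_count = 0,
                    class_weights = c(SNP = 0.1, INDEL = 0.05, MOB = 0.8,
                                      DEL = 0.05))
  sc <- simulate_scenario(cfg)
  det <- run_detection(sc)
  sv <- survey_is_downstream(det, "IS150")
  n_mob <- sum(sc$mutations$type == "MOB")
  expect_equal(unname(sv$summary["total"]), n_mob)
  # planted MOB events drive the significant count; it stays near the
  # planted number (type-I noise allows a little slack)
  planted_mob <- sum(sc$truth$mutation_id %in%
                       sc$mutations$id[sc$mutations$type == "MOB"])
  expect_gte(sv$summary[["significant"]], floor(0.7 * planted_mob))
  expect_lte(sv$summary[["significant"]], planted_mob + 3)
  expect_lte(sv$summary[["significant_and_silent"]],
             sv$summary[["significant"]])
  # no MOB mutations: empty survey
  cfg0 <- sim_config(seed = 32, mutation_count = 20,
                     planted_protogene_count = 2,
                     class_weights = c(SNP = 0.9, INDEL = 0.1, MOB = 0,
                                       DEL = 0))
  sc0 <- simulate_scenario(cfg0)
  sv0 <- survey_is_downstream(run_detection(sc0), "IS150")
  expect_equal(unname(sv0$summary["total"]), 0L)
  expect_equal(nrow(sv0$table), 0)
})

test_that("the Ribo-seq path runs the same cascade on ribosome evidence", {
  cfg <- sim_config(seed = 33, simulate_ribo = TRUE)
  sc <- simulate_scenario(cfg)
  expect_error(run_detection(get_scenario(1), assay = "ribo"), "read evidence")
  det <- run_detection(sc, assay = "ribo")
  # planted regions are untranslated (TE 0), so the Ribo cascade reports
  # none of them
  expect_false(any(det$report$mutation_id %in% sc$truth$mutation_id))
})

test_that("scenario artifacts write as plain text", {
  sc <- simulate_scenario(sim_config(seed = 34, mutation_count = 10,
                                     planted_protogene_count = 1,
                                     library_size = 2e4,
                                     condition_count = 3,
                                     condition_library_size = 5e3))
  dir <- withr::local_tempdir()
  write_scenario(sc, dir)
  expect_true(file.exists(file.path(dir, "ancestor.fasta")))
  expect_true(file.exists(file.path(dir, "mutations.gd")))
  fa <- read_fasta(file.path(dir, "ancestor.fasta"))
  expect_identical(unname(fa["ancestor"]), sc$genome$seq)
  m2 <- parse_genomediff(file.path(dir, "mutations.gd"))
  expect_equal(m2$position, sc$mutations$position)
  cfg2 <- read_sim_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$seed, sc$config$seed)
  expect_equal(cfg2$class_weights, sc$config$class_weights)
  # bedGraph coverage mass equals read mass for a sample
  s1 <- names(sc$reads$ancestor)[1]
  bg <- read.table(file.path(dir, paste0(s1, ".cov_plus.bedgraph")))
  r <- sc$reads$ancestor[[s1]]
  expect_equal(sum((bg$V3 - bg$V2) * bg$V4),
               sum((r$end - r$start)[r$strand == "+"]))
})
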