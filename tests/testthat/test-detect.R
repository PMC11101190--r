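mkmut <- function(...) {
  m <- protoscan:::mut_row(...)
  class(m) <- c("mutation_set", "data.frame")
  m
}

test_that("MOB mutations yield two regions on the promoter strand only", {
  seq <- random_seq(5000, 1)
  el <- c(ISX = random_seq(100, 2))
  m <- mkmut("mob1", "MOB", 2000, element = "ISX", element_length = 100L,
             strand = "+", dup_size = 3L)
  res <- apply_mutations(list(seq = seq, elements = el), m)
  reg <- extract_downstream_regions(m, res$map, 5000)
  expect_equal(nrow(reg), 2)
  expect_true(all(reg$strand == "+"))
  expect_setequal(reg$length, c(100, 200))
  # downstream includes the duplication: ancestral start = pos - 1 + dup
  expect_true(all(reg$anc_start == 2002))
  # evolved region begins right after element + duplication
  expect_true(all(reg$ev_start == 2002 + 100 + 3))
})

test_that("SNPs yield four regions: two lengths on both strands", {
  seq <- random_seq(5000, 3)
  m <- mkmut("s1", "SNP", 2500, new_base = "A")
  res <- apply_mutations(list(seq = seq, elements = NULL), m)
  reg <- extract_downstream_regions(m, res$map, 5000)
  expect_equal(nrow(reg), 4)
  expect_equal(sort(table(reg$strand)), sort(table(c("+", "+", "-", "-"))))
  plus <- reg[reg$strand == "+", ]
  minus <- reg[reg$strand == "-", ]
  expect_true(all(plus$anc_start == 2500))
  expect_true(all(minus$anc_end == 2499))
})

test_that("a deletion's downstream region abuts the evolved junction", {
  seq <- random_seq(20000, 4)
  m <- mkmut("bigdel", "DEL", 5000, size = 7849L)
  res <- apply_mutations(list(seq = seq, elements = NULL), m)
  reg <- extract_downstream_regions(m, res$map, 20000, lengths = 200)
  plus <- reg[reg$strand == "+", ]
  # ancestral: first base after the deleted span
  expect_equal(plus$anc_start, 4999 + 7849)
  # evolved: the junction position itself (deletion collapses to a point)
  expect_equal(plus$ev_start, 4999)
  expect_equal(plus$ev_end, 4999 + 200)
  # sequence downstream of the junction equals the ancestral sequence
  # downstream of the deletion
  expect_equal(substr(res$seq, 5000, 5199),
               substr(seq, 5000 + 7849, 5199 + 7849))
})

test_that("regions running off the genome end are truncated and flagged", {
  seq <- random_seq(1000, 5)
  m <- mkmut("s1", "SNP", 950, new_base = "A")
  res <- apply_mutations(list(seq = seq, elements = NULL), m)
  reg <- extract_downstream_regions(m, res$map, 1000)
  plus200 <- reg[reg$strand == "+" & reg$length == 200, ]
  expect_true(plus200$truncated)
  expect_equal(plus200$anc_end, 1000)
})

test_that("the candidate overlap filter is strict at 10 bp", {
  reg <- data.frame(region_id = c("r1", "r2", "r3"),
                    mutation_id = c("m1", "m2", "m3"),
                    mutation_type = "SNP", clone = "c1",
                    strand = "+", length = 200,
                    anc_start = c(0, 500, 1000),
                    anc_end = c(200, 700, 1200),
                    ev_start = NA, ev_end = NA, lift_status = "clean",
                    truncated = FALSE)
  ann <- data.frame(name = c("g1", "p1", "rna1"),
                    start = c(189, 689, 1190), end = c(400, 900, 1400),
                    strand = "+",
                    type = c("gene", "pseudogene", "rna"))
  out <- filter_candidate_overlaps(reg, ann)
  # 11-bp gene overlap and 11-bp pseudogene overlap exclude; 10-bp retains
  expect_equal(out$overlap_verdict, c("excluded", "excluded", "retained"))
  # opposite-strand overlap never triggers this filter
  ann2 <- transform(ann, strand = "-")
  out2 <- filter_candidate_overlaps(reg, ann2)
  expect_true(all(out2$overlap_verdict == "retained"))
})

test_that("dedup removes exact duplicates and opposite-strand repeat overlaps", {
  reg <- data.frame(region_id = c("a", "b", "c"),
                    strand = c("+", "+", "+"),
                    anc_start = c(100, 100, 900), anc_end = c(300, 300, 1100))
  ann <- data.frame(name = "rep1", start = 1050, end = 1200, strand = "-",
                    type = "repeat")
  out <- dedup_candidates(reg, ann)
  expect_equal(out$dedup_verdict, c("retained", "excluded", "excluded"))
  expect_match(out$dedup_detail[2], "duplicate")
  expect_match(out$dedup_detail[3], "opposite-strand repeat")
})

test_that("overlapping candidates from adjacent mutations collapse to one", {
  reg <- data.frame(region_id = c("strong", "weak"),
                    strand = "+", anc_start = c(100, 150),
                    anc_end = c(300, 350),
                    pvalue = c(1e-9, 1e-4), padj = c(1e-6, 1e-6),
                    log2FC = c(5, 4), carried = TRUE)
  out <- dedup_candidates(reg, data.frame(name = character(),
                                          start = integer(), end = integer(),
                                          strand = character(),
                                          type = character()))
  expect_equal(out$dedup_verdict, c("retained", "excluded"))
  expect_match(out$dedup_detail[2], "adjacent mutation")
})

test_that("the silence verdict follows the coverage rule", {
  L <- 2000
  zero <- list(plus = numeric(L), minus = numeric(L))
  cov0 <- list(zero, zero)
  expect_equal(ancestral_silence_check(500, 700, "+", cov0)$verdict, "silent")
  high <- list(plus = rep(50, L), minus = numeric(L))
  covh <- list(high, high)
  expect_equal(ancestral_silence_check(500, 700, "+", covh)$verdict,
               "expressed")
  # between thresholds (explicit bounds): ambiguous, order-invariant
  mid <- list(plus = rep(2, L), minus = numeric(L))
  lo <- list(plus = rep(0.1, L), minus = numeric(L))
  for (reps in list(list(mid, lo), list(lo, mid))) {
    chk <- ancestral_silence_check(500, 700, "+", reps,
                                   t_silent = 1, t_expr = 10)
    expect_equal(chk$verdict, "ambiguous")
  }
  # a replicate-consistent 25-bp run of coverage >= 3 breaks silence
  runcov <- numeric(L); runcov[601:625] <- 3
  runrep <- list(plus = runcov, minus = numeric(L))
  both <- ancestral_silence_check(500, 700, "+", list(runrep, runrep),
                                  t_silent = 1, t_expr = 10)
  expect_equal(both$verdict, "ambiguous")
  one <- ancestral_silence_check(500, 700, "+", list(runrep, zero),
                                 t_silent = 1, t_expr = 10)
  expect_equal(one$verdict, "silent")
  # a 24-bp run is below the rule's length
  shortcov <- numeric(L); shortcov[601:624] <- 3
  shortrep <- list(plus = shortcov, minus = numeric(L))
  expect_equal(ancestral_silence_check(500, 700, "+",
                                       list(shortrep, shortrep),
                                       t_silent = 1, t_expr = 10)$verdict,
               "silent")
  expect_error(ancestral_silence_check(1, 2, "+", list()), "coverage")
})

test_that("the cross-condition screen applies a per-condition floor", {
  expect_equal(cross_condition_filter(rep(0, 34)), "unseen")
  expect_equal(cross_condition_filter(c(rep(0, 33), 3)), "seen")
  # 2 reads in every condition never pools to visibility
  expect_equal(cross_condition_filter(rep(2, 34)), "unseen")
})

test_that("causes are classified by mutation type and context", {
  ann <- data.frame(name = "g1", start = 3000, end = 4500, strand = "+",
                    type = "gene")
  mob <- mkmut("m1", "MOB", 6000, element = "IS150", element_length = 1443L,
               strand = "+", dup_size = 3L)
  expect_equal(classify_cause(mob, "+", ann), "promoter in insertion sequence")
  # 7,849-bp deletion starting just after a gene: translocation class
  del <- mkmut("m2", "DEL", 4601, size = 7849L)
  expect_equal(classify_cause(del, "+", ann),
               "translocation to existing promoter")
  # same deletion with no nearby upstream gene
  far <- data.frame(name = "g1", start = 100, end = 900, strand = "+",
                    type = "gene")
  expect_match(classify_cause(del, "+", far), "unknown")
  snp <- mkmut("m3", "SNP", 1000, new_base = "G")
  expect_equal(classify_cause(snp, "+", ann),
               "point mutation or small indel (promoter status unknown)")
  small <- mkmut("m4", "DEL", 1000, size = 4L)
  expect_equal(classify_cause(small, "+", ann),
               "point mutation or small indel (promoter status unknown)")
})

test_that("ORF detection is strand-aware, three-frame, and strictly >30 bp", {
  # no start codon and no stop: nothing
  expect_equal(nrow(find_orfs(strrep("CCC", 50))), 0)
  # ATG + 32 codons + TAA = 102 bp
  set.seed(1)
  body <- paste(sample(c("GCT", "GAA", "CAT", "CCG"), 32, replace = TRUE),
                collapse = "")
  orf102 <- paste0("ATG", body, "TAA")
  hit <- find_orfs(paste0("CCCC", orf102, "CC"))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length, 102)
  expect_equal(hit$start, 4)
  # 33 bp passes the strict >30 rule, 30 bp does not
  orf33 <- paste0("ATG", strrep("GCA", 9), "TAA")  # 11 codons = 33 bp
  expect_equal(find_orfs(orf33)$length, 33)
  orf30 <- paste0("ATG", strrep("GCA", 8), "TAA")  # 10 codons = 30 bp
  expect_equal(nrow(find_orfs(orf30)), 0)
  # a 117-aa ORF reports 354 bp and is flagged longest
  body117 <- paste(sample(c("GCT", "GAA", "CAT", "CCG"), 116,
                          replace = TRUE), collapse = "")
  orf354 <- paste0("ATG", body117, "TGA")
  res <- find_orfs(paste0(random_seq(20, 2), orf354))
  expect_equal(max(res$length), 354)
  expect_true(res$longest[which.max(res$length)])
  # GTG and TTG starts count
  expect_equal(find_orfs(paste0("GTG", strrep("GCA", 10), "TAG"))$length, 36)
})

test_that("orf_scan_region orients the window to the transcribed strand", {
  set.seed(3)
  body <- paste(sample(c("GCT", "GAA", "CAT", "CCG"), 40, replace = TRUE),
                collapse = "")
  orf <- paste0("ATG", body, "TAA")  # 126 bp
  left <- random_seq(300, 4); right <- random_seq(300, 5)
  genome <- paste0(left, orf, right)
  # plus strand: anchor upstream of the ORF
  res_p <- orf_scan_region(genome, 290, "+")
  expect_true(126 %in% res_p$length)
  # minus strand: the reverse complement carries the ORF
  genome_m <- paste0(left, protoscan:::revcomp(orf), right)
  res_m <- orf_scan_region(genome_m, 300 + 126 + 10, "-")
  expect_true(126 %in% res_m$length)
})
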