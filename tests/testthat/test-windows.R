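test_that("partitioning tiles both strands and drops the terminal remainder", {
  ws <- partition_windows(50000, 400)
  expect_equal(nrow(ws$windows), 250)
  expect_equal(sum(ws$windows$strand == "+"), 125)
  ws2 <- partition_windows(799, 400)
  expect_equal(nrow(ws2$windows), 2)
  expect_equal(ws2$windows$end - ws2$windows$start, c(400, 400))
  expect_error(partition_windows(300, 400), "exceeds")
})

test_that("partitioning a genome-scale length matches explicit enumeration", {
  L <- 4629812
  ws <- partition_windows(L, 400)
  # enumeration oracle
  starts <- seq(0, L - 400, by = 400)
  expect_equal(nrow(ws$windows), 2 * length(starts))
  expect_equal(nrow(ws$windows), 23148)
  for (s in c("+", "-")) {
    w <- ws$windows[ws$windows$strand == s, ]
    expect_equal(w$start, starts)
    expect_equal(w$end, starts + 400)
  }
})

test_that("partition invariants: disjoint same-strand tiles forming an interval", {
  ws <- partition_windows(10000, 350)
  for (s in c("+", "-")) {
    w <- ws$windows[ws$windows$strand == s, ]
    w <- w[order(w$start), ]
    expect_true(all(w$start[-1] == w$end[-nrow(w)]))
    expect_equal(sum(w$end - w$start), 350 * nrow(w))
  }
})

test_that("no mutations and no IS annotations retain every window", {
  ws <- partition_windows(10000, 400)
  suppressMessages(
    fw <- filter_windows(ws, list(c1 = identity_map(10000)),
                         data.frame(start = integer(), end = integer(),
                                    strand = character(), type = character())))
  expect_equal(nrow(fw$windows), nrow(ws$windows))
  expect_equal(nrow(fw$dropped), 0)
})

test_that("windows drop on large indels but survive small ones", {
  seq <- random_seq(10000, 1)
  mk_del <- function(pos, size) {
    m <- protoscan:::mut_row("d1", "DEL", pos, size = as.integer(size))
    class(m) <- c("mutation_set", "data.frame")
    apply_mutations(list(seq = seq, elements = NULL), m)$map
  }
  ws <- partition_windows(10000, 400)
  ann0 <- data.frame(start = integer(), end = integer(),
                     strand = character(), type = character())
  # 25-bp deletion inside window [400, 800): dropped
  suppressMessages(f25 <- filter_windows(ws, list(c1 = mk_del(501, 25)), ann0))
  expect_true(all(c("wp00002", "wm00002") %in% f25$dropped$id))
  expect_equal(unique(f25$dropped$reason), "indel>10bp")
  # 11-bp dropped, 10-bp retained (strict > 10)
  suppressMessages(f11 <- filter_windows(ws, list(c1 = mk_del(501, 11)), ann0))
  expect_true("wp00002" %in% f11$dropped$id)
  suppressMessages(f10 <- filter_windows(ws, list(c1 = mk_del(501, 10)), ann0))
  expect_false("wp00002" %in% f10$dropped$id)
})

test_that("IS/repeat overlap of >= 1 bp drops a window on either strand", {
  ws <- partition_windows(4000, 400)
  ann <- data.frame(start = 799, end = 950, strand = "+", type = "repeat")
  suppressMessages(fw <- filter_windows(ws, list(c1 = identity_map(4000)), ann))
  # repeat touches window 2 ([400,800)) by 1 bp and window 3 on both strands
  expect_true(all(c("wp00002", "wm00002", "wp00003", "wm00003") %in%
                    fw$dropped$id))
  expect_true(all(fw$dropped$reason == "is-overlap"))
})

test_that("filtering matches a brute-force re-check on random fixtures", {
  for (seed in 1:4) {
    L <- 8000
    seq <- random_seq(L, seed)
    maps <- list()
    all_muts <- list()
    for (cl in 1:5) {
      fx <- random_mutation_fixture(L, 6, seed * 10 + cl)
      maps[[paste0("c", cl)]] <- apply_mutations(
        list(seq = seq, elements = fx$elements), fx$mutations)$map
      all_muts[[cl]] <- fx$mutations
    }
    ws <- partition_windows(L, 400)
    ann0 <- data.frame(start = integer(), end = integer(),
                       strand = character(), type = character())
    suppressMessages(fw <- filter_windows(ws, maps, ann0))
    # brute force: a window survives iff in every clone it is not wholly
    # deleted and carries no single event inserting/deleting > 10 bp in it
    for (i in seq_len(nrow(ws$windows))) {
      w <- ws$windows[i, ]
      keep <- TRUE
      for (cl in 1:5) {
        lf <- lift_interval(maps[[cl]], w$start, w$end)
        if (lf$status == "deleted" || lf$indel > 10) keep <- FALSE
      }
      expect_equal(w$id %in% fw$windows$id, keep,
                   label = paste("seed", seed, "window", w$id))
    }
  }
})

test_that("filter survivors only shrink when a mutation is added", {
  L <- 8000
  seq <- random_seq(L, 3)
  fx <- random_mutation_fixture(L, 8, 33)
  ws <- partition_windows(L, 400)
  ann0 <- data.frame(start = integer(), end = integer(),
                     strand = character(), type = character())
  prev <- NULL
  for (k in 1:8) {
    m <- fx$mutations[seq_len(k), , drop = FALSE]
    class(m) <- c("mutation_set", "data.frame")
    map <- apply_mutations(list(seq = seq, elements = fx$elements), m)$map
    suppressMessages(fw <- filter_windows(ws, list(c1 = map), ann0))
    ids <- fw$windows$id
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("categorisation applies the strict 10-bp same-strand rule", {
  ws <- partition_windows(2000, 400)
  mk <- function(gs, ge, strand) {
    data.frame(name = "g1", start = gs, end = ge, strand = strand,
               type = "gene")
  }
  # window [0,400)+ entirely inside a same-strand gene
  cw <- categorize_windows(ws, mk(0, 1000, "+"))
  expect_equal(cw$windows$category[cw$windows$id == "wp00001"], "annotated")
  # exactly 10 bp of same-strand overlap stays non-genic
  cw10 <- categorize_windows(ws, mk(390, 1000, "+"))
  expect_equal(cw10$windows$category[cw10$windows$id == "wp00001"],
               "intergenic")
  cw11 <- categorize_windows(ws, mk(389, 1000, "+"))
  expect_equal(cw11$windows$category[cw11$windows$id == "wp00001"],
               "annotated")
  # the same 10-bp overlap seen from the opposite strand is antisense
  expect_equal(cw10$windows$category[cw10$windows$id == "wm00001"],
               "antisense")
})

test_that("antisense requires an opposite-strand coding gene", {
  ws <- partition_windows(2000, 400)
  g <- data.frame(name = "g1", start = 399, end = 900, strand = "-",
                  type = "gene")
  cw <- categorize_windows(ws, g)
  expect_equal(cw$windows$category[cw$windows$id == "wp00001"], "antisense")
  expect_equal(cw$windows$category[cw$windows$id == "wm00001"], "intergenic")
  expect_error(categorize_windows(ws, transform(g, strand = "?")),
               "strand")
})

test_that("categories match an exhaustive oracle on random fixtures", {
  for (seed in 1:6) {
    set.seed(seed)
    L <- 20000
    n <- 12
    gs <- sort(sample.int(L - 1500, n))
    genes <- data.frame(name = paste0("g", 1:n), start = gs,
                        end = gs + sample(200:1200, n, replace = TRUE),
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        type = "gene")
    ws <- partition_windows(L, 400)
    cw <- categorize_windows(ws, genes)
    oracle <- bf_categorize(cw$windows, genes, L = L)
    expect_equal(cw$windows$category, oracle$category,
                 label = paste("seed", seed))
    expect_equal(cw$windows$gene_adjacent, oracle$gene_adjacent,
                 label = paste("seed", seed))
    # category partition: each window exactly one category, tallies add up
    tl <- window_tally(cw)
    expect_equal(sum(tl[c("annotated", "antisense", "intergenic")]),
                 tl[["total"]])
  }
})
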