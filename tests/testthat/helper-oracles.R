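# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain loops
# and a character-vector string-edit model.

# O(n*m) same-strand >=1 bp overlap counting
bf_count_reads <- function(features, reads) {
  counts <- integer(nrow(features))
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(reads))) {
      if (features$strand[i] == reads$strand[j] &&
          max(features$start[i], reads$start[j]) <
            min(features$end[i], reads$end[j])) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  setNames(counts, features$id)
}

# textbook BH step-up
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exhaustive window categorisation by the stated rules
bf_categorize <- function(windows, genes, genic_overlap = 10,
                          upstream = 300, downstream = 100, L = Inf) {
  cat <- character(nrow(windows))
  adj <- rep(NA, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    same <- anti <- 0
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      ov <- max(0, min(w$end, g$end) - max(w$start, g$start))
      if (g$strand == w$strand) same <- max(same, ov) else anti <- max(anti, ov)
    }
    cat[i] <- if (same > genic_overlap) "annotated"
              else if (anti >= 1) "antisense" else "intergenic"
    if (cat[i] != "annotated") {
      hit <- FALSE
      for (j in seq_len(nrow(genes))) {
        g <- genes[j, ]
        if (g$strand != w$strand) next
        if (g$strand == "+") {
          fl <- rbind(c(g$start - upstream, g$start), c(g$end, g$end + downstream))
        } else {
          fl <- rbind(c(g$end, g$end + upstream), c(g$start - downstream, g$start))
        }
        for (k in 1:2) {
          a <- max(0, fl[k, 1]); b <- min(L, fl[k, 2])
          if (b > a && max(w$start, a) < min(w$end, b)) hit <- TRUE
        }
      }
      adj[i] <- hit
    }
  }
  list(category = cat, gene_adjacent = adj)
}

# string-edit oracle: apply mutations left-to-right on a character vector
# with cumulative offsets, tracking each evolved base's ancestral origin
bf_apply <- function(seq, mutations, elements) {
  chars <- strsplit(seq, "")[[1]]
  origin <- seq_along(chars)           # evolved index -> 1-based anc base
  ord <- order(mutations$position)
  off <- 0L
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  for (i in ord) {
    m <- mutations[i, ]
    p <- m$position + off
    if (m$type == "SNP") {
      chars[p] <- m$new_base
    } else if (m$type == "DEL") {
      keep <- setdiff(seq_along(chars), p:(p + m$size - 1))
      chars <- chars[keep]; origin <- origin[keep]
      off <- off - m$size
    } else if (m$type == "INS") {
      ins <- strsplit(m$sequence, "")[[1]]
      chars <- append(chars, ins, after = p)
      origin <- append(origin, rep(NA_integer_, length(ins)), after = p)
      off <- off + length(ins)
    } else if (m$type == "MOB") {
      d <- m$dup_size
      el <- elements[[m$element]]
      if (m$strand == "-") el <- rc(el)
      dup <- substr(seq, m$position, m$position + d - 1)
      ins <- strsplit(paste0(el, dup), "")[[1]]
      at <- p + d - 1
      chars <- append(chars, ins, after = at)
      origin <- append(origin, rep(NA_integer_, length(ins)), after = at)
      off <- off + length(ins)
    }
  }
  list(seq = paste(chars, collapse = ""), origin = origin)
}

# lifted span of an ancestral 0-based half-open interval per the oracle
bf_lift <- function(origin, start, end) {
  ev <- which(origin %in% ((start + 1):end))  # evolved 1-based positions
  if (length(ev) == 0) return(NULL)
  c(min(ev) - 1L, max(ev))                    # 0-based half-open
}

# small random mutation set with non-overlapping footprints, built
# independently of sample_mutations
random_mutation_fixture <- function(L, n, seed, elements = c(ISX = NULL)) {
  set.seed(seed)
  el_seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = "")
  rows <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  types <- sample(c("SNP", "DEL", "INS", "MOB"), n, replace = TRUE)
  for (i in order(match(types, c("DEL", "MOB", "INS", "SNP")))) {
    ty <- types[i]
    sz <- switch(ty, SNP = 1L, DEL = sample(3:40, 1), INS = 1L, MOB = 3L)
    repeat {
      p <- sample.int(L - 60, 1) + 5L
      s0 <- p - 1; e0 <- s0 + sz + 1  # +1 buffer keeps insertion points apart
      if (nrow(occupied) == 0 ||
          all(e0 <= occupied[, 1] | s0 >= occupied[, 2])) {
        occupied <- rbind(occupied, c(s0, e0)); break
      }
    }
    rows[[i]] <- switch(ty,
      SNP = data.frame(id = paste0("x", i), type = "SNP", position = p,
                       new_base = "A", size = NA_integer_,
                       sequence = NA_character_, element = NA_character_,
                       element_length = NA_integer_, strand = NA_character_,
                       dup_size = NA_integer_, class = "SNP"),
      DEL = data.frame(id = paste0("x", i), type = "DEL", position = p,
                       new_base = NA_character_, size = sz,
                       sequence = NA_character_, element = NA_character_,
                       element_length = NA_integer_, strand = NA_character_,
                       dup_size = NA_integer_, class = "DEL"),
      INS = data.frame(id = paste0("x", i), type = "INS", position = p,
                       new_base = NA_character_, size = 5L,
                       sequence = paste(sample(c("A", "C", "G", "T"), 5,
                                               replace = TRUE), collapse = ""),
                       element = NA_character_, element_length = NA_integer_,
                       strand = NA_character_, dup_size = NA_integer_,
                       class = "INDEL"),
      MOB = data.frame(id = paste0("x", i), type = "MOB", position = p,
                       new_base = NA_character_, size = NA_integer_,
                       sequence = NA_character_, element = "ISX",
                       element_length = 120L,
                       strand = sample(c("+", "-"), 1), dup_size = 3L,
                       class = "MOB"))
  }
  muts <- do.call(rbind, rows)
  class(muts) <- c("mutation_set", "data.frame")
  list(mutations = muts, elements = c(ISX = el_seq))
}

random_seq <- function(L, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
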