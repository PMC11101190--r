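#' Sample a mutation set for one evolved clone
#'
#' Draws `mutation_count` mutations whose classes follow `class_weights`
#' (SNPs and small indels dominate, with rarer IS insertions and large
#' deletions). Footprints are mutually non-overlapping so the set can be
#' applied exactly; positions are 1-based ancestral coordinates. MOB
#' records carry the element identity, insertion strand and target-site
#' duplication size; large deletions never remove the whole genome.
#'
#' @param genome A `genome_record`.
#' @param config A [sim_config()].
#' @param ids Optional id prefix (default "m").
#' @return A data.frame of mutation records with class `mutation_set`:
#'   columns `id`, `type` (SNP/INS/DEL/MOB), `position` (1-based),
#'   `new_base`, `size`, `sequence`, `element`, `element_length`,
#'   `strand`, `dup_size`, `class` (the sampled class label, where small
#'   indels keep class "INDEL" but type INS or DEL).
#' @export
sample_mutations <- function(genome, config, ids = "m") {
  set.seed(stage_seed(config$seed, "mutations"))
  n <- config$mutation_count
  empty <- empty_mutation_set()
  if (n == 0) return(empty)
  L <- genome$length

  classes <- sample(names(config$class_weights), n, replace = TRUE,
                    prob = config$class_weights)
  occupied <- matrix(numeric(0), ncol = 2)  # 0-based half-open footprints
  rows <- vector("list", n)
  bases <- c("A", "C", "G", "T")

  place <- function(fp_len, class) {
    # rejection-sample a non-overlapping footprint of fp_len bp
    for (try in seq_len(2000)) {
      p <- sample.int(L - fp_len, 1)  # 1-based start, footprint [p-1, p-1+fp_len)
      s0 <- p - 1; e0 <- s0 + fp_len
      if (nrow(occupied) == 0 ||
          all(e0 <= occupied[, 1] | s0 >= occupied[, 2])) {
        occupied <<- rbind(occupied, c(s0, e0))
        return(p)
      }
    }
    stop("no placeable positions left for mutation class ", class)
  }

  # place big-footprint classes first: a large deletion cannot find a free
  # contiguous span once dozens of point mutations are scattered
  ord <- order(match(classes, c("DEL", "MOB", "INDEL", "SNP")))
  for (i in ord) {
    cl <- classes[i]
    id <- sprintf("%s%03d", ids, i)
    if (cl == "SNP") {
      p <- place(1L, cl)
      ref <- substr(genome$seq, p, p)
      nb <- sample(setdiff(bases, ref), 1)
      rows[[i]] <- mut_row(id, "SNP", p, new_base = nb, class = cl)
    } else if (cl == "INDEL") {
      sz <- sample(config$small_indel_range[1]:config$small_indel_range[2], 1)
      if (runif(1) < 0.5) {  # small insertion
        p <- place(1L, cl)
        ins <- paste(sample(bases, sz, replace = TRUE), collapse = "")
        rows[[i]] <- mut_row(id, "INS", p, sequence = ins, size = sz, class = cl)
      } else {             # small deletion
        p <- place(sz, cl)
        rows[[i]] <- mut_row(id, "DEL", p, size = sz, class = cl)
      }
    } else if (cl == "DEL") {
      sz <- sample(config$large_del_range[1]:config$large_del_range[2], 1)
      sz <- min(sz, L - 1L)  # never the entire genome
      p <- place(sz, cl)
      rows[[i]] <- mut_row(id, "DEL", p, size = sz, class = cl)
    } else {  # MOB
      d <- config$tsd_size
      p <- place(max(d, 1L), cl)
      rows[[i]] <- mut_row(id, "MOB", p,
                           element = config$is_element_name,
                           element_length = config$is_element_length,
                           strand = sample(c("+", "-"), 1),
                           dup_size = d, class = cl)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mutation_set", "data.frame")
  out
}

mut_row <- function(id, type, position, new_base = NA_character_,
                    size = NA_integer_, sequence = NA_character_,
                    element = NA_character_, element_length = NA_integer_,
                    strand = NA_character_, dup_size = NA_integer_,
                    class = type) {
  data.frame(id = id, type = type, position = as.integer(position),
             new_base = new_base, size = as.integer(size),
             sequence = sequence, element = element,
             element_length = as.integer(element_length), strand = strand,
             dup_size = as.integer(dup_size), class = class,
             stringsAsFactors = FALSE)
}

empty_mutation_set <- function() {
  out <- mut_row("x", "SNP", 1)[0, ]
  class(out) <- c("mutation_set", "data.frame")
  out
}

#' Mutation footprints in 0-based half-open ancestral coordinates
#'
#' SNPs occupy 1 bp; deletions their deleted span; insertions are a
#' zero-width point after `position`; MOB footprints cover the duplicated
#' target site (zero-width at the insertion point when the duplication size
#' is 0).
#'
#' @param mutations A `mutation_set`.
#' @return data.frame `id`, `type`, `fp_start`, `fp_end`, `net_indel`
#'   (signed bp gained by the event).
#' @export
mutation_footprints <- function(mutations) {
  if (nrow(mutations) == 0) {
    return(data.frame(id = character(), type = character(),
                      fp_start = integer(), fp_end = integer(),
                      net_indel = integer()))
  }
  fp_start <- fp_end <- net <- integer(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    if (m$type == "SNP") {
      fp_start[i] <- m$position - 1L; fp_end[i] <- m$position; net[i] <- 0L
    } else if (m$type == "DEL") {
      fp_start[i] <- m$position - 1L; fp_end[i] <- m$position - 1L + m$size
      net[i] <- -m$size
    } else if (m$type == "INS") {
      fp_start[i] <- m$position; fp_end[i] <- m$position  # point after base
      net[i] <- nchar(m$sequence)
    } else if (m$type == "MOB") {
      d <- if (is.na(m$dup_size)) 3L else m$dup_size
      fp_start[i] <- m$position - 1L; fp_end[i] <- m$position - 1L + d
      net[i] <- m$element_length + d
    } else stop("unsupported mutation type: ", m$type)
  }
  data.frame(id = mutations$id, type = mutations$type,
             fp_start = fp_start, fp_end = fp_end, net_indel = net,
             stringsAsFactors = FALSE)
}
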