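#' Apply mutations to a genome and build an exact coordinate map
#'
#' Produces the evolved clone's sequence together with an ancestral-to-
#' evolved coordinate map, replacing aligner-based remapping with exact
#' arithmetic. Semantics follow the breseq dialect the clone records use:
#' a SNP substitutes one base; DEL removes `size` bases starting at
#' `position`; INS inserts `sequence` after `position`; MOB duplicates the
#' `dup_size` target-site bases at `position` and places the element
#' sequence (reverse-complemented for `-` insertions) between the two
#' copies. Mutations must be mutually non-overlapping; conflicts raise an
#' error listing the offending ids. The evolved length always equals the
#' ancestral length plus the signed sum of event sizes.
#'
#' @param genome A `genome_record` (or a list with `seq` and optionally
#'   `elements`).
#' @param mutations A `mutation_set` data.frame.
#' @param elements Named character vector of element sequences for MOB
#'   records; defaults to `genome$elements`.
#' @return A list with `seq` (evolved sequence) and `map` (a `coord_map`).
#' @export
apply_mutations <- function(genome, mutations, elements = genome$elements) {
  seq <- genome$seq
  L <- nchar(seq)
  fp <- mutation_footprints(mutations)

  if (nrow(fp) > 0) {
    bad <- fp$fp_start < 0 | fp$fp_end > L | mutations$position > L
    if (any(bad)) {
      stop("mutation position out of range for: ",
           paste(fp$id[bad], collapse = ", "))
    }
    conflicts <- footprint_conflicts(fp)
    if (length(conflicts)) {
      stop("overlapping mutations: ", paste(conflicts, collapse = "; "))
    }
  }

  # SNPs change bases but not coordinates; apply them up front
  snps <- mutations[mutations$type == "SNP", , drop = FALSE]
  for (i in seq_len(nrow(snps))) {
    substr(seq, snps$position[i], snps$position[i]) <- snps$new_base[i]
  }

  # coordinate-changing ops, ascending; non-overlap makes this equivalent
  # to position-descending application on the original coordinates
  ops <- coordinate_ops(mutations, seq, elements)
  ops <- ops[order(ops$at), , drop = FALSE]

  pieces <- character(0)
  seg_rows <- list()
  ins_rows <- list()
  anc_cur <- 0L; ev_cur <- 0L
  add_mapped <- function(upto) {
    if (upto > anc_cur) {
      w <- upto - anc_cur
      seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
        anc_start = anc_cur, anc_end = upto,
        ev_start = ev_cur, ev_end = ev_cur + w, status = "mapped")
      pieces[[length(pieces) + 1L]] <<- substr(seq, anc_cur + 1L, upto)
      ev_cur <<- ev_cur + w
      anc_cur <<- upto
    }
  }
  for (i in seq_len(nrow(ops))) {
    op <- ops[i, ]
    add_mapped(op$at)
    if (op$kind == "del") {
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        anc_start = op$at, anc_end = op$at + op$size,
        ev_start = ev_cur, ev_end = ev_cur, status = "deleted")
      anc_cur <- anc_cur + op$size
    } else {  # insertion of op$payload after ancestral point op$at
      w <- nchar(op$payload)
      ins_rows[[length(ins_rows) + 1L]] <- data.frame(
        point = op$at, ev_start = ev_cur, ev_end = ev_cur + w, id = op$id)
      pieces[[length(pieces) + 1L]] <- op$payload
      ev_cur <- ev_cur + w
    }
  }
  add_mapped(L)

  evolved <- paste(pieces, collapse = "")
  net <- if (nrow(fp)) sum(fp$net_indel) else 0L
  stopifnot(nchar(evolved) == L + net)

  map <- structure(list(
    segments = if (length(seg_rows)) do.call(rbind, seg_rows) else
      data.frame(anc_start = 0L, anc_end = L, ev_start = 0L, ev_end = L,
                 status = "mapped"),
    insertions = if (length(ins_rows)) do.call(rbind, ins_rows) else
      data.frame(point = integer(), ev_start = integer(),
                 ev_end = integer(), id = character()),
    events = fp,
    anc_length = L, ev_length = nchar(evolved)), class = "coord_map")
  list(seq = evolved, map = map)
}

#' An identity coordinate map (no mutations)
#' @param length Genome length in bp.
#' @return A `coord_map`.
#' @export
identity_map <- function(length) {
  structure(list(
    segments = data.frame(anc_start = 0L, anc_end = length,
                          ev_start = 0L, ev_end = length, status = "mapped"),
    insertions = data.frame(point = integer(), ev_start = integer(),
                            ev_end = integer(), id = character()),
    events = mutation_footprints(empty_mutation_set()),
    anc_length = length, ev_length = length), class = "coord_map")
}

footprint_conflicts <- function(fp) {
  out <- character(0)
  n <- nrow(fp)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- fp$fp_start[i]; e1 <- fp$fp_end[i]
    s2 <- fp$fp_start[j]; e2 <- fp$fp_end[j]
    hit <- max(s1, s2) < min(e1, e2) ||
      (s1 == e1 && s1 > s2 && s1 < e2) ||
      (s2 == e2 && s2 > s1 && s2 < e1) ||
      (s1 == e1 && s2 == e2 && s1 == s2)
    if (hit) out <- c(out, paste(fp$id[i], fp$id[j], sep = "/"))
  }
  out
}

coordinate_ops <- function(mutations, seq, elements) {
  rows <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    if (m$type == "SNP") next
    if (m$type == "DEL") {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "del", at = m$position - 1L, size = m$size,
        payload = "", id = m$id)
    } else if (m$type == "INS") {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "ins", at = m$position, size = nchar(m$sequence),
        payload = m$sequence, id = m$id)
    } else if (m$type == "MOB") {
      d <- if (is.na(m$dup_size)) 3L else m$dup_size
      if (is.null(elements) || !m$element %in% names(elements)) {
        stop("element sequence not supplied for MOB record ", m$id,
             " (", m$element, ")")
      }
      el <- elements[[m$element]]
      if (nchar(el) != m$element_length) {
        stop("element ", m$element, " sequence length ", nchar(el),
             " != declared element_length ", m$element_length)
      }
      if (m$strand == "-") el <- revcomp(el)
      dup <- if (d > 0) substr(seq, m$position, m$position + d - 1L) else ""
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "ins", at = m$position - 1L + d, size = nchar(el) + d,
        payload = paste0(el, dup), id = m$id)
    } else stop("unsupported mutation type: ", m$type,
                " (AMP/INV are rejected by design)")
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), at = integer(), size = integer(),
               payload = character(), id = character())
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Lift an ancestral interval onto the evolved genome
#'
#' Returns the evolved-genome span containing all surviving ancestral bases
#' of the interval, plus a status: `"clean"` when no mutation intersects
#' the interval (the evolved subsequence is then identical to the ancestral
#' one), `"deleted"` when every base lies inside a deletion, `"partial"`
#' when a deletion truncates the interval at one of its ends, and
#' `"contains-indel"` otherwise, with `indel` reporting the largest bp span
#' any single event inserts into or deletes from the interval (a
#' substitution-only intersection reports `indel = 0`). Reverse lifting
#' maps an evolved interval back to ancestral coordinates.
#'
#' @param map A `coord_map`.
#' @param start,end 0-based half-open interval.
#' @param direction "forward" (ancestral to evolved) or "reverse".
#' @return A one-row data.frame: `start`, `end` (lifted coordinates, NA if
#'   deleted), `status`, `indel`.
#' @export
lift_interval <- function(map, start, end, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (direction == "reverse") return(lift_reverse(map, start, end))
  if (start < 0 || end > map$anc_length || start >= end) {
    stop("interval [", start, ",", end, ") outside ancestral genome of ",
         map$anc_length, " bp")
  }
  seg <- map$segments
  hit <- seg[seg$anc_end > start & seg$anc_start < end, , drop = FALSE]
  width <- end - start

  del_bp <- 0L
  ev_lo <- Inf; ev_hi <- -Inf
  first_deleted <- last_deleted <- FALSE
  for (i in seq_len(nrow(hit))) {
    s <- hit[i, ]
    a0 <- max(start, s$anc_start); a1 <- min(end, s$anc_end)
    if (s$status == "deleted") {
      del_bp <- del_bp + (a1 - a0)
      if (a0 == start) first_deleted <- TRUE
      if (a1 == end) last_deleted <- TRUE
    } else {
      off <- s$ev_start - s$anc_start
      ev_lo <- min(ev_lo, a0 + off)
      ev_hi <- max(ev_hi, a1 + off)
    }
  }

  if (del_bp >= width) {
    junction <- hit$ev_start[hit$status == "deleted"][1]
    return(data.frame(start = junction, end = junction,
                      status = "deleted", indel = del_bp))
  }

  ev <- map$events
  inter <- ev[ev$fp_end > start & ev$fp_start < end |
                (ev$fp_start == ev$fp_end &
                   ev$fp_start > start & ev$fp_start < end), , drop = FALSE]
  ins <- map$insertions
  ins_in <- ins[ins$point > start & ins$point < end, , drop = FALSE]

  if (nrow(inter) == 0 && nrow(ins_in) == 0) {
    return(data.frame(start = ev_lo, end = ev_hi, status = "clean",
                      indel = 0L))
  }

  # largest per-event span inserted into / deleted from the interval
  indel <- 0L
  for (i in seq_len(nrow(inter))) {
    e <- inter[i, ]
    if (e$type == "DEL") {
      indel <- max(indel, min(end, e$fp_end) - max(start, e$fp_start))
    } else if (e$type %in% c("INS", "MOB")) {
      ip <- ins$point[ins$id == e$id]
      if (length(ip) && ip > start && ip < end) {
        indel <- max(indel, abs(e$net_indel))
      }
    }
  }
  status <- if (first_deleted || last_deleted) "partial" else "contains-indel"
  data.frame(start = ev_lo, end = ev_hi, status = status, indel = indel)
}

lift_reverse <- function(map, start, end) {
  if (start < 0 || end > map$ev_length || start >= end) {
    stop("interval [", start, ",", end, ") outside evolved genome of ",
         map$ev_length, " bp")
  }
  seg <- map$segments
  mp <- seg[seg$status == "mapped" & seg$ev_end > start & seg$ev_start < end, ,
            drop = FALSE]
  ins <- map$insertions
  ins_hit <- ins[ins$ev_end > start & ins$ev_start < end, , drop = FALSE]
  if (nrow(mp) == 0) {
    return(data.frame(start = NA_integer_, end = NA_integer_,
                      status = "inserted-material", indel = end - start))
  }
  lo <- Inf; hi <- -Inf
  for (i in seq_len(nrow(mp))) {
    s <- mp[i, ]
    e0 <- max(start, s$ev_start); e1 <- min(end, s$ev_end)
    off <- s$anc_start - s$ev_start
    lo <- min(lo, e0 + off); hi <- max(hi, e1 + off)
  }
  status <- if (nrow(ins_hit) == 0 && hi - lo == end - start) "clean"
            else "contains-indel"
  data.frame(start = lo, end = hi, status = status,
             indel = if (nrow(ins_hit)) sum(pmin(end, ins_hit$ev_end) -
                                              pmax(start, ins_hit$ev_start)) else 0L)
}

#' Lift many intervals at once
#'
#' @param map A `coord_map`.
#' @param intervals data.frame with `start`, `end` (0-based half-open).
#' @return `intervals` with columns `ev_start`, `ev_end`, `status`, `indel`
#'   appended.
#' @export
lift_intervals <- function(map, intervals) {
  res <- lapply(seq_len(nrow(intervals)), function(i) {
    lift_interval(map, intervals$start[i], intervals$end[i])
  })
  res <- do.call(rbind, res)
  intervals$ev_start <- res$start
  intervals$ev_end <- res$end
  intervals$status <- res$status
  intervals$indel <- res$indel
  intervals
}

#' @export
print.coord_map <- function(x, ...) {
  cat("<coord_map>", x$anc_length, "bp ->", x$ev_length, "bp;",
      sum(x$segments$status == "deleted"), "deletion segment(s),",
      nrow(x$insertions), "insertion(s)\n")
  invisible(x)
}
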