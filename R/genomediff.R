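#' Read and write simplified GenomeDiff files
#'
#' The dialect is a tab-separated file with header line
#' `#=GENOME_DIFF simplified-1` and one record per line:
#' `type  id  position` followed by type-specific fields
#' (SNP: `new_base`; DEL: `size`; INS: `sequence`;
#' MOB: `element_name  element_length  strand  duplication_size`).
#' Mutation positions are 1-based, matching the breseq convention of the
#' clone records this mirrors. Unknown record types are skipped with a
#' single warning carrying their count; malformed coordinates or negative
#' sizes raise an error naming the offending line.
#'
#' @param path File path.
#' @return `parse_genomediff` returns a `mutation_set` data.frame.
#' @export
parse_genomediff <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#=GENOME_DIFF")) {
    stop("not a GenomeDiff file (missing #=GENOME_DIFF header): ", path)
  }
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rows <- list()
  skipped <- 0L
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    type <- f[1]
    if (!type %in% c("SNP", "DEL", "INS", "MOB")) { skipped <- skipped + 1L; next }
    if (length(f) < 3) stop("line ", ln, ": too few fields")
    pos <- suppressWarnings(as.integer(f[3]))
    if (is.na(pos) || pos < 1) stop("line ", ln, ": malformed coordinate '", f[3], "'")
    id <- f[2]
    row <- switch(type,
      SNP = {
        if (length(f) < 4) stop("line ", ln, ": SNP needs new_base")
        mut_row(id, "SNP", pos, new_base = f[4])
      },
      DEL = {
        sz <- suppressWarnings(as.integer(f[4]))
        if (is.na(sz) || sz < 1) stop("line ", ln, ": DEL size must be >= 1, got '", f[4], "'")
        mut_row(id, "DEL", pos, size = sz,
                class = if (sz > 10) "DEL" else "INDEL")
      },
      INS = {
        if (length(f) < 4 || !nzchar(f[4])) stop("line ", ln, ": INS needs a sequence")
        mut_row(id, "INS", pos, sequence = f[4], size = nchar(f[4]), class = "INDEL")
      },
      MOB = {
        if (length(f) < 7) stop("line ", ln, ": MOB needs element, length, strand, dup_size")
        el <- suppressWarnings(as.integer(f[5]))
        dd <- suppressWarnings(as.integer(f[7]))
        if (is.na(el) || el < 1) stop("line ", ln, ": MOB element_length must be >= 1")
        if (is.na(dd) || dd < 0) stop("line ", ln, ": MOB duplication_size must be >= 0")
        if (!f[6] %in% c("+", "-")) stop("line ", ln, ": MOB strand must be + or -")
        mut_row(id, "MOB", pos, element = f[4], element_length = el,
                strand = f[6], dup_size = dd)
      })
    rows[[length(rows) + 1L]] <- row
  }
  if (skipped > 0) {
    warning(skipped, " record(s) of unsupported type skipped ",
            "(only SNP, DEL, INS, MOB are applied; AMP/INV are rejected by design)")
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_mutation_set()
  rownames(out) <- NULL
  class(out) <- c("mutation_set", "data.frame")
  out
}

#' @param mutations A `mutation_set` data.frame.
#' @rdname parse_genomediff
#' @export
write_genomediff <- function(mutations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#=GENOME_DIFF simplified-1", con)
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    fields <- switch(m$type,
      SNP = c("SNP", m$id, m$position, m$new_base),
      DEL = c("DEL", m$id, m$position, m$size),
      INS = c("INS", m$id, m$position, m$sequence),
      MOB = c("MOB", m$id, m$position, m$element, m$element_length,
              m$strand, m$dup_size),
      stop("unsupported mutation type: ", m$type))
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
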