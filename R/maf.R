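#' Read a multiple alignment in MAF format
#'
#' Parses alignment blocks anchored to a named reference species. Each `s`
#' line is `s src start size strand srcSize text` with `src` of the form
#' `assembly.chrom`; the text before the first `.` is used as the species
#' key. Coordinates are kept exactly as in the file (0-based, strand-local
#' for minus-strand rows). Blocks lacking a row for the reference species
#' are skipped with a warning; malformed lines raise an error naming the
#' line number.
#'
#' @param path MAF file path.
#' @param reference species key of the reference genome (e.g. `"hg19"`).
#' @return list of `alignment_block` objects, in file order. Each block has
#'   `ref_chrom`, `ref_start` (0-based), `ref_size` and a data frame `rows`
#'   with columns species, chrom, start, size, strand, src_size, text.
#' @export
read_maf <- function(path, reference) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush_block <- function(cur) {
    if (is.null(cur) || nrow(cur) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L)
      stop("alignment rows of unequal length in block ending near line ",
           cur$line[nrow(cur)])
    ref <- cur[cur$species == reference, , drop = FALSE]
    if (nrow(ref) == 0L) {
      warning("block without reference species '", reference,
              "' skipped (line ", cur$line[1L], ")")
      return(NULL)
    }
    ref <- ref[1L, ]
    ungapped <- nchar(gsub("-", "", ref$text, fixed = TRUE))
    if (ungapped != ref$size)
      stop("reference row size mismatch at line ", ref$line)
    structure(list(ref_chrom = ref$chrom, ref_start = ref$start,
                   ref_size = ref$size,
                   rows = cur[, c("species", "chrom", "start", "size",
                                  "strand", "src_size", "text")]),
              class = "alignment_block")
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^a\\b", line) || grepl("^a$", line)) {
      b <- flush_block(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- data.frame(species = character(), chrom = character(),
                        start = integer(), size = integer(),
                        strand = character(), src_size = integer(),
                        text = character(), line = integer())
    } else if (grepl("^s\\s", line)) {
      if (is.null(cur)) stop("s line outside a block at line ", i)
      f <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(f) != 7L) stop("malformed s line at line ", i)
      src <- f[2L]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0L) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0L) substr(src, dot + 1L, nchar(src)) else ""
      start <- suppressWarnings(as.integer(f[3L]))
      size <- suppressWarnings(as.integer(f[4L]))
      src_size <- suppressWarnings(as.integer(f[6L]))
      if (is.na(start) || is.na(size) || is.na(src_size) ||
          !f[5L] %in% c("+", "-"))
        stop("malformed s line at line ", i)
      cur <- rbind(cur, data.frame(
        species = species, chrom = chrom, start = start, size = size,
        strand = f[5L], src_size = src_size, text = toupper(f[7L]),
        line = i))
    }
    # i/e/q and comment lines are ignored
  }
  b <- flush_block(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write alignment blocks to MAF
#'
#' Inverse of [read_maf()]; round-tripping a file through
#' `read_maf()`/`write_maf()` preserves every block.
#'
#' @param blocks list of `alignment_block` objects.
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a", con)
    r <- b$rows
    src <- ifelse(nchar(r$chrom) > 0L, paste0(r$species, ".", r$chrom),
                  r$species)
    writeLines(sprintf("s %s %d %d %s %d %s", src, r$start, r$size,
                       r$strand, r$src_size, r$text), con)
  }
  invisible(path)
}

#' Forward-strand start coordinate of a MAF row
#'
#' MAF stores minus-strand rows with coordinates counted from the start of
#' the reverse-complemented source; this converts to the conventional
#' forward-strand 0-based start.
#'
#' @param row one row of a block's `rows` data frame.
#' @return 0-based forward-strand start.
#' @export
maf_forward_start <- function(row) {
  ifelse(row$strand == "-", row$src_size - row$start - row$size, row$start)
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("alignment_block ", x$ref_chrom, ":", x$ref_start, "-",
      x$ref_start + x$ref_size, " (", nrow(x$rows), " rows)\n", sep = "")
  invisible(x)
}
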