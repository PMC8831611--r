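# Internal constructor; columns are plus-strand reference positions
# window[1]..window[2]-1. species_mat entries: A/C/G/T, "-" (gap in the
# species row), "." (no alignment). probe_cols / cpg_cols index into the
# matrix columns.
new_site_alignment <- function(chrom, cpg_position, window, option,
                               probe_length, ref_cols, species_mat,
                               insertion, reference) {
  pw <- probe_window(cpg_position, option$type, option$strand, probe_length)
  cols <- seq.int(window[1L], window[2L] - 1L)
  probe_cols <- which(cols >= pw[1L] & cols < pw[2L])
  cpg_cols <- which(cols == cpg_position | cols == cpg_position + 1L)
  cpg_conserved <- apply(species_mat[, cpg_cols, drop = FALSE], 1L,
                         function(x) identical(unname(x), c("C", "G")))
  structure(list(
    chrom = chrom, cpg_position = cpg_position, window = window,
    option = option, probe_length = probe_length,
    ref_cols = ref_cols, species_mat = species_mat,
    probe_cols = probe_cols, cpg_cols = cpg_cols,
    insertion = insertion, cpg_conserved = cpg_conserved,
    reference = reference), class = "site_alignment")
}

#' @export
print.site_alignment <- function(x, ...) {
  cat("site_alignment ", x$chrom, ":", x$cpg_position, " (", x$option$type,
      " ", x$option$strand, "), ", nrow(x$species_mat), " species\n",
      sep = "")
  invisible(x)
}

#' Extract the per-CpG probe-window alignment
#'
#' Slices the multiple alignment around one CpG site for a given design
#' option. Every reference column of the probe window plus the two CpG
#' columns is classified per species as A/C/G/T, `-` (the species has a
#' gap at an aligned column) or `.` (the column falls outside any
#' alignment for that species). Species carrying an insertion relative to
#' the reference inside the window are flagged. Only the alignment block
#' covering the CpG columns is used; window columns outside it are
#' unaligned.
#'
#' @param blocks list of `alignment_block` from [read_maf()].
#' @param genome a [ref_genome()].
#' @param chrom chromosome name.
#' @param cpg_position 0-based C position; must be a CpG in the reference.
#' @param option one-row data frame with `type` and `strand`.
#' @param probe_length probe length (default 50).
#' @param species optional species universe; species absent from the
#'   covering block get all-unaligned rows. Defaults to the species present
#'   in the covering block.
#' @return a `site_alignment`, or a `site_skip` object whose `reason` is
#'   one of `"window_out_of_bounds"`, `"reference_N"`, `"no_alignment"`
#'   when the site cannot be used for this option.
#' @export
extract_site_alignment <- function(blocks, genome, chrom, cpg_position,
                                   option, probe_length = 50L,
                                   species = NULL) {
  if (!chrom %in% names(genome$sequences))
    stop("unknown chromosome: ", chrom)
  seqlen <- nchar(genome$sequences[[chrom]])
  if (genome_slice(genome, chrom, cpg_position, cpg_position + 2L) != "CG")
    stop("position ", cpg_position, " is not a CpG on ", chrom)
  w <- site_window(cpg_position, option$type, option$strand, probe_length)
  if (w[1L] < 0L || w[2L] > seqlen)
    return(site_skip("window_out_of_bounds"))
  ref_seq <- genome_slice(genome, chrom, w[1L], w[2L])
  if (grepl("N", ref_seq, fixed = TRUE))
    return(site_skip("reference_N"))
  ref_cols <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]

  # the block whose reference span contains the CpG columns
  blk <- NULL
  for (b in blocks) {
    if (b$ref_chrom == chrom && b$ref_start <= cpg_position &&
        b$ref_start + b$ref_size >= cpg_position + 2L) { blk <- b; break }
  }
  if (is.null(blk)) return(site_skip("no_alignment"))

  rows <- blk$rows
  blk_species <- setdiff(unique(rows$species), "")
  if (is.null(species)) species <- blk_species
  width <- w[2L] - w[1L]
  mat <- matrix(".", nrow = length(species), ncol = width,
                dimnames = list(species, NULL))
  insertion <- stats::setNames(rep(FALSE, length(species)), species)

  # reference row: identified by the block's anchor chrom/start/size
  # (read_maf guarantees its presence)
  ref_row <- rows[rows$chrom == blk$ref_chrom & rows$start == blk$ref_start &
                  rows$size == blk$ref_size, , drop = FALSE][1L, ]
  ref_text <- strsplit(ref_row$text, "", fixed = TRUE)[[1L]]
  is_base <- ref_text != "-"
  # alignment column -> 0-based reference position (NA at ref gaps)
  ref_pos <- rep(NA_integer_, length(ref_text))
  ref_pos[is_base] <- seq.int(blk$ref_start,
                              blk$ref_start + blk$ref_size - 1L)
  in_win <- !is.na(ref_pos) & ref_pos >= w[1L] & ref_pos < w[2L]
  win_cols <- ref_pos[in_win] - w[1L] + 1L     # matrix column indices
  aln_cols <- which(in_win)                    # alignment column indices

  for (sp in species) {
    srow <- rows[rows$species == sp, , drop = FALSE]
    if (nrow(srow) == 0L) next                 # stays all-unaligned
    stext <- strsplit(srow$text[1L], "", fixed = TRUE)[[1L]]
    mat[sp, win_cols] <- stext[aln_cols]
    # insertion: species base at a reference-gap column strictly between
    # the first and last window columns
    if (length(aln_cols) > 1L) {
      between <- seq.int(min(aln_cols), max(aln_cols))
      gap_cols <- between[is.na(ref_pos[between])]
      if (any(stext[gap_cols] != "-")) insertion[sp] <- TRUE
    }
  }
  # the reference species row must mirror the reference sequence
  ref_sp <- ref_row$species
  if (ref_sp %in% species) {
    mat[ref_sp, ] <- ref_cols
    insertion[ref_sp] <- FALSE
  }
  new_site_alignment(chrom, cpg_position, w, option, probe_length,
                     ref_cols, mat, insertion, ref_sp)
}

# lightweight marker for sites unusable under a given design option
site_skip <- function(reason) structure(list(reason = reason),
                                        class = "site_skip")
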