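#' The four Infinium probe design options
#'
#' Infinium chemistry offers two probe types (I and II) and either genomic
#' strand, giving four design options per CpG.
#'
#' @return data frame with columns `type` and `strand`.
#' @export
design_options <- function() {
  expand.grid(type = c("TypeI", "TypeII"),
              strand = c("forward", "reverse"),
              stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)[, c("type", "strand")]
}

#' Probe window for a design option
#'
#' Probes are `probe_length`-mers flanking the target CpG (C at `site`,
#' G at `site + 1`). The geometry convention used throughout the package:
#' Type II forward occupies the `probe_length` bases immediately 5' of the
#' C (CpG excluded from the window); Type I forward ends at and includes
#' the C. Reverse designs mirror these symmetrically about the G.
#'
#' @param site 0-based reference position of the C.
#' @param type `"TypeI"` or `"TypeII"`.
#' @param strand `"forward"` or `"reverse"`.
#' @param probe_length probe length in bases (default 50).
#' @return integer c(start, end), 0-based half-open, or NULL with a reason
#'   attribute via [probe_window_ok()] checks downstream.
#' @export
probe_window <- function(site, type = c("TypeI", "TypeII"),
                         strand = c("forward", "reverse"),
                         probe_length = 50L) {
  type <- match.arg(type)
  strand <- match.arg(strand)
  L <- as.integer(probe_length)
  if (strand == "forward") {
    if (type == "TypeII") c(site - L, site)          # excludes CpG
    else c(site - L + 1L, site + 1L)                 # ends at the C
  } else {
    # mirror about the G at site + 1
    if (type == "TypeII") c(site + 2L, site + 2L + L)
    else c(site + 1L, site + 1L + L)                 # starts at the G
  }
}

# window that a site alignment must cover: probe window plus CpG columns
site_window <- function(site, type, strand, probe_length = 50L) {
  w <- probe_window(site, type, strand, probe_length)
  c(min(w[1L], site), max(w[2L], site + 2L))
}

#' Maximum degenerate-base budget for a probe
#'
#' At most `design_cap` degenerate bases fit in a probe (default 3, the
#' chemistry limit). For Type II probes, every CpG dinucleotide present in
#' the probe sequence other than the target itself consumes one slot of the
#' budget; Type I probes are not charged for CpG content. `design_cap` may
#' be a function of the window sequence, standing in for a vendor design
#' score.
#'
#' @param type `"TypeI"` or `"TypeII"`.
#' @param window_seq the probe-window reference sequence (plus strand).
#' @param design_cap integer cap, or a function `window_seq -> integer`.
#' @return integer budget >= 0.
#' @export
max_degenerate_budget <- function(type, window_seq, design_cap = 3L) {
  cap <- if (is.function(design_cap)) design_cap(window_seq)
         else as.integer(design_cap)
  if (type == "TypeI") return(cap)
  n_cg <- length(gregexpr("(?=CG)", window_seq, perl = TRUE)[[1L]])
  if (gregexpr("(?=CG)", window_seq, perl = TRUE)[[1L]][1L] == -1L)
    n_cg <- 0L
  max(0L, cap - n_cg)
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"), K = c("G", "T"),
  S = c("C", "G"), W = c("A", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Minimal IUPAC code covering a set of bases
#'
#' @param bases character vector drawn from A/C/G/T.
#' @return single IUPAC symbol.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be A/C/G/T")
  key <- paste(bases, collapse = "")
  hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
    identical(sort(s), bases), logical(1L))]
  if (length(hit) == 0L) stop("no IUPAC code for ", key)
  hit[1L]
}

#' Expand a degenerate probe sequence
#'
#' Every IUPAC ambiguity position is expanded so that the result contains
#' one explicit sequence for each combination of alternatives; the
#' cardinality is the product over degenerate positions of the number of
#' bases each code covers. The reference allele is always among them by
#' construction of the codes.
#'
#' @param seq sequence over A/C/G/T plus IUPAC ambiguity codes.
#' @return character vector of explicit A/C/G/T sequences.
#' @export
expand_degenerate <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  unknown <- setdiff(chars, names(IUPAC_SETS))
  if (length(unknown) > 0L)
    stop("unknown symbol(s): ", paste(unknown, collapse = ", "))
  sets <- IUPAC_SETS[chars]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

#' Build the IUPAC probe sequence for a designed candidate
#'
#' Constructs the probe in its own 5' to 3' orientation: forward designs
#' read the plus strand of the window; reverse designs are the reverse
#' complement. Degenerate positions (given as 0-based offsets within the
#' plus-strand window, with their alternate alleles) are written as the
#' minimal IUPAC code covering reference plus alternates.
#'
#' @param genome a [ref_genome()].
#' @param chrom chromosome name.
#' @param site 0-based C position of the target CpG.
#' @param type,strand design option.
#' @param degenerate data frame with columns `offset` (0-based plus-strand
#'   window offset) and `alternate`; may be empty or NULL.
#' @param probe_length probe length (default 50).
#' @return IUPAC probe sequence string.
#' @export
probe_sequence <- function(genome, chrom, site, type, strand,
                           degenerate = NULL, probe_length = 50L) {
  w <- probe_window(site, type, strand, probe_length)
  chars <- strsplit(genome_slice(genome, chrom, w[1L], w[2L]), "",
                    fixed = TRUE)[[1L]]
  if (!is.null(degenerate) && nrow(degenerate) > 0L) {
    for (off in unique(degenerate$offset)) {
      alts <- degenerate$alternate[degenerate$offset == off]
      j <- off + 1L
      chars[j] <- iupac_code(c(chars[j], alts))
    }
  }
  seq <- paste(chars, collapse = "")
  if (strand == "reverse") reverse_complement(seq) else seq
}
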