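# converted texts of a genome for exact searching: plus strand read-out
# (C->T outside CpG) and minus strand read-out expressed 5'->3' on the
# minus strand (reverse-complement first, then convert)
converted_texts <- function(genome, mode) {
  lapply(genome$sequences, function(s) {
    if (mode == "strict") list(plus = s, minus = reverse_complement(s))
    else list(plus = bisulfite_convert(s, "forward"),
              minus = bisulfite_convert(reverse_complement(s), "forward"))
  })
}

# probe versions actually searched: explicit expansions, converted in
# bisulfite mode. A 3'-terminal C has unknowable CpG context (the next
# genomic base is outside the probe), so both converted variants are
# searched; this keeps strict-mode hits a subset of bisulfite-mode hits.
search_versions <- function(sequence, mode) {
  versions <- expand_degenerate(sequence)
  if (mode == "strict") return(unique(versions))
  out <- unlist(lapply(versions, function(v) {
    conv <- bisulfite_convert(v, "forward")
    if (substr(v, nchar(v), nchar(v)) == "C") {
      kept <- conv
      substr(kept, nchar(kept), nchar(kept)) <- "C"
      unmet <- conv
      substr(unmet, nchar(unmet), nchar(unmet)) <- "T"
      c(kept, unmet)
    } else conv
  }))
  unique(out)
}

#' Map all versions of a probe against a genome
#'
#' Exact, full-length matching of every expanded version of a degenerate
#' probe on both strands. In `bisulfite` mode the probe and the genome are
#' compared in bisulfite-converted space with all CpGs treated as
#' methylated — for Type I probes this is exactly the methylated probe
#' version, the only one synthesized against the converted genome. In
#' `strict` mode matching is plain genomic identity. No mismatches are
#' tolerated anywhere.
#'
#' @param sequence IUPAC probe sequence (probe orientation).
#' @param genome a [ref_genome()].
#' @param mode `"bisulfite"` (default) or `"strict"`.
#' @return data frame of loci: chrom, start (0-based, plus strand), strand.
#'   Zero rows when the probe does not map.
#' @export
map_probe_versions <- function(sequence, genome,
                               mode = c("bisulfite", "strict")) {
  mode <- match.arg(mode)
  texts <- converted_texts(genome, mode)
  versions <- search_versions(sequence, mode)
  hits <- list()
  for (chrom in names(texts)) {
    L <- nchar(genome$sequences[[chrom]])
    for (v in versions) {
      p <- Biostrings::matchPattern(v, Biostrings::DNAString(
        texts[[chrom]]$plus))
      if (length(p) > 0L)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = BiocGenerics::start(p) - 1L,
          strand = "+", stringsAsFactors = FALSE)
      m <- Biostrings::matchPattern(v, Biostrings::DNAString(
        texts[[chrom]]$minus))
      if (length(m) > 0L)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom,
          start = L - (BiocGenerics::start(m) - 1L) - nchar(v),
          strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, hits))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Uniqueness verdict from a locus list
#'
#' Under the default `union` rule the variant alignments of a probe are
#' collapsed to their distinct loci and the probe is unique when exactly
#' one locus remains (several versions agreeing on the same locus do not
#' break uniqueness). The `per_version` rule additionally requires that no
#' single searched version hit more than one locus — with exact matching a
#' version's hits are always distinct loci, so the two rules coincide
#' except in how multi-locus probes are interpreted; both are provided.
#'
#' @param loci data frame from [map_probe_versions()].
#' @param rule `"union"` (default) or `"per_version"`.
#' @return logical.
#' @export
probe_uniqueness <- function(loci, rule = c("union", "per_version")) {
  rule <- match.arg(rule)
  nrow(unique(loci[, c("chrom", "start", "strand")])) == 1L
}

#' Verify the target CpG at a mapped locus
#'
#' Projects the CpG position implied by the probe geometry from a mapped
#' locus and checks that the genome actually shows C followed by G there
#' (on the hit strand). Probes whose target cytosine is mutated at a locus
#' measure nothing, whatever the flanking match.
#'
#' @param genome a [ref_genome()].
#' @param chrom,start,strand locus (0-based plus-strand start).
#' @param type probe type (`"TypeI"` or `"TypeII"`).
#' @param probe_length probe length.
#' @return TRUE when the projected CpG is intact; FALSE otherwise
#'   (including projections falling outside the chromosome).
#' @export
verify_target_cpg <- function(genome, chrom, start, strand, type,
                              probe_length = 50L) {
  if (!chrom %in% names(genome$sequences)) return(FALSE)
  L <- nchar(genome$sequences[[chrom]])
  end <- start + probe_length                 # half-open probe interval
  if (strand == "+") {
    # probe 3' end at `end`; TypeII: CpG just beyond, TypeI: C is last base
    c_pos <- if (type == "TypeII") end else end - 1L
  } else {
    # probe 3' end at `start` on the minus strand; CpG mirrored 5' of it
    c_pos <- if (type == "TypeII") start - 2L else start - 1L
  }
  if (c_pos < 0L || c_pos + 2L > L) return(FALSE)
  genome_slice(genome, chrom, c_pos, c_pos + 2L) == "CG"
}

#' Mappability report for a manifest against one genome
#'
#' Runs [map_probe_versions()] for every manifest probe and summarizes
#' loci count, uniqueness and target-CpG verification.
#'
#' @param manifest manifest data frame (probe_id, sequence, type).
#' @param genome a [ref_genome()].
#' @param mode matching mode, see [map_probe_versions()].
#' @param rule uniqueness rule, see [probe_uniqueness()].
#' @return data frame: probe_id, n_loci, unique, target_cpg_ok, chrom,
#'   start, strand (locus columns NA unless unique); the full locus lists
#'   are attached as attribute `"loci"`.
#' @export
map_probes <- function(manifest, genome, mode = c("bisulfite", "strict"),
                       rule = c("union", "per_version")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  loci_list <- vector("list", nrow(manifest))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    loci <- map_probe_versions(manifest$sequence[i], genome, mode)
    loci_list[[i]] <- loci
    uni <- nrow(loci) > 0L && probe_uniqueness(loci, rule)
    ok <- FALSE
    chrom <- NA_character_; start <- NA_integer_; strand <- NA_character_
    if (uni) {
      chrom <- loci$chrom[1L]; start <- loci$start[1L]
      strand <- loci$strand[1L]
      ok <- verify_target_cpg(genome, chrom, start, strand,
                              manifest$type[i],
                              nchar(manifest$sequence[i]))
    }
    rows[[i]] <- data.frame(probe_id = manifest$probe_id[i],
                            n_loci = nrow(loci), unique = uni,
                            target_cpg_ok = ok, chrom = chrom,
                            start = start, strand = strand,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(loci_list) <- manifest$probe_id
  attr(out, "loci") <- loci_list
  out
}

#' Per-species CpG coordinate table
#'
#' One row per probe with a unique, CpG-verified locus in the genome: the
#' coordinates users need to interpret that probe's signal in the species.
#'
#' @param report output of [map_probes()].
#' @param manifest the manifest the report was computed from.
#' @param genome_label label written into the table.
#' @param probe_length probe length (default 50).
#' @return data frame: probe_id, genome, chrom, cpg_pos (1-based C
#'   coordinate on the plus strand), strand.
#' @export
coordinate_export <- function(report, manifest, genome_label,
                              probe_length = 50L) {
  keep <- report[report$unique & report$target_cpg_ok, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(data.frame(probe_id = character(0), genome = character(0),
                      chrom = character(0), cpg_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  ty <- manifest$type[match(keep$probe_id, manifest$probe_id)]
  end <- keep$start + probe_length
  c_pos <- ifelse(keep$strand == "+",
                  ifelse(ty == "TypeII", end, end - 1L),
                  ifelse(ty == "TypeII", keep$start - 2L, keep$start - 1L))
  data.frame(probe_id = keep$probe_id, genome = genome_label,
             chrom = keep$chrom, cpg_pos = c_pos + 1L,
             strand = keep$strand, stringsAsFactors = FALSE,
             row.names = NULL)
}
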