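#' Reference genome container
#'
#' A minimal in-memory genome: a named set of chromosome sequences over the
#' alphabet A/C/G/T/N plus a free-text assembly label. All coordinates used
#' by the package are 0-based, half-open; 1-based coordinates appear only in
#' exported tables and are labelled as such.
#'
#' @param sequences named character vector, one uppercase nucleotide string
#'   per chromosome.
#' @param assembly free-text assembly label (e.g. `"toyRef1"`).
#' @return an object of class `ref_genome`.
#' @export
ref_genome <- function(sequences, assembly = "") {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L))
    stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence for ", names(sequences)[bad][1L],
         " contains characters outside A/C/G/T/N")
  structure(list(sequences = sequences, assembly = assembly),
            class = "ref_genome")
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @param assembly assembly label; defaults to the file name without
#'   extension.
#' @return a [ref_genome()].
#' @export
read_genome_fasta <- function(path, assembly = NULL) {
  if (is.null(assembly))
    assembly <- tools::file_path_sans_ext(basename(path))
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ref_genome(seqs, assembly)
}

#' Write a genome to FASTA
#'
#' @param genome a [ref_genome()].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ref_genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequences), path)
  invisible(path)
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("ref_genome:", x$assembly, "-", length(x$sequences),
      "sequence(s),", sum(nchar(x$sequences)), "bp total\n")
  invisible(x)
}

# 0-based half-open slice of a chromosome; errors outside bounds
genome_slice <- function(genome, chrom, start0, end0) {
  if (!chrom %in% names(genome$sequences))
    stop("unknown chromosome: ", chrom)
  seq <- genome$sequences[[chrom]]
  if (start0 < 0 || end0 > nchar(seq) || start0 > end0)
    stop("interval [", start0, ", ", end0, ") outside ", chrom)
  substr(seq, start0 + 1L, end0)
}

#' Enumerate CpG sites on a chromosome
#'
#' Returns the 0-based positions of every cytosine that is immediately
#' followed by a guanine on the forward strand. Overlapping CGCG runs yield
#' both sites.
#'
#' @param genome a [ref_genome()].
#' @param chrom chromosome name.
#' @return sorted integer vector of 0-based C positions.
#' @export
enumerate_cpg_sites <- function(genome, chrom) {
  if (!chrom %in% names(genome$sequences))
    stop("unknown chromosome: ", chrom)
  seq <- genome$sequences[[chrom]]
  m <- gregexpr("(?=CG)", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Export CpG sites as BED intervals
#'
#' One 2-bp interval (C and G) per site, 0-based half-open.
#'
#' @param chrom chromosome name.
#' @param sites 0-based C positions.
#' @param path output BED path.
#' @export
cpg_sites_to_bed <- function(chrom, sites, path) {
  df <- data.frame(chrom = chrom, start = sites, end = sites + 2L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Handles IUPAC ambiguity codes, so degenerate probe sequences can be
#' mirrored between strands.
#'
#' @param seq nucleotide string (A/C/G/T/N plus IUPAC codes).
#' @return the reverse complement.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTRYMKSWBDHVN", "TGCAYRKMSWVHDBN", toupper(seq))
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE)
}

#' In-silico bisulfite conversion
#'
#' Converts a sequence the way bisulfite treatment reads it out. On the
#' forward strand every cytosine becomes thymine except, in
#' `all_CpG_methylated` mode, cytosines immediately followed by guanine
#' (methylated CpGs are protected). Reverse-strand conversion is expressed
#' on the forward-strand text as G to A with the mirrored CpG exception
#' (G preceded by C is protected). Length is always preserved.
#'
#' @param seq nucleotide string.
#' @param strand `"forward"` or `"reverse"`.
#' @param methylation_mode `"all_CpG_methylated"` (default) or
#'   `"fully_unmethylated"`.
#' @return converted sequence, same length.
#' @export
bisulfite_convert <- function(seq, strand = c("forward", "reverse"),
                              methylation_mode = c("all_CpG_methylated",
                                                   "fully_unmethylated")) {
  strand <- match.arg(strand)
  methylation_mode <- match.arg(methylation_mode)
  seq <- toupper(seq)
  if (strand == "forward") {
    if (methylation_mode == "fully_unmethylated") chartr("C", "T", seq)
    else gsub("C(?!G)", "T", seq, perl = TRUE)
  } else {
    if (methylation_mode == "fully_unmethylated") chartr("G", "A", seq)
    else gsub("(?<!C)G", "A", seq, perl = TRUE)
  }
}
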