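#' Read a gene model from GFF3/GTF
#'
#' Imports gene, exon and UTR features and derives per-gene transcription
#' start sites (strand-aware) and introns (gene body minus exons).
#' Features are grouped by the `ID` attribute of gene records and the
#' `Parent` attribute of their children; a `gene_id` attribute is used
#' when present (GTF).
#'
#' @param path GFF3/GTF file.
#' @return list of class `gene_model`: `genes` (data frame gene_id, chrom,
#'   strand, start, end, tss — 1-based), plus `GRanges` for exons,
#'   five_prime_utr, three_prime_utr, introns, each carrying `gene_id`.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  gene_id_of <- function(i) {
    for (fld in c("gene_id", "ID", "Parent")) {
      v <- md[[fld]]
      if (!is.null(v)) {
        x <- if (methods::is(v, "CharacterList")) {
          vapply(v[i], function(e) if (length(e)) e[[1L]] else NA_character_,
                 character(1L))
        } else as.character(v[i])
        if (!all(is.na(x))) return(x)
      }
    }
    rep(NA_character_, length(i))
  }
  ty <- tolower(as.character(md$type))
  gi <- which(ty == "gene")
  genes <- data.frame(
    gene_id = gene_id_of(gi),
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(BiocGenerics::strand(gr)[gi]),
    start = BiocGenerics::start(gr)[gi], end = BiocGenerics::end(gr)[gi],
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

  pick <- function(types) {
    idx <- which(ty %in% types)
    g <- gr[idx]
    ids <- character(length(idx))
    if (length(idx) > 0L) {
      # children reference their gene via Parent (or gene_id in GTF)
      par <- md[["Parent"]]
      if (!is.null(par)) {
        ids <- vapply(par[idx], function(e)
          if (length(e)) e[[1L]] else NA_character_, character(1L))
      }
      gid <- md[["gene_id"]]
      if (!is.null(gid)) {
        g2 <- as.character(gid[idx])
        ids[is.na(ids) | !nzchar(ids)] <- g2[is.na(ids) | !nzchar(ids)]
      }
      # strip transcript-level parents down to the owning gene when the
      # parent id matches a known gene after removing a trailing ".tN"
      ids[!ids %in% genes$gene_id] <-
        sub("\\.t\\d+$", "", ids[!ids %in% genes$gene_id])
    }
    S4Vectors::mcols(g)$gene_id <- ids
    g
  }
  exons <- pick("exon")
  utr5 <- pick(c("five_prime_utr", "5utr", "five_prime_UTR"))
  utr3 <- pick(c("three_prime_utr", "3utr", "three_prime_UTR"))

  introns_list <- list()
  for (i in seq_len(nrow(genes))) {
    body <- GenomicRanges::GRanges(
      genes$chrom[i], IRanges::IRanges(genes$start[i], genes$end[i]))
    ex <- exons[S4Vectors::mcols(exons)$gene_id == genes$gene_id[i]]
    intr <- GenomicRanges::setdiff(body,
                                   GenomicRanges::reduce(
                                     GenomicRanges::granges(ex)))
    if (length(intr) > 0L) {
      S4Vectors::mcols(intr)$gene_id <- genes$gene_id[i]
      introns_list[[length(introns_list) + 1L]] <- intr
    }
  }
  introns <- if (length(introns_list) > 0L)
    do.call(c, introns_list)
  else GenomicRanges::GRanges(gene_id = character(0))
  structure(list(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
                 introns = introns), class = "gene_model")
}

# promoter windows, gene-strand oriented: 10 kb upstream to 100 bp
# downstream of the TSS (1-based inclusive coordinates)
promoter_ranges <- function(genes, upstream = 10000L, downstream = 100L) {
  start <- ifelse(genes$strand == "-", genes$tss - downstream,
                  genes$tss - upstream)
  end <- ifelse(genes$strand == "-", genes$tss + upstream,
                genes$tss + downstream)
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(pmax(1L, start), end),
                         gene_id = genes$gene_id)
}

#' Assign gene regions to CpG positions
#'
#' Each CpG (the C base, 1 bp) receives exactly one category, resolved in
#' the fixed priority order exon > promoter > intron > 5' UTR > 3' UTR >
#' intergenic, where the promoter spans 10 kb upstream to 100 bp
#' downstream of the nearest TSS in gene orientation. The nearest gene by
#' TSS distance and the signed distance (positive downstream of the TSS
#' in gene orientation) are reported for every CpG.
#'
#' @param cpgs data frame with columns `chrom` and `pos` (1-based C
#'   coordinate) and optionally `probe_id`.
#' @param gene_model a [read_gene_model()] result.
#' @return data frame: probe_id (if given), chrom, pos, category,
#'   nearest_gene, dist_tss.
#' @export
assign_gene_region <- function(cpgs, gene_model) {
  genes <- gene_model$genes
  n <- nrow(cpgs)
  category <- rep("intergenic", n)
  nearest_gene <- rep(NA_character_, n)
  dist_tss <- rep(NA_integer_, n)
  if (nrow(genes) > 0L) {
    q <- GenomicRanges::GRanges(cpgs$chrom,
                                IRanges::IRanges(cpgs$pos, width = 1L))
    layers <- list(exon = gene_model$exons,
                   promoter = promoter_ranges(genes),
                   intron = gene_model$introns,
                   five_prime_UTR = gene_model$utr5,
                   three_prime_UTR = gene_model$utr3)
    for (nm in rev(names(layers))) {      # apply lowest priority first
      hits <- GenomicRanges::findOverlaps(q, layers[[nm]],
                                          ignore.strand = TRUE)
      category[unique(S4Vectors::queryHits(hits))] <- nm
    }
    # order above walked reversed, so exon overwrote promoter etc.
    for (i in seq_len(n)) {
      same <- which(genes$chrom == cpgs$chrom[i])
      if (length(same) == 0L) next
      d <- cpgs$pos[i] - genes$tss[same]
      j <- same[which.min(abs(d))]
      nearest_gene[i] <- genes$gene_id[j]
      sign <- if (genes$strand[j] == "-") -1L else 1L
      dist_tss[i] <- sign * (cpgs$pos[i] - genes$tss[j])
    }
  }
  out <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos,
                    category = category, nearest_gene = nearest_gene,
                    dist_tss = dist_tss, stringsAsFactors = FALSE)
  if (!is.null(cpgs$probe_id)) out <- cbind(probe_id = cpgs$probe_id, out)
  out
}

#' Overlap CpGs with an interval set
#'
#' Tests whether each CpG base (1 bp, the C) falls inside any interval of
#' a BED-style set (0-based half-open). The interval start coordinate is
#' inside; the end coordinate is not.
#'
#' @param cpgs data frame with `chrom` and `pos` (1-based C coordinate).
#' @param intervals a `GRanges`, or a path to a BED file.
#' @return logical vector, one entry per CpG.
#' @export
overlap_annotate <- function(cpgs, intervals) {
  if (is.character(intervals)) {
    lines <- readLines(intervals)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, function(p)
      length(p) < 3L || is.na(suppressWarnings(as.integer(p[2L]))) ||
        is.na(suppressWarnings(as.integer(p[3L]))), logical(1L)))
    if (length(bad) > 0L)
      stop("malformed BED line ", bad[1L], " in ", intervals)
    intervals <- GenomicRanges::GRanges(
      vapply(parts, `[`, "", 1L),
      IRanges::IRanges(as.integer(vapply(parts, `[`, "", 2L)) + 1L,
                       as.integer(vapply(parts, `[`, "", 3L))))
  }
  if (length(intervals) == 0L) return(rep(FALSE, nrow(cpgs)))
  q <- GenomicRanges::GRanges(cpgs$chrom,
                              IRanges::IRanges(cpgs$pos, width = 1L))
  IRanges::overlapsAny(q, intervals, ignore.strand = TRUE)
}

#' Fold enrichment against a background
#'
#' Fold = (k_on/n_on) / (K_bg/N_bg): the fraction of array CpGs carrying
#' an annotation relative to the fraction among all background CpGs.
#'
#' @param k_on annotated CpGs on the array.
#' @param n_on total CpGs on the array.
#' @param K_bg annotated CpGs in the background.
#' @param N_bg total background CpGs.
#' @return fold enrichment; `NaN` with a warning when the background
#'   carries no annotated CpGs.
#' @export
enrichment_fold <- function(k_on, n_on, K_bg, N_bg) {
  stopifnot(n_on > 0, N_bg > 0)
  if (K_bg == 0) {
    warning("background annotation count is zero; fold undefined")
    return(NaN)
  }
  (k_on / n_on) / (K_bg / N_bg)
}

#' Ortholog concordance of gene assignments across species
#'
#' For probes annotated in both a reference species and a second species,
#' computes the fraction whose gene assignment in the second species is
#' the known ortholog of the reference assignment. Discordant probes that
#' are intergenic (outside promoters) in the second species are counted
#' separately — such cases often reflect an inaccurate assignment rather
#' than true rearrangement.
#'
#' @param ref_calls [assign_gene_region()] output for the reference, with
#'   `probe_id`.
#' @param species_calls same for the other species.
#' @param ortholog_table data frame `ref_gene`, `species_gene`.
#' @return list: `concordance` (fraction), `n` (probes compared),
#'   `n_concordant`, `n_discordant_intergenic`.
#' @export
ortholog_concordance <- function(ref_calls, species_calls,
                                 ortholog_table) {
  if (is.null(ortholog_table)) stop("ortholog table is required")
  shared <- intersect(ref_calls$probe_id, species_calls$probe_id)
  r <- ref_calls[match(shared, ref_calls$probe_id), ]
  s <- species_calls[match(shared, species_calls$probe_id), ]
  expected <- ortholog_table$species_gene[
    match(r$nearest_gene, ortholog_table$ref_gene)]
  conc <- !is.na(expected) & !is.na(s$nearest_gene) &
    s$nearest_gene == expected
  disc_intergenic <- !conc & s$category == "intergenic"
  list(concordance = if (length(shared) > 0L) mean(conc) else NA_real_,
       n = length(shared), n_concordant = sum(conc),
       n_discordant_intergenic = sum(disc_intergenic))
}
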