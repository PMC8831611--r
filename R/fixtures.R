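#' Generate the deterministic toy fixture bundle
#'
#' Writes a self-consistent desk-scale data set exercising the whole
#' pipeline: a reference chromosome with CpGs, a multi-species alignment
#' (MAF) carrying planted substitutions, gaps and CpG losses whose optimal
#' degenerate solutions are recorded in a sidecar truth file (computed at
#' generation time by the exhaustive reference search), a second genome
#' with a planted duplicated probe target (mappability truth:
#' non-unique), a toy gene model (GFF3), CpG-island intervals (BED) and an
#' EPIC-style metadata table (CSV). Identical seeds give byte-identical
#' bundles.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_species number of aligned non-reference species (default 10).
#' @param chrom_length reference chromosome length (default 50000).
#' @return invisibly, a named list of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1L, n_species = 10L,
                          chrom_length = 50000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  chrom <- "chrT"
  bases <- c("A", "C", "G", "T")
  ref_chars <- sample(bases, chrom_length, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3))
  ref <- paste(ref_chars, collapse = "")
  genome <- ref_genome(stats::setNames(ref, chrom), "toyRef")
  species <- sprintf("sp%02d", seq_len(n_species))

  # species rows: low substitution rate, occasional gap columns
  sp_texts <- lapply(species, function(sp) {
    chars <- ref_chars
    idx <- which(stats::runif(chrom_length) < 0.01)
    chars[idx] <- vapply(chars[idx], function(b)
      sample(setdiff(bases, b), 1L), character(1L))
    gaps <- which(stats::runif(chrom_length) < 0.002)
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  names(sp_texts) <- species
  rows <- data.frame(
    species = c("toyRef", species), chrom = chrom,
    start = 0L, size = chrom_length, strand = "+",
    src_size = chrom_length,
    text = c(ref, unlist(sp_texts, use.names = FALSE)),
    stringsAsFactors = FALSE)
  # species sizes must discount gap columns
  rows$size <- nchar(gsub("-", "", rows$text, fixed = TRUE))
  blocks <- list(structure(list(ref_chrom = chrom, ref_start = 0L,
                                ref_size = chrom_length, rows = rows),
                           class = "alignment_block"))
  maf_path <- file.path(dir, "toy_alignment.maf")
  write_maf(blocks, maf_path)
  fasta_path <- file.path(dir, "toy_reference.fa")
  write_genome_fasta(genome, fasta_path)

  # target genome with a planted duplicated 50-mer probe target
  sites <- enumerate_cpg_sites(genome, chrom)
  inner <- sites[sites > 100 & sites < chrom_length - 100]
  dup_site <- inner[ceiling(length(inner) / 2)]
  dup_window <- genome_slice(genome, chrom, dup_site - 50L, dup_site + 2L)
  target_seq <- paste0(substr(ref, 1L, 20000L), dup_window,
                       substr(ref, 20001L, chrom_length))
  target <- ref_genome(stats::setNames(target_seq, chrom), "toyTarget")
  target_path <- file.path(dir, "toy_target.fa")
  write_genome_fasta(target, target_path)

  # toy gene model: genes every ~10 kb with exons and UTRs
  gff_path <- file.path(dir, "toy_genes.gff3")
  gff <- c("##gff-version 3")
  gid <- 0L
  gene_step <- max(5000L, min(10000L, chrom_length %/% 5L))
  for (gs in seq(min(2000L, chrom_length %/% 10L),
                 max(2001L, chrom_length - 5000L), by = gene_step)) {
    gid <- gid + 1L
    id <- sprintf("gene%02d", gid)
    strand <- if (gid %% 2L == 0L) "-" else "+"
    ge <- min(gs + 3999L, chrom_length - 100L)
    gff <- c(gff,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom, gs, ge,
              strand, id),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s", chrom, gs,
              gs + 499L, strand, id),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tParent=%s", chrom,
              gs + 2000L, gs + 2499L, strand, id),
      sprintf("%s\ttoy\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
              chrom, gs, gs + 99L, strand, id),
      sprintf("%s\ttoy\tthree_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
              chrom, gs + 2400L, gs + 2499L, strand, id))
  }
  writeLines(gff, gff_path)

  # CpG-island style intervals
  bed_path <- file.path(dir, "toy_islands.bed")
  isl <- data.frame(chrom = chrom,
                    start = seq(1000L, chrom_length - 2000L, by = 5000L))
  isl$end <- isl$start + 400L
  utils::write.table(isl, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # EPIC-style metadata over a sample of CpG sites
  epic_path <- file.path(dir, "toy_epic.csv")
  epic_sites <- sort(sample(inner, min(30L, length(inner))))
  epic <- data.frame(cpg_id = sprintf("epic%03d", seq_along(epic_sites)),
                     chrom = chrom, pos = epic_sites + 1L,
                     type = sample(c("TypeI", "TypeII"),
                                   length(epic_sites), replace = TRUE),
                     strand = sample(c("forward", "reverse"),
                                     length(epic_sites), replace = TRUE))
  utils::write.csv(epic, epic_path, row.names = FALSE, quote = FALSE)

  # sidecar truth: exhaustive-search optimum for a handful of sites
  truth_sites <- utils::head(inner, 5L)
  truth <- lapply(truth_sites, function(s) {
    opt <- data.frame(type = "TypeII", strand = "forward",
                      stringsAsFactors = FALSE)
    sa <- extract_site_alignment(blocks, genome, chrom, s, opt)
    if (!inherits(sa, "site_alignment"))
      return(list(site = s, optimum = NA))
    prof <- build_mismatch_profile(sa, 3L)
    list(site = s,
         optimum = exhaustive_degenerate_search(prof, 3L)$coverage)
  })
  truth_path <- file.path(dir, "toy_truth.csv")
  utils::write.csv(
    data.frame(site = vapply(truth, function(t) t$site, numeric(1L)),
               optimal_coverage = vapply(truth, function(t)
                 as.numeric(t$optimum), numeric(1L)),
               dup_site = dup_site),
    truth_path, row.names = FALSE, quote = FALSE)

  invisible(list(maf = maf_path, fasta = fasta_path,
                 target_fasta = target_path, gff = gff_path,
                 bed = bed_path, epic = epic_path, truth = truth_path))
}

#' Summarize an array manifest table
#'
#' Computes headline counts from a manifest: distinct targeted cytosines
#' (by chromosome and coordinate), total probe sets (rows), and the total
#' number of explicit sequences after degenerate expansion.
#'
#' @param manifest manifest data frame (or path to a manifest CSV) with
#'   columns chrom, pos and sequence.
#' @return list: `n_unique_cytosines`, `n_probe_sets`,
#'   `n_expanded_sequences`.
#' @export
manifest_summary <- function(manifest) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  n_exp <- sum(vapply(manifest$sequence, function(s)
    length(expand_degenerate(s)), numeric(1L)))
  list(n_unique_cytosines = nrow(unique(manifest[, c("chrom", "pos")])),
       n_probe_sets = nrow(manifest),
       n_expanded_sequences = n_exp)
}
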