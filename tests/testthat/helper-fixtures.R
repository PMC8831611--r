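# shared fixtures and independent oracles used across the suite

# hand-written two-block, three-species MAF; block 2 carries a
# minus-strand row (hand-converted forward start: 1000 - 30 - 10 = 960)
toy_maf_text <- function() {
  c("##maf version=1",
    "",
    "a score=1.0",
    "s hg.chr1   10 12 + 100 ACGTACGTACGT",
    "s mm.chr5   20 12 + 200 ACGTACGAACGT",
    "s rn.chr2    5 11 + 150 ACGTAC-TACGT",
    "",
    "a score=2.0",
    "s hg.chr1   40 10 + 100 AACCGGTTAA",
    "s mm.chr5   60 10 + 200 AACCGATTAA",
    "s rn.chr2   30 10 - 150 AACCGGTTAA")
}

write_toy_maf <- function(path = tempfile(fileext = ".maf")) {
  writeLines(toy_maf_text(), path)
  path
}

# build a site_alignment from explicit species window strings; "." marks
# unaligned and "-" gaps. site sits so that the chosen geometry fits.
make_site_alignment <- function(ref_window, species_rows,
                                type = "TypeII", strand = "forward",
                                insertion = NULL) {
  probe_length <- nchar(ref_window)
  opt <- data.frame(type = type, strand = strand, stringsAsFactors = FALSE)
  site <- probe_length + 2L
  w <- consmeth:::site_window(site, type, strand, probe_length)
  width <- w[2L] - w[1L]
  cols <- seq.int(w[1L], w[2L] - 1L)
  # ref window string covers the probe window; fill CpG columns with CG
  ref_cols <- rep("A", width)
  pw <- probe_window(site, type, strand, probe_length)
  pidx <- which(cols >= pw[1L] & cols < pw[2L])
  ref_cols[pidx] <- strsplit(ref_window, "")[[1L]]
  ref_cols[cols == site] <- "C"
  ref_cols[cols == site + 1L] <- "G"
  species <- names(species_rows)
  mat <- matrix(rep(ref_cols, each = length(species) + 1L),
                nrow = length(species) + 1L,
                dimnames = list(c("ref", species), NULL))
  for (sp in species) {
    row <- species_rows[[sp]]
    stopifnot(nchar(row$window) == probe_length)
    mat[sp, pidx] <- strsplit(row$window, "")[[1L]]
    if (isTRUE(row$no_cpg)) mat[sp, which(cols == site)] <- "T"
    if (isTRUE(row$unaligned)) mat[sp, ] <- "."
  }
  ins <- stats::setNames(rep(FALSE, length(species) + 1L),
                         c("ref", species))
  if (!is.null(insertion)) ins[insertion] <- TRUE
  consmeth:::new_site_alignment("chrF", site, w, opt, probe_length,
                                ref_cols, mat, ins, "ref")
}

# brute-force CG counter (string scan)
count_cg_oracle <- function(seq) {
  chars <- strsplit(seq, "")[[1L]]
  n <- 0L
  for (i in seq_len(nchar(seq) - 1L))
    if (chars[i] == "C" && chars[i + 1L] == "G") n <- n + 1L
  n
}

# explicit cartesian-product expansion oracle
expand_oracle <- function(seq) {
  sets <- consmeth:::IUPAC_SETS[strsplit(seq, "")[[1L]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

# naive sliding-window mapping oracle: per-position character comparison
# against both strands. Bisulfite mode converts the genome with full
# genomic context and the probe with probe-internal context, allowing a
# 3'-terminal probe C to match either C or T.
naive_map_oracle <- function(sequence, genome, mode) {
  versions <- expand_degenerate(sequence)
  hits <- data.frame(chrom = character(0), start = integer(0),
                     strand = character(0))
  match_at <- function(pchars, tchars, s) {
    L <- length(pchars)
    seg <- tchars[s:(s + L - 1L)]
    if (mode == "strict") return(all(pchars == seg))
    for (i in seq_len(L)) {
      p <- pchars[i]
      g <- seg[i]
      # convert genome char with genomic context
      gnext <- if (s + i <= length(tchars)) tchars[s + i] else ""
      gc <- if (g == "C" && !identical(gnext, "G")) "T" else g
      # convert probe char with probe context; terminal C ambiguous
      pnext <- if (i < L) pchars[i + 1L] else NA
      if (p == "C" && is.na(pnext)) {
        if (!(gc %in% c("C", "T"))) return(FALSE)
      } else {
        pc <- if (p == "C" && !identical(pnext, "G")) "T" else p
        if (pc != gc) return(FALSE)
      }
    }
    TRUE
  }
  for (chrom in names(genome$sequences)) {
    text <- genome$sequences[[chrom]]
    L <- nchar(text)
    tplus <- strsplit(text, "")[[1L]]
    tminus <- strsplit(reverse_complement(text), "")[[1L]]
    for (v in versions) {
      pchars <- strsplit(v, "")[[1L]]
      pl <- length(pchars)
      if (pl > L) next
      for (s in 1:(L - pl + 1L)) {
        if (match_at(pchars, tplus, s))
          hits <- rbind(hits, data.frame(chrom = chrom, start = s - 1L,
                                         strand = "+"))
        if (match_at(pchars, tminus, s))
          hits <- rbind(hits, data.frame(chrom = chrom,
                                         start = L - (s - 1L) - pl,
                                         strand = "-"))
      }
    }
  }
  u <- unique(hits)
  u[order(u$chrom, u$start, u$strand), , drop = FALSE]
}

random_genome <- function(len, seed, chrom = "chrR") {
  set.seed(seed)
  ref_genome(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), chrom), "rand")
}
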