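#' Simulate a per-CpG site alignment
#'
#' Generates a synthetic probe-window alignment around one CpG: a random
#' reference window with the target CpG in place, and species rows derived
#' from the reference by planting substitutions, gap columns, whole-row
#' unaligned species, and CpG losses at controlled rates. This emulates
#' the local structure of a genome alignment at a conserved CpG —
#' substitution-dominated divergence with occasional indels — and is the
#' workhorse for property tests of the degenerate-base optimizer.
#'
#' @param n_species number of non-reference species.
#' @param probe_length window width in bases (default 50; 10 for small
#'   stress instances).
#' @param p_mismatch per-column substitution probability per species.
#' @param p_gap probability a species carries a gap column in the window.
#' @param p_unaligned probability a species is entirely unaligned.
#' @param p_cpg_loss probability a species has lost the target CpG.
#' @param type,strand design option for the window geometry.
#' @param seed integer seed; the instance is fully reproducible from it.
#' @return a `site_alignment` with species `sp01..spNN` and reference
#'   `ref`.
#' @export
simulate_site_alignment <- function(n_species = 8L, probe_length = 50L,
                                    p_mismatch = 0.05, p_gap = 0.02,
                                    p_unaligned = 0.05, p_cpg_loss = 0.05,
                                    type = "TypeII", strand = "forward",
                                    seed = 1L) {
  set.seed(seed)
  opt <- data.frame(type = type, strand = strand,
                    stringsAsFactors = FALSE)
  # place the CpG far enough from origin that every geometry fits
  site <- probe_length + 2L
  w <- site_window(site, type, strand, probe_length)
  width <- w[2L] - w[1L]
  cols <- seq.int(w[1L], w[2L] - 1L)
  ref_cols <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  ref_cols[cols == site] <- "C"
  ref_cols[cols == site + 1L] <- "G"
  species <- sprintf("sp%02d", seq_len(n_species))
  mat <- matrix(rep(ref_cols, each = n_species + 1L),
                nrow = n_species + 1L,
                dimnames = list(c("ref", species), NULL))
  insertion <- stats::setNames(rep(FALSE, n_species + 1L),
                               c("ref", species))
  cpg_cols <- which(cols == site | cols == site + 1L)
  for (sp in species) {
    if (stats::runif(1L) < p_unaligned) {
      mat[sp, ] <- "."
      next
    }
    for (j in seq_len(width)) {
      if (j %in% cpg_cols) next
      u <- stats::runif(1L)
      if (u < p_gap) mat[sp, j] <- "-"
      else if (u < p_gap + p_mismatch)
        mat[sp, j] <- sample(setdiff(c("A", "C", "G", "T"),
                                     mat[sp, j]), 1L)
    }
    if (stats::runif(1L) < p_cpg_loss) {
      j <- sample(cpg_cols, 1L)
      mat[sp, j] <- sample(setdiff(c("A", "C", "G", "T"), mat[sp, j]), 1L)
    }
  }
  new_site_alignment("chrSim", site, w, opt, probe_length, ref_cols, mat,
                     insertion, "ref")
}
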