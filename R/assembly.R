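#' Assembly configuration
#'
#' Parameters of the probe-selection pipeline. The defaults mirror the
#' published design: fill the array with every Type II probe expected to
#' work in the model species, top up by species coverage to a fixed total,
#' add the best EPIC-shared CpGs, then a Type I complement; the
#' mappability filter keeps probes unique in at least 80% of targeted
#' high-quality genomes unless they target at least 40 species.
#'
#' @param model_species assembly name whose coverage anchors step 1
#'   (e.g. `"mm10"`).
#' @param total_after_topup total CpG count after steps 1+2 (default
#'   53000).
#' @param n_epic CpGs added from the EPIC overlap step (default 3000).
#' @param n_typeI Type I CpGs added last (default 4000).
#' @param mappability_fraction_threshold uniqueness fraction required
#'   (default 0.8).
#' @param rescue_species_count coverage at which the mapping criterion is
#'   waived (default 40).
#' @param epic_metadata optional data frame: cpg_id, chrom, pos (1-based C
#'   coordinate), type, strand.
#' @param biomarker_list optional probe table, see [merge_biomarkers()].
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(model_species, total_after_topup = 53000L,
                            n_epic = 3000L, n_typeI = 4000L,
                            mappability_fraction_threshold = 0.8,
                            rescue_species_count = 40L,
                            epic_metadata = NULL, biomarker_list = NULL) {
  stopifnot(mappability_fraction_threshold >= 0,
            mappability_fraction_threshold <= 1,
            total_after_topup >= 0, n_epic >= 0, n_typeI >= 0)
  structure(list(model_species = model_species,
                 total_after_topup = as.integer(total_after_topup),
                 n_epic = as.integer(n_epic),
                 n_typeI = as.integer(n_typeI),
                 mappability_fraction_threshold =
                   mappability_fraction_threshold,
                 rescue_species_count = as.integer(rescue_species_count),
                 epic_metadata = epic_metadata,
                 biomarker_list = biomarker_list),
            class = "assembly_config")
}

covered_list <- function(x) strsplit(x, ",", fixed = TRUE)

#' Assemble the array manifest from design candidates
#'
#' Applies the four selection steps to a candidate table from
#' [design_probes()]:
#' step 1 takes every retained Type II probe whose covered species include
#' the model species; step 2 tops up with the remaining sites in
#' descending Type II coverage until `total_after_topup` sites are
#' reached; step 3 adds up to `n_epic` not-yet-selected CpGs listed in the
#' EPIC metadata, using the EPIC probe type and strand with the degenerate
#' bases chosen here, ranked by coverage; step 4 adds the top `n_typeI`
#' remaining sites by Type I coverage. All sorts break ties by genomic
#' coordinate ascending, so re-running on identical input is byte
#' identical. A CpG site is selected at most once.
#'
#' @param candidates candidate data frame from [design_probes()].
#' @param config an [assembly_config()].
#' @return manifest data frame: probe_id, chrom, pos (1-based C
#'   coordinate), type, strand, sequence, degenerate, coverage, covered,
#'   provenance_step, duplicate_suffix.
#' @export
assemble <- function(candidates, config) {
  stopifnot(inherits(config, "assembly_config"))
  cand <- candidates[candidates$valid & candidates$retained, , drop = FALSE]
  t2 <- cand[cand$type == "TypeII", , drop = FALSE]
  t1 <- cand[cand$type == "TypeI", , drop = FALSE]
  key <- function(d) paste(d$chrom, d$site)

  in_model <- vapply(covered_list(t2$covered), function(cs)
    config$model_species %in% cs, logical(1L))
  s1 <- t2[in_model, , drop = FALSE]
  s1 <- s1[order(s1$chrom, s1$site), , drop = FALSE]

  rest2 <- t2[!key(t2) %in% key(s1), , drop = FALSE]
  rest2 <- rest2[order(-rest2$coverage, rest2$chrom, rest2$site), ,
                 drop = FALSE]
  n2 <- config$total_after_topup - nrow(s1)
  if (n2 < 0L) {
    warning("step-1 set already exceeds total_after_topup; no top-up")
    n2 <- 0L
  }
  if (n2 > nrow(rest2)) {
    warning("only ", nrow(rest2), " candidates available for top-up of ",
            n2)
    n2 <- nrow(rest2)
  }
  s2 <- utils::head(rest2, n2)

  selected <- c(key(s1), key(s2))
  s3 <- NULL
  if (config$n_epic > 0L) {
    em <- config$epic_metadata
    if (is.null(em))
      stop("n_epic > 0 requires epic_metadata in the assembly config")
    if (any(is.na(em$strand) | !nzchar(em$strand))) {
      warning("EPIC rows without strand skipped")
      em <- em[!is.na(em$strand) & nzchar(em$strand), , drop = FALSE]
    }
    em$site <- em$pos - 1L                      # metadata is 1-based
    ek <- paste(em$chrom, em$site)
    em <- em[!ek %in% selected, , drop = FALSE]
    # candidate row matching the EPIC probe type and strand
    all_valid <- candidates[candidates$valid, , drop = FALSE]
    mk <- paste(all_valid$chrom, all_valid$site, all_valid$type,
                all_valid$strand)
    want <- paste(em$chrom, em$site, em$type, em$strand)
    hit <- match(want, mk)
    s3 <- all_valid[hit[!is.na(hit)], , drop = FALSE]
    s3 <- s3[order(-s3$coverage, s3$chrom, s3$site), , drop = FALSE]
    s3 <- utils::head(s3, min(config$n_epic, nrow(s3)))
    selected <- c(selected, key(s3))
  }

  rest1 <- t1[!key(t1) %in% selected, , drop = FALSE]
  rest1 <- rest1[order(-rest1$coverage, rest1$chrom, rest1$site), ,
                 drop = FALSE]
  s4 <- utils::head(rest1, min(config$n_typeI, nrow(rest1)))

  steps <- list(S1_model_species = s1, S2_topup = s2, S3_epic = s3,
                S4_typeI = s4)
  rows <- list()
  for (nm in names(steps)) {
    d <- steps[[nm]]
    if (is.null(d) || nrow(d) == 0L) next
    d$provenance_step <- nm
    rows[[length(rows) + 1L]] <- d
  }
  man <- do.call(rbind, rows)
  if (is.null(man))
    man <- cbind(candidates[0L, ], provenance_step = character(0))
  data.frame(probe_id = sprintf("cg%08d", seq_len(nrow(man))),
             chrom = man$chrom, pos = man$site + 1L, type = man$type,
             strand = man$strand, sequence = man$sequence,
             degenerate = man$degenerate, coverage = man$coverage,
             covered = man$covered,
             provenance_step = man$provenance_step,
             duplicate_suffix = "", stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mappability filter over a genome panel
#'
#' A probe is retained when the fraction of targeted panel genomes in
#' which every version of it maps uniquely reaches the threshold, or when
#' its species coverage reaches the rescue count (probes expected to work
#' in very many species keep their utility even if multi-mapping in a few
#' genomes). By default the denominator is the intersection of the panel
#' with the probe's covered species; `denominator = "panel"` uses the
#' whole panel. A probe covering none of the panel genomes is retained
#' vacuously under the default denominator.
#'
#' @param manifest manifest from [assemble()].
#' @param uniqueness logical matrix, probes (rownames = probe_id) by panel
#'   genomes; TRUE when the probe maps uniquely in that genome.
#' @param config an [assembly_config()].
#' @param denominator `"targeted"` (default) or `"panel"`.
#' @return manifest with columns `unique_fraction`, `mappability_pass`
#'   added, filtered to passing rows; the dropped rows are attached as
#'   attribute `"dropped"`.
#' @export
apply_mappability_filter <- function(manifest, uniqueness, config,
                                     denominator = c("targeted", "panel")) {
  denominator <- match.arg(denominator)
  panel <- colnames(uniqueness)
  missing <- setdiff(manifest$probe_id, rownames(uniqueness))
  if (length(missing) > 0L)
    stop("probes absent from uniqueness report: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  frac <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    targeted <- if (denominator == "panel") panel
                else intersect(panel,
                               covered_list(manifest$covered[i])[[1L]])
    frac[i] <- if (length(targeted) == 0L) 1
               else mean(uniqueness[manifest$probe_id[i], targeted])
  }
  pass <- frac >= config$mappability_fraction_threshold |
    manifest$coverage >= config$rescue_species_count
  out <- manifest
  out$unique_fraction <- frac
  out$mappability_pass <- pass
  kept <- out[pass, , drop = FALSE]
  attr(kept, "dropped") <- out[!pass, , drop = FALSE]
  kept
}

#' Merge biomarker probes into a manifest
#'
#' Appends externally supplied probes (human biomarker content) with
#' provenance `biomarker`. Rows must carry probe_id, chrom, pos, type,
#' strand and sequence; `ch`-prefixed probes (cytosines not followed by
#' guanine) and `rs` SNP probes are accepted without CpG validation. When
#' a biomarker targets a cytosine already on the manifest, both rows are
#' kept and suffixed `.1` (design) and `.2` (biomarker).
#'
#' @param manifest manifest data frame.
#' @param biomarker_list data frame of biomarker probes.
#' @return combined manifest.
#' @export
merge_biomarkers <- function(manifest, biomarker_list) {
  if (is.null(biomarker_list) || nrow(biomarker_list) == 0L)
    return(manifest)
  need <- c("probe_id", "chrom", "pos", "type", "strand", "sequence")
  for (i in seq_len(nrow(biomarker_list))) {
    vals <- biomarker_list[i, intersect(need, names(biomarker_list))]
    if (length(vals) < length(need) ||
        any(is.na(unlist(vals))) || any(!nzchar(as.character(unlist(vals)))))
      stop("malformed biomarker row ", i)
  }
  bm <- data.frame(probe_id = biomarker_list$probe_id,
                   chrom = biomarker_list$chrom,
                   pos = biomarker_list$pos,
                   type = biomarker_list$type,
                   strand = biomarker_list$strand,
                   sequence = biomarker_list$sequence,
                   degenerate = "", coverage = NA_integer_, covered = "",
                   provenance_step = "biomarker", duplicate_suffix = "",
                   stringsAsFactors = FALSE)
  for (extra in setdiff(names(manifest), names(bm))) bm[[extra]] <- NA
  bm <- bm[, names(manifest)]
  out <- rbind(manifest, bm)
  dup_key <- paste(out$chrom, out$pos)
  for (k in unique(dup_key[duplicated(dup_key)])) {
    idx <- which(dup_key == k)
    # design probes first, then biomarkers; suffix in order
    idx <- idx[order(out$provenance_step[idx] == "biomarker")]
    out$duplicate_suffix[idx] <- paste0(".", seq_along(idx))
    out$probe_id[idx] <- paste0(sub("\\.\\d+$", "", out$probe_id[idx]),
                                out$duplicate_suffix[idx])
  }
  rownames(out) <- NULL
  out
}

#' Write a manifest and its BED companion
#'
#' @param manifest manifest data frame.
#' @param csv_path CSV output path.
#' @param bed_path optional BED path of targeted cytosines (0-based
#'   half-open, 2 bp).
#' @export
write_manifest <- function(manifest, csv_path, bed_path = NULL) {
  utils::write.csv(manifest, csv_path, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = manifest$chrom, start = manifest$pos - 1L,
                      end = manifest$pos + 1L, name = manifest$probe_id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(csv_path)
}
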