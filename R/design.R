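#' Mismatch profile of a site alignment
#'
#' For each species in the window, counts its mismatches against the
#' reference probe sequence and decides feasibility: a species is feasible
#' for the probe when it has the target CpG, no gap or unaligned column and
#' no insertion inside the window, and at most `M` mismatches (each of
#' which could be absorbed by a degenerate base). The degenerate position
#' of every mismatch of every feasible species is accumulated into a
#' multiset `P`, and alternate-allele counts over feasible species are
#' tabulated per position.
#'
#' @param sa a `site_alignment`.
#' @param M maximum number of degenerate bases available for this probe.
#' @param mode `"strict"` compares bases in genomic space;
#'   `"bisulfite"` collapses non-CpG C/T (forward designs) or G/A
#'   (reverse designs) before comparison, emulating the converted read-out.
#' @return an object of class `mismatch_profile` with elements `species`
#'   (data frame: species, structural_ok, M_s, feasible), `mismatches`
#'   (per feasible species, data frame offset/base; offsets are 0-based
#'   within the probe window), `P` (integer multiset of offsets),
#'   `alt_counts` (offset, base, count over feasible species), `M`,
#'   `reference`.
#' @export
build_mismatch_profile <- function(sa, M, mode = c("strict", "bisulfite")) {
  mode <- match.arg(mode)
  ref_chars <- sa$ref_cols[sa$probe_cols]
  if (mode == "bisulfite")
    ref_cmp <- strsplit(bisulfite_convert(paste(ref_chars, collapse = ""),
                                          sa$option$strand), "",
                        fixed = TRUE)[[1L]]
  else ref_cmp <- ref_chars
  species <- rownames(sa$species_mat)
  st_ok <- logical(length(species))
  m_s <- integer(length(species))
  mism <- vector("list", length(species))
  names(mism) <- species
  for (i in seq_along(species)) {
    sp <- species[i]
    row <- sa$species_mat[sp, sa$probe_cols]
    st_ok[i] <- !any(row %in% c("-", ".")) && !sa$insertion[[sp]] &&
      isTRUE(sa$cpg_conserved[[sp]])
    if (!st_ok[i]) { m_s[i] <- NA_integer_; next }
    cmp <- row
    if (mode == "bisulfite")
      cmp <- strsplit(bisulfite_convert(paste(row, collapse = ""),
                                        sa$option$strand), "",
                      fixed = TRUE)[[1L]]
    diff <- which(cmp != ref_cmp)
    m_s[i] <- length(diff)
    mism[[sp]] <- data.frame(offset = diff - 1L, base = row[diff],
                             stringsAsFactors = FALSE)
  }
  feasible <- st_ok & !is.na(m_s) & m_s <= M
  fm <- mism[species[feasible]]
  P <- sort(unlist(lapply(fm, function(d) d$offset), use.names = FALSE))
  if (is.null(P)) P <- integer(0)
  ac <- do.call(rbind, fm)
  if (is.null(ac) || nrow(ac) == 0L) {
    alt_counts <- data.frame(offset = integer(0), base = character(0),
                             count = integer(0))
  } else {
    alt_counts <- stats::aggregate(list(count = rep(1L, nrow(ac))),
                                   by = list(offset = ac$offset,
                                             base = ac$base), FUN = sum)
    alt_counts <- alt_counts[order(alt_counts$offset, alt_counts$base), ]
    rownames(alt_counts) <- NULL
  }
  structure(list(
    species = data.frame(species = species, structural_ok = st_ok,
                         M_s = m_s, feasible = feasible,
                         stringsAsFactors = FALSE),
    mismatches = fm, P = P, alt_counts = alt_counts, M = M,
    reference = sa$reference), class = "mismatch_profile")
}

# sub-multiset compositions of P of size m, offsets ascending; yields
# count vectors in an order equivalent to lexicographic order of the
# sorted offset vectors (largest count on the smallest offset first)
enumerate_compositions <- function(mult, m) {
  n <- length(mult)
  out <- list()
  rec <- function(i, left, acc) {
    if (i > n) {
      if (left == 0L) out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    rest <- if (i < n) sum(mult[(i + 1L):n]) else 0L
    hi <- min(mult[i], left)
    lo <- max(0L, left - rest)
    if (hi < lo) return(invisible())
    for (c in seq.int(hi, lo)) rec(i + 1L, left - c, c(acc, c))
  }
  rec(1L, m, integer(0))
  out
}

#' Select degenerate bases maximizing species coverage
#'
#' The greedy search over the mismatch-position multiset `P`: every
#' distinct sub-multiset of size `min(M, |P|)` is considered; within a
#' sub-multiset, a position occurring `k` times receives the `k` alternate
#' alleles carried by the most feasible species at that position (ties
#' broken alphabetically; `k` larger than the number of distinct alternates
#' selects all of them). The sub-multiset whose chosen substitutions cover
#' the most feasible species wins; remaining ties go to the
#' lexicographically smallest position vector. The reference species always
#' counts as covered.
#'
#' @param profile a `mismatch_profile`.
#' @param M degenerate-base budget (defaults to the profile's).
#' @return list with `degenerate` (data frame offset/alternate, sorted),
#'   `covered` (character vector of species, reference included),
#'   `coverage` (its length).
#' @export
select_degenerate_bases <- function(profile, M = profile$M) {
  F_sp <- profile$species$species[profile$species$feasible]
  base_cover <- union(F_sp[vapply(profile$mismatches[F_sp], function(d)
    is.null(d) || nrow(d) == 0L, logical(1L))], profile$reference)
  empty <- list(degenerate = data.frame(offset = integer(0),
                                        alternate = character(0),
                                        stringsAsFactors = FALSE),
                covered = sort(base_cover),
                coverage = length(base_cover))
  if (length(profile$P) == 0L || M <= 0L) return(empty)
  offs <- sort(unique(profile$P))
  mult <- vapply(offs, function(o) sum(profile$P == o), integer(1L))
  m <- min(M, length(profile$P))
  best <- NULL
  for (cnt in enumerate_compositions(mult, m)) {
    chosen <- data.frame(offset = integer(0), alternate = character(0),
                         stringsAsFactors = FALSE)
    for (j in which(cnt > 0L)) {
      cand <- profile$alt_counts[profile$alt_counts$offset == offs[j], ]
      cand <- cand[order(-cand$count, cand$base), ]
      take <- utils::head(cand, cnt[j])
      chosen <- rbind(chosen, data.frame(offset = take$offset,
                                         alternate = take$base,
                                         stringsAsFactors = FALSE))
    }
    covered <- covered_by(profile, chosen)
    if (is.null(best) || length(covered) > best$coverage) {
      best <- list(degenerate = chosen[order(chosen$offset,
                                             chosen$alternate), ],
                   covered = sort(covered), coverage = length(covered))
      rownames(best$degenerate) <- NULL
    }
  }
  if (best$coverage < empty$coverage) empty else best
}

# species covered by a set of (offset, alternate) substitutions: feasible
# species whose every mismatch is among the chosen pairs, plus reference
covered_by <- function(profile, chosen) {
  F_sp <- profile$species$species[profile$species$feasible]
  key <- paste(chosen$offset, chosen$alternate)
  ok <- vapply(F_sp, function(sp) {
    d <- profile$mismatches[[sp]]
    if (is.null(d) || nrow(d) == 0L) return(TRUE)
    all(paste(d$offset, d$base) %in% key)
  }, logical(1L))
  union(F_sp[ok], profile$reference)
}

#' Exhaustive search over degenerate substitution sets
#'
#' Reference optimizer for small instances: enumerates every set of at
#' most `M` (position, alternate) substitutions drawn from the mismatches
#' of feasible species and returns the best achievable coverage. Serves as
#' an independent optimum against which the greedy selection is compared.
#'
#' @param profile a `mismatch_profile`.
#' @param M substitution budget.
#' @return list with `coverage`, `covered`, `degenerate` for one optimum.
#' @export
exhaustive_degenerate_search <- function(profile, M = profile$M) {
  pairs <- profile$alt_counts[, c("offset", "base")]
  best <- list(degenerate = data.frame(offset = integer(0),
                                       alternate = character(0)),
               covered = sort(covered_by(
                 profile, data.frame(offset = integer(0),
                                     alternate = character(0)))))
  best$coverage <- length(best$covered)
  n <- nrow(pairs)
  if (n > 0L && M > 0L) {
    for (k in seq_len(min(M, n))) {
      idx <- utils::combn(n, k)
      for (j in seq_len(ncol(idx))) {
        chosen <- data.frame(offset = pairs$offset[idx[, j]],
                             alternate = pairs$base[idx[, j]],
                             stringsAsFactors = FALSE)
        covered <- covered_by(profile, chosen)
        if (length(covered) > best$coverage)
          best <- list(degenerate = chosen, covered = sort(covered),
                       coverage = length(covered))
      }
    }
  }
  best
}

#' Replay a degenerate design against the raw alignment
#'
#' Independent soundness check: a species matches the probe when its
#' window row, compared column by column against the reference, differs
#' only at chosen degenerate offsets with a base among the allowed
#' alternates, has the target CpG, and has no gap, unaligned column or
#' insertion. Works directly on the site alignment matrix, bypassing the
#' mismatch-profile machinery.
#'
#' @param sa a `site_alignment`.
#' @param degenerate data frame offset/alternate (0-based probe-window
#'   offsets).
#' @return named logical vector over species (reference included, TRUE).
#' @export
replay_probe_match <- function(sa, degenerate) {
  ref_chars <- sa$ref_cols[sa$probe_cols]
  species <- rownames(sa$species_mat)
  allowed <- split(degenerate$alternate, degenerate$offset)
  res <- stats::setNames(logical(length(species)), species)
  for (sp in species) {
    if (sp == sa$reference) { res[sp] <- TRUE; next }
    row <- sa$species_mat[sp, sa$probe_cols]
    if (any(row %in% c("-", ".")) || sa$insertion[[sp]] ||
        !isTRUE(sa$cpg_conserved[[sp]])) next
    ok <- TRUE
    for (j in seq_along(row)) {
      if (row[j] == ref_chars[j]) next
      alts <- allowed[[as.character(j - 1L)]]
      if (is.null(alts) || !(row[j] %in% alts)) { ok <- FALSE; break }
    }
    res[sp] <- ok
  }
  res
}

#' Design probes for one CpG site under all four options
#'
#' Evaluates Type I / Type II on both strands, running the degenerate-base
#' selection for each in-bounds window, and marks per probe type the
#' strand with the greater species coverage as retained (ties go to the
#' forward strand).
#'
#' @param blocks alignment blocks from [read_maf()].
#' @param genome a [ref_genome()].
#' @param chrom chromosome name.
#' @param site 0-based C position of the CpG.
#' @param probe_length probe length (default 50).
#' @param design_cap degenerate cap or function, see
#'   [max_degenerate_budget()].
#' @param mode comparison space, see [build_mismatch_profile()].
#' @param species optional species universe.
#' @return data frame with one row per evaluated option: chrom, site,
#'   type, strand, M, degenerate (encoded `"offset:alt;..."`), coverage,
#'   covered (comma-separated), sequence (IUPAC, probe orientation),
#'   valid, reason, retained.
#' @export
best_design_for_site <- function(blocks, genome, chrom, site,
                                 probe_length = 50L, design_cap = 3L,
                                 mode = "strict", species = NULL) {
  opts <- design_options()
  rows <- vector("list", nrow(opts))
  for (i in seq_len(nrow(opts))) {
    opt <- opts[i, ]
    sa <- extract_site_alignment(blocks, genome, chrom, site, opt,
                                 probe_length, species)
    if (!inherits(sa, "site_alignment")) {
      rows[[i]] <- data.frame(
        chrom = chrom, site = site, type = opt$type, strand = opt$strand,
        M = NA_integer_, degenerate = "", coverage = NA_integer_,
        covered = "", sequence = "", valid = FALSE,
        reason = if (inherits(sa, "site_skip")) sa$reason else "invalid",
        stringsAsFactors = FALSE)
      next
    }
    win_seq <- paste(sa$ref_cols[sa$probe_cols], collapse = "")
    M <- max_degenerate_budget(opt$type, win_seq, design_cap)
    prof <- build_mismatch_profile(sa, M, mode)
    sel <- select_degenerate_bases(prof, M)
    rows[[i]] <- data.frame(
      chrom = chrom, site = site, type = opt$type, strand = opt$strand,
      M = M, degenerate = encode_degenerate(sel$degenerate),
      coverage = sel$coverage,
      covered = paste(sel$covered, collapse = ","),
      sequence = probe_sequence(genome, chrom, site, opt$type, opt$strand,
                                sel$degenerate, probe_length),
      valid = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$retained <- FALSE
  for (ty in c("TypeI", "TypeII")) {
    sub <- out[out$type == ty & out$valid, , drop = FALSE]
    if (nrow(sub) == 0L) next
    best_cov <- max(sub$coverage)
    winners <- sub[sub$coverage == best_cov, , drop = FALSE]
    pick <- if (any(winners$strand == "forward")) "forward"
            else winners$strand[1L]
    out$retained[out$type == ty & out$valid & out$strand == pick &
                 out$coverage == best_cov] <- TRUE
    # if both strands tie only one row may be retained
    ri <- which(out$retained & out$type == ty)
    if (length(ri) > 1L) out$retained[ri[-1L]] <- FALSE
  }
  out
}

#' Design probes for many CpG sites
#'
#' Driver applying [best_design_for_site()] across a chromosome (or a
#' supplied site list), skipping sites invalid for every option.
#'
#' @inheritParams best_design_for_site
#' @param sites 0-based C positions; defaults to every CpG on `chrom`.
#' @param verbose log per-site progress counts.
#' @return candidate data frame (rows from [best_design_for_site()]).
#' @export
design_probes <- function(blocks, genome, chrom, sites = NULL,
                          probe_length = 50L, design_cap = 3L,
                          mode = "strict", species = NULL,
                          verbose = FALSE) {
  if (is.null(sites)) sites <- enumerate_cpg_sites(genome, chrom)
  if (is.null(species)) {
    species <- sort(unique(unlist(lapply(blocks, function(b)
      b$rows$species))))
  }
  out <- lapply(sites, function(s)
    best_design_for_site(blocks, genome, chrom, s, probe_length,
                         design_cap, mode, species))
  res <- do.call(rbind, out)
  if (verbose)
    message(length(sites), " sites evaluated, ",
            sum(res$retained), " candidate probes retained")
  res
}

#' Encode / decode a degenerate-base set
#'
#' Degenerate sets travel in tables as `"offset:alternate;..."` strings
#' (0-based probe-window offsets).
#'
#' @param degenerate data frame offset/alternate.
#' @return `encode_degenerate`: a single string;
#'   `decode_degenerate`: a data frame.
#' @export
encode_degenerate <- function(degenerate) {
  if (is.null(degenerate) || nrow(degenerate) == 0L) return("")
  paste(paste0(degenerate$offset, ":", degenerate$alternate),
        collapse = ";")
}

#' @rdname encode_degenerate
#' @param s encoded string.
#' @export
decode_degenerate <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(offset = integer(0), alternate = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":",
                    fixed = TRUE)
  data.frame(offset = as.integer(vapply(parts, `[`, "", 1L)),
             alternate = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
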