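# the five-species worked example: A matches exactly, B and C share one
# mismatch (offset 2 -> T), D mismatches at offset 4, E lacks the CpG
five_species_sa <- function() {
  ref <- "ACGAACGAGT"
  sub_at <- function(s, i, b) { substr(s, i, i) <- b; s }
  make_site_alignment(ref, list(
    A = list(window = ref),
    B = list(window = sub_at(ref, 3, "T")),
    C = list(window = sub_at(ref, 3, "T")),
    D = list(window = sub_at(ref, 5, "C")),
    E = list(window = ref, no_cpg = TRUE)))
}

test_that("mismatch profile classifies the worked five-species example", {
  sa <- five_species_sa()
  prof <- build_mismatch_profile(sa, 3L)
  sp <- prof$species
  expect_true(all(sp$feasible[sp$species %in% c("ref", "A", "B", "C", "D")]))
  expect_false(sp$feasible[sp$species == "E"])
  expect_equal(sp$M_s[sp$species == "B"], 1L)
  expect_equal(sort(prof$P), c(2L, 2L, 4L))
  expect_equal(prof$mismatches[["D"]]$offset, 4L)
})

test_that("all-identical alignments give full coverage and empty P", {
  ref <- "TTACGGATCA"
  sa <- make_site_alignment(ref, list(a = list(window = ref),
                                      b = list(window = ref)))
  prof <- build_mismatch_profile(sa, 3L)
  expect_length(prof$P, 0L)
  sel <- select_degenerate_bases(prof, 3L)
  expect_equal(sel$coverage, 3L)
  expect_equal(nrow(sel$degenerate), 0L)
})

test_that("a gap column makes a species infeasible regardless of budget", {
  ref <- "TTACGGATCA"
  gapped <- "TTACG-ATCA"
  sa <- make_site_alignment(ref, list(a = list(window = gapped)))
  prof <- build_mismatch_profile(sa, 10L)
  expect_false(prof$species$feasible[prof$species$species == "a"])
  # oracle: no substitution-only set can cover a gapped species
  ex <- exhaustive_degenerate_search(prof, 10L)
  expect_false("a" %in% ex$covered)
})

test_that("selection on the worked example matches the brute-force optimum", {
  sa <- five_species_sa()
  prof <- build_mismatch_profile(sa, 3L)
  sel1 <- select_degenerate_bases(prof, 1L)
  expect_equal(sel1$degenerate,
               data.frame(offset = 2L, alternate = "T"))
  expect_setequal(sel1$covered, c("ref", "A", "B", "C"))
  expect_equal(sel1$coverage,
               exhaustive_degenerate_search(prof, 1L)$coverage)

  sel2 <- select_degenerate_bases(prof, 2L)
  expect_equal(sel2$coverage, 5L)   # ref, A, B, C, D; E stays uncovered
  expect_setequal(sel2$covered, c("ref", "A", "B", "C", "D"))
  expect_equal(sel2$degenerate$offset, c(2L, 4L))
  expect_equal(sel2$coverage,
               exhaustive_degenerate_search(prof, 2L)$coverage)
})

test_that("alternate alleles at one position are ranked by feasible-species count", {
  ref <- "ACGAACGAGT"
  sub_at <- function(s, i, b) { substr(s, i, i) <- b; s }
  # offset 7: two species carry C, one carries T
  sa <- make_site_alignment(ref, list(
    a = list(window = sub_at(ref, 8, "C")),
    b = list(window = sub_at(ref, 8, "C")),
    c = list(window = sub_at(ref, 8, "T"))))
  prof <- build_mismatch_profile(sa, 1L)
  sel <- select_degenerate_bases(prof, 1L)
  expect_equal(sel$degenerate, data.frame(offset = 7L, alternate = "C"))
  expect_setequal(sel$covered, c("ref", "a", "b"))
  # with budget 2 both alternates at the shared position are taken
  prof2 <- build_mismatch_profile(sa, 2L)
  sel2 <- select_degenerate_bases(prof2, 2L)
  expect_equal(sel2$coverage, 4L)
})

test_that("greedy coverage never exceeds and usually equals the exhaustive optimum", {
  n_eq <- 0L
  for (i in 1:60) {
    sa <- simulate_site_alignment(n_species = sample(3:8, 1),
                                  probe_length = 10L, p_mismatch = 0.08,
                                  p_gap = 0.02, p_unaligned = 0.05,
                                  p_cpg_loss = 0.08, seed = 5000 + i)
    M <- sample(0:2, 1)
    prof <- build_mismatch_profile(sa, M)
    sel <- select_degenerate_bases(prof, M)
    ex <- exhaustive_degenerate_search(prof, M)
    expect_lte(sel$coverage, ex$coverage)
    if (sel$coverage == ex$coverage) n_eq <- n_eq + 1L
    # soundness: replay every covered species against the raw alignment
    rep <- replay_probe_match(sa, sel$degenerate)
    expect_true(all(rep[sel$covered]))
    # when every position has a single alternate, greedy is exact
    single_alt <- all(table(prof$alt_counts$offset) == 1L)
    if (single_alt) expect_equal(sel$coverage, ex$coverage)
  }
  expect_gte(n_eq / 60, 0.9)
})

test_that("coverage is non-decreasing in the degenerate budget", {
  for (i in 1:25) {
    sa <- simulate_site_alignment(n_species = 6L, probe_length = 10L,
                                  p_mismatch = 0.1, seed = 7000 + i)
    covs <- vapply(0:3, function(m)
      select_degenerate_bases(build_mismatch_profile(sa, m), m)$coverage,
      integer(1L))
    expect_true(all(diff(covs) >= 0L))
  }
})

test_that("identical inputs give identical degenerate sets", {
  for (i in 1:10) {
    sa <- simulate_site_alignment(n_species = 7L, probe_length = 10L,
                                  p_mismatch = 0.1, seed = 9000 + i)
    prof <- build_mismatch_profile(sa, 2L)
    expect_identical(select_degenerate_bases(prof, 2L),
                     select_degenerate_bases(prof, 2L))
  }
})

test_that("per-type retention keeps the strand with more species, forward on ties", {
  set.seed(31)
  # genome whose CpG has a mismatch cluster only in the forward window
  chars <- sample(c("A", "C", "G", "T"), 220, replace = TRUE)
  chars[111] <- "C"; chars[112] <- "G"
  ref <- paste(chars, collapse = "")
  g <- ref_genome(c(c1 = ref))
  sp_chars <- chars
  for (k in c(70, 80, 90, 100)) # 4 mismatches 5' of the CpG
    sp_chars[k] <- setdiff(c("A", "C", "G", "T"), sp_chars[k])[1]
  rows <- data.frame(species = c("ref", "sp"), chrom = "c1", start = 0L,
                     size = 220L, strand = "+", src_size = 220L,
                     text = c(ref, paste(sp_chars, collapse = "")),
                     stringsAsFactors = FALSE)
  blocks <- list(structure(list(ref_chrom = "c1", ref_start = 0L,
                                ref_size = 220L, rows = rows),
                           class = "alignment_block"))
  res <- best_design_for_site(blocks, g, "c1", 110L)
  t2 <- res[res$type == "TypeII", ]
  # forward window has 4 mismatches (> M = 3) -> sp infeasible there;
  # reverse window is clean -> reverse retained with higher coverage
  expect_equal(t2$strand[t2$retained], "reverse")
  expect_gt(t2$coverage[t2$retained],
            t2$coverage[t2$strand == "forward"])

  # palindromic tie: identical species -> both strands tie, forward kept
  rows2 <- rows
  rows2$text[2] <- ref
  blocks2 <- list(structure(list(ref_chrom = "c1", ref_start = 0L,
                                 ref_size = 220L, rows = rows2),
                            class = "alignment_block"))
  res2 <- best_design_for_site(blocks2, g, "c1", 110L)
  for (ty in c("TypeI", "TypeII")) {
    kept <- res2[res2$type == ty & res2$retained, ]
    expect_equal(nrow(kept), 1L)
    expect_equal(kept$strand, "forward")
  }
})

test_that("degenerate set encoding round-trips", {
  d <- data.frame(offset = c(2L, 9L), alternate = c("T", "A"))
  expect_equal(decode_degenerate(encode_degenerate(d)), d)
  expect_equal(nrow(decode_degenerate("")), 0L)
})
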