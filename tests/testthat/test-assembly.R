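# toy candidate table: 20 sites with hand-assigned coverages.
# Type II coverage: odd site index i -> 10+i, even -> 5; mm10 covered only
# at sites 1..3. Type I coverage: 30 - i.
toy_candidates <- function() {
  rows <- list()
  for (i in 1:20) {
    site <- 100L * i
    cov2 <- if (i %% 2 == 1) 10L + i else 5L
    covered2 <- if (i <= 3) "hg19,mm10,rn5" else "hg19,rn5"
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", site = site, type = "TypeII", strand = "forward",
      M = 3L, degenerate = "", coverage = cov2, covered = covered2,
      sequence = strrep("A", 50), valid = TRUE, reason = "",
      retained = TRUE, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = "chr1", site = site, type = "TypeI", strand = "forward",
      M = 3L, degenerate = "", coverage = 30L - i, covered = "hg19",
      sequence = strrep("C", 50), valid = TRUE, reason = "",
      retained = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

toy_config <- function() {
  epic <- data.frame(cpg_id = c("e1", "e2", "e3"), chrom = "chr1",
                     pos = c(101L, 401L, 601L),    # sites 100, 400, 600
                     type = "TypeII", strand = "forward",
                     stringsAsFactors = FALSE)
  assembly_config(model_species = "mm10", total_after_topup = 10L,
                  n_epic = 2L, n_typeI = 2L, epic_metadata = epic)
}

test_that("assembly reproduces the hand-enumerated manifest", {
  man <- assemble(toy_candidates(), toy_config())
  # hand enumeration: S1 = sites 1..3 (mm10, coordinate order);
  # S2 = sites 19,17,15,13,11,9,7 by descending Type II coverage;
  # S3 = EPIC sites 4 and 6 (site 1 already selected), tie -> coordinate;
  # S4 = Type I for sites 5 and 8 (highest Type I coverage remaining)
  expect_equal(man$pos - 1L,
               100L * c(1, 2, 3, 19, 17, 15, 13, 11, 9, 7, 4, 6, 5, 8))
  expect_equal(man$provenance_step,
               c(rep("S1_model_species", 3), rep("S2_topup", 7),
                 rep("S3_epic", 2), rep("S4_typeI", 2)))
  expect_equal(man$type, c(rep("TypeII", 12), rep("TypeI", 2)))
  expect_equal(sum(man$provenance_step %in%
                     c("S1_model_species", "S2_topup")), 10L)
  expect_false(any(duplicated(paste(man$chrom, man$pos))))
  expect_equal(man$probe_id, sprintf("cg%08d", 1:14))
})

test_that("assembly is deterministic and handles an empty model-species set", {
  m1 <- assemble(toy_candidates(), toy_config())
  m2 <- assemble(toy_candidates(), toy_config())
  expect_identical(m1, m2)

  cfg <- toy_config()
  cfg$model_species <- "nosuch"
  man <- assemble(toy_candidates(), cfg)
  expect_false(any(man$provenance_step == "S1_model_species"))
  expect_equal(sum(man$provenance_step == "S2_topup"), 10L)
})

test_that("an EPIC-listed site already selected keeps its original provenance", {
  man <- assemble(toy_candidates(), toy_config())
  expect_equal(man$provenance_step[man$pos == 101L], "S1_model_species")
  expect_equal(sum(man$pos == 101L), 1L)
})

test_that("requesting EPIC probes without metadata errors", {
  cfg <- toy_config()
  cfg$epic_metadata <- NULL
  expect_error(assemble(toy_candidates(), cfg), "epic_metadata")
})

test_that("mappability filter applies the 80% / rescue-count rule on constructed cases", {
  panel <- sprintf("g%02d", 1:16)
  # 20 cases: number of unique panel genomes and species coverage chosen
  # to probe the thresholds from both sides
  n_unique <- c(16, 13, 12, 7, 0, 16, 13, 12, 8, 15,
                14, 11, 10, 9, 13, 12, 6, 5, 16, 12)
  coverage <- c(50, 20, 20, 45, 41, 16, 16, 39, 40, 16,
                16, 40, 16, 16, 41, 16, 16, 40, 39, 38)
  man <- data.frame(probe_id = sprintf("p%02d", 1:20), chrom = "chr1",
                    pos = 1:20 * 10L, type = "TypeII", strand = "forward",
                    sequence = strrep("A", 50), degenerate = "",
                    coverage = coverage,
                    covered = paste(panel, collapse = ","),
                    provenance_step = "S1_model_species",
                    duplicate_suffix = "", stringsAsFactors = FALSE)
  uniq <- matrix(FALSE, 20, 16, dimnames = list(man$probe_id, panel))
  for (i in 1:20) if (n_unique[i] > 0) uniq[i, seq_len(n_unique[i])] <- TRUE
  cfg <- assembly_config("mm10")
  got <- apply_mappability_filter(man, uniq, cfg)
  expected <- (n_unique / 16 >= 0.8) | (coverage >= 40)
  expect_setequal(got$probe_id, man$probe_id[expected])
  # the boundary cases spelled out:
  expect_true("p02" %in% got$probe_id)    # 13/16 = 0.8125 -> retained
  expect_false("p03" %in% got$probe_id)   # 12/16 = 0.75, coverage 20
  expect_true("p04" %in% got$probe_id)    # 7/16 but coverage 45 -> rescue
})

test_that("raising the threshold never retains a previously dropped probe", {
  panel <- sprintf("g%02d", 1:10)
  set.seed(17)
  man <- data.frame(probe_id = sprintf("p%02d", 1:30), chrom = "c",
                    pos = 1:30, type = "TypeII", strand = "forward",
                    sequence = strrep("A", 50), degenerate = "",
                    coverage = sample(5:45, 30, replace = TRUE),
                    covered = paste(panel, collapse = ","),
                    provenance_step = "S2_topup", duplicate_suffix = "",
                    stringsAsFactors = FALSE)
  uniq <- matrix(runif(300) < 0.8, 30, 10,
                 dimnames = list(man$probe_id, panel))
  prev <- NULL
  for (thr in c(0.2, 0.5, 0.8, 0.95)) {
    cfg <- assembly_config("mm10", mappability_fraction_threshold = thr)
    kept <- apply_mappability_filter(man, uniq, cfg)$probe_id
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("filter errors on probes absent from the uniqueness report", {
  man <- assemble(toy_candidates(), toy_config())
  uniq <- matrix(TRUE, 2, 2, dimnames = list(man$probe_id[1:2],
                                             c("g1", "g2")))
  expect_error(apply_mappability_filter(man, uniq, toy_config()),
               "absent from uniqueness")
})

test_that("the targeted-panel denominator ignores genomes the probe does not cover", {
  man <- assemble(toy_candidates(), toy_config())[1, , drop = FALSE]
  man$covered <- "hg19,g1"
  man$coverage <- 2L
  uniq <- matrix(c(TRUE, FALSE, FALSE), 1, 3,
                 dimnames = list(man$probe_id, c("g1", "g2", "g3")))
  cfg <- toy_config()
  expect_equal(nrow(apply_mappability_filter(man, uniq, cfg)), 1L)
  expect_equal(nrow(apply_mappability_filter(man, uniq, cfg,
                                             denominator = "panel")), 0L)
})

test_that("biomarker merge appends, suffixes collisions, accepts ch probes", {
  man <- assemble(toy_candidates(), toy_config())
  expect_identical(merge_biomarkers(man, NULL), man)

  bm <- data.frame(probe_id = c("cg99999999", "ch00000001"),
                   chrom = "chr1", pos = c(101L, 5001L),
                   type = "TypeII", strand = "forward",
                   sequence = strrep("G", 50), stringsAsFactors = FALSE)
  out <- merge_biomarkers(man, bm)
  expect_equal(nrow(out), nrow(man) + 2L)
  dup <- out[out$pos == 101L, ]
  expect_equal(nrow(dup), 2L)
  expect_equal(sort(dup$duplicate_suffix), c(".1", ".2"))
  expect_equal(dup$duplicate_suffix[dup$provenance_step == "biomarker"],
               ".2")
  expect_true(grepl("\\.1$", dup$probe_id[dup$provenance_step !=
                                            "biomarker"]))
  ch <- out[out$probe_id == "ch00000001", ]
  expect_equal(ch$provenance_step, "biomarker")

  bad <- data.frame(probe_id = "x", chrom = "chr1", pos = NA_integer_,
                    type = "TypeII", strand = "forward", sequence = "A")
  expect_error(merge_biomarkers(man, bad), "malformed biomarker row 1")
})
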