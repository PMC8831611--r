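write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t20001\t30000\t.\t+\t.\tID=geneA",
    "chr1\ttoy\texon\t20001\t20500\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\texon\t25001\t25500\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\tfive_prime_UTR\t20001\t20100\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\tthree_prime_UTR\t25400\t25500\t.\t+\t.\tParent=geneA",
    "chr1\ttoy\tgene\t60001\t70000\t.\t-\t.\tID=geneB",
    "chr1\ttoy\texon\t69001\t70000\t.\t-\t.\tParent=geneB",
    "chr1\ttoy\tgene\t100001\t110000\t.\t+\t.\tID=geneC"), path)
  path
}

test_that("gene regions resolve by the fixed priority with a strand-aware promoter", {
  gm <- read_gene_model(write_toy_gff())
  expect_equal(gm$genes$tss, c(20001L, 70000L, 100001L))
  cpgs <- data.frame(
    probe_id = sprintf("p%d", 1:7),
    chrom = "chr1",
    pos = c(15001L,   # 5 kb upstream of geneA TSS -> promoter
            20050L,   # exon and promoter and 5'UTR -> exon wins
            22000L,   # inside gene body, no exon -> intron
            25450L,   # exon and 3'UTR overlap -> exon wins
            500000L,  # far from everything -> intergenic
            72000L,   # 2 kb upstream of minus-strand geneB -> promoter
            69500L))  # geneB exon
  calls <- assign_gene_region(cpgs, gm)
  expect_equal(calls$category,
               c("promoter", "exon", "intron", "exon", "intergenic",
                 "promoter", "exon"))
  expect_equal(calls$nearest_gene[1], "geneA")
  expect_equal(calls$dist_tss[1], 15001L - 20001L)
  # minus-strand distances are signed in gene orientation
  expect_equal(calls$nearest_gene[6], "geneB")
  expect_equal(calls$dist_tss[6], -(72000L - 70000L))
})

test_that("promoter window spans -10 kb to +100 bp of the TSS in gene orientation", {
  gm <- read_gene_model(write_toy_gff())
  probe <- function(pos) assign_gene_region(
    data.frame(chrom = "chr1", pos = pos), gm)$category
  expect_equal(probe(20001L - 10000L), "promoter")     # upstream edge
  expect_equal(probe(20001L - 10001L), "intergenic")   # just beyond
  # geneC has no exons: its body is intron except where the promoter
  # window (TSS-10000 .. TSS+100) outranks it
  expect_equal(probe(100101L), "promoter")             # TSS+100, inclusive
  expect_equal(probe(100102L), "intron")               # one base further
  # minus-strand geneB: upstream means higher coordinates
  expect_equal(probe(80000L), "promoter")              # TSS+10000 on "-"
  expect_equal(probe(80001L), "intergenic")
})

test_that("empty gene model marks everything intergenic", {
  p <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p)
  gm <- read_gene_model(p)
  calls <- assign_gene_region(data.frame(chrom = "chr1",
                                         pos = c(10L, 20L)), gm)
  expect_equal(calls$category, c("intergenic", "intergenic"))
})

test_that("interval overlap uses half-open BED semantics on the C base", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  cpgs <- data.frame(chrom = "chr1", pos = c(101L, 200L, 201L, 50L))
  # pos is 1-based: BED start 100 covers 1-based 101..200
  expect_equal(overlap_annotate(cpgs, bed), c(TRUE, TRUE, FALSE, FALSE))
  # empty interval set
  empty <- GenomicRanges::GRanges()
  expect_equal(overlap_annotate(cpgs, empty), rep(FALSE, 4))
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\toops"), bad)
  expect_error(overlap_annotate(cpgs, bad), "malformed BED line 2")
})

test_that("overlap agrees with a brute-force per-base scan", {
  set.seed(19)
  for (rep in 1:10) {
    n_int <- sample(1:6, 1)
    starts <- sort(sample(0:900, n_int))
    ends <- starts + sample(10:60, n_int, replace = TRUE)
    gr <- GenomicRanges::GRanges("c", IRanges::IRanges(starts + 1, ends))
    pos <- sample(1:1000, 50)
    got <- overlap_annotate(data.frame(chrom = "c", pos = pos), gr)
    want <- vapply(pos, function(p)
      any(p - 1 >= starts & p - 1 < ends), logical(1))
    expect_equal(got, want)
  }
})

test_that("fold enrichment follows (k/n)/(K/N)", {
  expect_equal(enrichment_fold(10, 100, 1000, 10000), 1.0)
  expect_equal(enrichment_fold(30, 100, 1000, 10000), 3.0)
  expect_equal(enrichment_fold(0, 100, 1000, 10000), 0.0)
  expect_warning(f <- enrichment_fold(5, 10, 0, 100), "undefined")
  expect_true(is.nan(f))
})

test_that("uniform random subsets have fold enrichment near 1", {
  set.seed(23)
  N <- 20000L; K <- 4000L
  annotated <- seq_len(N) <= K
  folds <- replicate(20, {
    pick <- sample.int(N, 800)
    enrichment_fold(sum(annotated[pick]), 800, K, N)
  })
  # binomial sampling: sd of k/n is sqrt(p(1-p)/n)/p ~ 0.07 relative
  expect_true(all(abs(folds - 1) < 0.3))
  expect_lt(abs(mean(folds) - 1), 0.05)
})

test_that("ortholog concordance counts matches and intergenic discordance", {
  ref <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    nearest_gene = c("gA", "gA", "gB", "gB"),
                    category = "promoter", stringsAsFactors = FALSE)
  ortho <- data.frame(ref_gene = c("gA", "gB"),
                      species_gene = c("mA", "mB"),
                      stringsAsFactors = FALSE)
  identical_sp <- data.frame(probe_id = ref$probe_id,
                             nearest_gene = c("mA", "mA", "mB", "mB"),
                             category = "promoter",
                             stringsAsFactors = FALSE)
  expect_equal(ortholog_concordance(ref, identical_sp, ortho)$concordance,
               1.0)
  one_off <- identical_sp
  one_off$nearest_gene[2] <- "mB"          # non-ortholog for p2
  expect_equal(ortholog_concordance(ref, one_off, ortho)$concordance,
               0.75)
  all_inter <- identical_sp
  all_inter$nearest_gene <- "mX"
  all_inter$category <- "intergenic"
  res <- ortholog_concordance(ref, all_inter, ortho)
  expect_equal(res$n_concordant, 0L)
  expect_equal(res$n_discordant_intergenic, 4L)
  expect_error(ortholog_concordance(ref, identical_sp, NULL), "required")
})
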