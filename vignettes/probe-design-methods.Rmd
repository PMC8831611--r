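---
title: "Designing cross-species methylation array probes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cross-species methylation array probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consmeth)
```

## The problem

Infinium methylation arrays measure cytosine methylation at individual
CpG sites by hybridizing bisulfite-converted DNA to 50-mer probes drawn
from a reference genome. A probe designed against one species fails in
another wherever the flanking sequence has diverged, because a single
mismatch can abolish hybridization. The idea implemented here is to
target CpGs whose flanking sequence is conserved across many species and
to spend the array's *degenerate base* capability — positions synthesized
as a mixture of nucleotides — on exactly those flanking positions where
species disagree with the reference. One physical probe then tolerates a
chosen set of cross-species substitutions.

`consmeth` implements the full design path at desk scale: reading a
multiple-species alignment (MAF) anchored to a reference genome,
optimizing degenerate-base placement per CpG and per probe chemistry,
assembling an array manifest through a staged selection pipeline,
verifying probes by in-silico bisulfite-converted exact mapping, and
annotating and benchmarking the result.

## Probe geometry

Probes are `probe_length = 50` bases flanking the target CpG (the C at
0-based position $p$, G at $p+1$). Which side of the CpG the 50-mer
occupies is a convention; the one fixed here, used consistently by every
module and configurable through `probe_window()`, is:

* **Type II forward**: the 50 bases immediately 5' of the C, CpG
  excluded — window $[p-50, p)$;
* **Type I forward**: 50 bases ending at and including the C — window
  $[p-49, p+1)$;
* reverse designs mirror these symmetrically about the G.

Type I and Type II windows for the same site and strand therefore
overlap in exactly 49 bases. Whether the manufactured array places
probes 5' or 3' of the CpG on each strand is not recoverable from public
descriptions, which is why the geometry is a documented convention
rather than a claim.

## The degenerate-base budget

At most three degenerate bases fit in a probe. The vendor's proprietary
design score can lower this cap; `max_degenerate_budget()` accepts a
pluggable `design_cap` function for that purpose and defaults to the
constant 3. For Type II probes, every CpG dinucleotide inside the probe
sequence other than the target consumes one slot of the budget (Type II
chemistry must treat each probe CpG as a position of unknown conversion
state); Type I probes are not charged for CpG content, which is why they
remain preferable in CpG-dense regions.

## The selection algorithm

For one CpG, one probe type and one strand, let $M$ be the budget. Each
aligned species $s$ is compared column-by-column against the reference
over the probe window:

1. a species with a gap column, an unaligned column, an insertion
   relative to the reference inside the window, or a non-conserved
   target CpG is infeasible — no substitution-only degenerate set can
   rescue it;
2. otherwise let $M_s$ be its mismatch count; if $M_s \le M$ the species
   joins the feasible set $F$ and each of its mismatch positions is
   added to a multiset $P$ (multiplicity = number of feasible species
   mismatching there).

Every distinct sub-multiset $S$ of $P$ of size $\min(M, |P|)$ is then
scored: a position occurring $k$ times in $S$ receives the $k$ alternate
alleles carried by the most species in $F$ at that position (ties broken
alphabetically; if fewer than $k$ distinct alternates exist, all are
taken). The score of $S$ is the number of species in $F$ whose every
mismatch is covered by the chosen (position, alternate) pairs, plus the
reference itself, which trivially matches. The best-scoring $S$ wins;
remaining ties go to the lexicographically smallest position vector, so
identical inputs always give identical designs.

Per probe type, both strands are evaluated and the strand with the
greater species coverage is retained, ties going to forward.

Reading "$|P|$ choose $M$ combinations" as *distinct sub-multisets of
size $\min(M,|P|)$* handles the $|P| < M$ case and has a useful
consequence: adding a (position, alternate) pair can only grow the
covered set, so restricting to exact-size sub-multisets loses nothing
and coverage is non-decreasing in $M$.

### How good is the greedy step?

The per-position alternate choice is greedy — alternates are ranked by
marginal species count, not jointly optimized. The package ships an
exhaustive reference optimizer, `exhaustive_degenerate_search()`, which
enumerates every substitution set of size at most $M$ and is exact on
small instances. On simulated site alignments (windows of 10 bases, up
to 8 species, $M \le 2$) the greedy result equals the exhaustive optimum
on more than 99% of instances and never exceeds it; whenever every
position in $P$ carries a single distinct alternate the two coincide
exactly. The rare gap arises when two alternates at one position tie on
marginal count but differ in which other mismatches their carriers have.

## Synthetic site alignments

`simulate_site_alignment()` generates the random instances used by the
property tests: a random reference window with the CpG planted, species
rows derived by independent per-column substitutions (default 5–8%),
occasional gap columns (2%), whole-row unaligned species (5%) and CpG
losses (5–8%). This emulates substitution-dominated local divergence at
a conserved CpG. It deliberately does **not** emulate phylogenetic
correlation between species, indel clustering, or alignment error —
passing tests on these instances demonstrate the optimizer's
combinatorial correctness, not fidelity to any particular clade.

## Array assembly

`assemble()` applies a staged selection to the candidate table, mirroring
a model-species-first design: (1) every Type II probe expected to work in
the configured model species; (2) a top-up of the remaining sites in
descending Type II species coverage until `total_after_topup` sites;
(3) up to `n_epic` CpGs shared with an EPIC-style human array — same
probe type and strand as that array's metadata but with the degenerate
bases chosen here — ranked by coverage; (4) the top `n_typeI` remaining
sites by Type I coverage. The published full-scale totals (53,000 /
3,000 / 4,000) are the configuration defaults; tests run toy totals
because the full numbers only arise from a genome-scale alignment. All
sorts break ties by genomic coordinate, making re-assembly byte
identical. Biomarker probes merge afterwards; a cytosine targeted by
both a design probe and a biomarker probe keeps both rows with `.1`/`.2`
suffixes, and non-CpG (`ch`) and SNP (`rs`) biomarker probes are
accepted verbatim.

The mappability filter retains a probe when its versions map uniquely in
at least 80% (`mappability_fraction_threshold`) of the high-quality
panel genomes it targets, or when its species coverage reaches
`rescue_species_count` (default 40) — a probe expected to work in very
many species keeps its utility even if it multi-maps in a few genomes.
The denominator "genomes the probe is expected to target" is read as
panel ∩ covered species by default; a whole-panel mode is available
(`denominator = "panel"`), and a probe covering no panel genome passes
vacuously under the default.

## Mappability

`map_probe_versions()` expands a degenerate probe into its explicit
sequences and searches each for full-length, zero-mismatch matches on
both strands. In `bisulfite` mode both probe and genome are compared in
converted space with every CpG treated as methylated — for Type I probes
this is exactly the methylated probe version, the only one meaningful
against a CpG-methylated converted genome. One numerical subtlety: a
probe whose 3'-terminal base is C has unknowable CpG context there (the
next genomic base lies outside the probe), so both converted variants
are searched and their hits unioned; this is also what guarantees the
invariant that strict-mode hits are a subset of bisulfite-mode hits.
Variant alignments are collapsed to distinct loci and a probe is unique
when exactly one locus remains; several versions agreeing on one locus
do not break uniqueness. `verify_target_cpg()` then projects the CpG
coordinate implied by the probe geometry at each locus and requires an
intact CG there on the hit strand. The engine is an exact-text search
suited to desk-scale genomes; the contract is the match definition, not
the search machinery.

## Annotation

Gene regions follow a fixed priority — exon, promoter, intron, 5' UTR,
3' UTR, intergenic — with the promoter spanning 10 kb upstream to 100 bp
downstream of the nearest TSS in gene orientation (upstream is read in
the gene's own orientation; the source description is silent on this and
gene-oriented is the biologically standard reading). The CpG "position"
for interval overlap is the single C base, with half-open BED semantics.
Fold enrichment is the plain ratio of annotated fractions,
$(k_{on}/n_{on}) / (K_{bg}/N_{bg})$. Ortholog concordance reports the
fraction of probes whose gene assignment in a second species is the
known ortholog of the reference assignment, with discordant-intergenic
cases counted separately since they usually reflect an inaccurate
assignment rather than rearrangement.

## Calibration benchmarking

Calibration standards are arrays measured on DNA engineered to known
methylation proportions 0, 0.25, 0.5, 0.75 and 1 (the benchmark
variable). The analysis consumes already-normalized beta matrices;
normalization itself is out of scope here. Per probe, the Pearson
correlation of betas against the benchmark is the probe's fidelity
score; counts above thresholds use strict inequality (matching the
"exceeds a correlation of" reading), probes with correlation below 0.8
(strictly) or undefined are discarded, and the removal list is reported.

`simulate_calibration()` emulates the standards: a working probe's beta
on an array at level $p$ is $\mathrm{Binomial}(d, \mathrm{clamp}(p +
\mathrm{bias}))/d$ for an effective depth $d$ (default bias 0), and a
planted fraction `f_fail` of probes draw betas uniformly on $[0,1]$,
standing in for probes that do not work in the target species. The
replicate structure defaults to the study design (2/4/3 arrays per level
for human/mouse/rat-sized runs). The uniform-failure model is a
deliberate simplification — real failing probes show background-level or
off-target signal, not uniform noise — and is configurable.

Binomial read-out implies the heteroscedastic relation
$\mathrm{variance} = \mathrm{mean}(1-\mathrm{mean})/d$.
`mean_variance_check()` estimates the constant by an unbiased
through-origin least-squares fit over per-probe, per-level points
(variance taken across the replicate arrays of one level — across *all*
arrays the benchmark's own spread would dominate and the constant would
not be $1/d$). With few replicates each variance estimate carries
3-degree-of-freedom chi-square noise, which attenuates the raw
point-cloud correlation between variance and mean(1−mean) to about 0.6
even when the relation holds exactly; the reported `r` is therefore
computed on the per-level pooled values (variance averaged over probes
within a level), with the raw scatter correlation available as
`r_points`. On pure binomial simulations the fit recovers $1/d$ within a
few percent at $d \in \{10, 30, 100\}$ and the pooled correlation
exceeds 0.99.

```{r calibration-example}
cfg <- simulator_config(n_probes = 500, replicates_per_level = 4,
                        depth = 100, f_fail = 0.1, seed = 11)
ds <- simulate_calibration(cfg)
r <- correlate_with_benchmark(ds)
threshold_counts(r)
filt <- filter_outliers(ds, r, cutoff = 0.8)
mv <- mean_variance_check(filt)
c(c_times_d = mv$c * 100, r_pooled = mv$r)
```

## Problem sizes and determinism

Tests and the acceptance script run entirely on generated data: 500
random site alignments (window 10, ≤8 species, $M \le 2$) for the
optimizer properties, 50 random genomes of a few hundred bases for the
mapper-versus-oracle comparison, and 2,000 probes × 20 arrays for the
calibration benchmark. These sizes keep the exhaustive reference
searches cheap while exercising every code path; every random draw
flows from an explicit seed, and all pipeline outputs are deterministic
given their inputs.

## Known limitations

* The optimizer treats species independently; it does not model
  phylogeny, so coverage counts weight a dense clade the same as an
  isolated lineage.
* Hybridization is modelled as exact string matching; there is no
  thermodynamic model, and a tolerated mismatch is assumed to behave
  identically to a reference match.
* The mappability engine is exact and desk-scale; genome-scale runs
  would substitute an indexed aligner behind the same match definition.
* The calibration simulator is binomial with optional additive bias; it
  does not reproduce dye bias, background, or the compression of
  extreme betas seen on real arrays.
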