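---
title: "Methods and design of polyplex"
author: "polyplex maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of polyplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

polyplex analyses multi-sample SNV data from species complexes that mix
diploids with allopolyploids: hard filtering, ploidy estimation from allele
balance, parental-lineage inference from group-exclusive SNVs, gene
diversity, ABBA-BABA introgression tests and SNV phylogenies, plus a
synthetic species-complex generator used to validate every stage. This
vignette documents the models, the tunable parameters and the design
decisions, so that the defaults can be audited rather than trusted.

## The variant container

All stages operate on a `variant_set`: a columnar table of sites (CHROM,
POS, REF, ALT, QUAL and the numeric INFO annotations MQ, QD, FS, MQRankSum,
ReadPosRankSum, SOR, DP) with per-sample genotype and allele-depth strings
kept verbatim from the VCF. Keeping genotypes as strings of allele indices
is deliberate: it represents diploid `0/1`, tetraploid `0/0/1/1` and
hexaploid calls in one matrix, missing data stays `./.` and is never
imputed, and multi-allelic records survive parsing so that the filter stage
can *count* their removal instead of losing them silently. Variant
positions are 1-based throughout (VCF convention); BED's 0-based half-open
coordinates are converted once, at `read_intervals()`, into the 1-based
closed `GRanges` convention that every R overlap operation downstream
uses — one conversion site, testable against both dialects.

## Hard filters

SNV sites pass when MQ > 40, QD > 2, FS < 60, MQRankSum > -12.5,
ReadPosRankSum > -8, SOR < 3 and DP >= 10; the depth rule is the only
non-strict comparison, and boundary tests pin both kinds (MQ = 40 fails,
DP = 10 passes). Sites with any missing genotype and sites with more than
two alleles are removed. Indels pass when QD > 2, QUAL > 30.0, FS < 200,
no genotype is missing, and at least two individuals carry an indel allele
(support counts carriers regardless of zygosity). Two policies are
configurable because the right answer is data-dependent:

* `missing_annotation`: a record lacking a required INFO key fails by
  default (conservative — callers sometimes omit rank-sum annotations at
  sites without heterozygotes); a `"pass"` switch lets users audit how
  much that policy costs, and the removal report lists the
  `missing_annotation:<key>` counts separately so the decision is visible.
* every failing site carries one reason per violated rule, and
  `filter_snvs()` / `filter_indels()` aggregate them into per-rule removal
  counts.

## Ploidy from allele balance

At a heterozygous site carrying the alternate allele in $i$ of $k$ copies,
the fraction of alternate reads is approximately $\mathrm{Binomial}(d,
i/k)/d$ at depth $d$, so the allele-balance (AB) density of a $k$-ploid
peaks near $i/k$: one peak at 0.50 for a diploid, three near
0.25/0.50/0.75 for a tetraploid, five near 0.17/0.33/0.50/0.67/0.83 for a
hexaploid. Profiles use only biallelic sites whose genotype is
heterozygous *and* whose depths are informative (0 < alt < total): an AB of
exactly 0 or 1 contradicts the het call and is excluded. A chromosome
whitelist restricts profiles to pseudo-chromosomes when assemblies carry
unplaced scaffolds.

`detect_modes()` is pinned for reproducibility: Gaussian KDE, bandwidth
0.02 on the AB scale, 512 evaluation points on (0, 1); modes are local
maxima, and maxima below 10% of the global maximum are discarded
(`min_rel_density = 0.1` — low enough to keep the broad low-balance
secondary mode visible, high enough to drop noise wiggles).

`call_ploidy()` greedily matches detected modes to each candidate template
$\{i/k\}$ within a tolerance (default 0.05); the candidate matching the
most template peaks wins, ties broken by lower mean absolute deviation and
then by smaller $k$. Two details matter:

* Modes inside the low-balance window (default [0.05, 0.25)) are held to
  a stricter matching tolerance (`low_tol = 0.02`). Even true diploids
  show a broad, low mode in that window — collapsed repeats and segmental
  duplications produce reads from more than two haplotypes — so window
  evidence is unreliable and only counts when it falls almost exactly on
  a template peak: a tetraploid mode at 0.243 still supports the 0.25
  peak, while a diploid's broad secondary bump at 0.12 is not accepted as
  the hexaploid's 0.167 peak. Window modes left unmatched never count
  against a candidate; they set the `secondary_mode` flag instead.
* At 30x depth a hexaploid's three interior components overlap heavily
  (per-component binomial sd ≈ 0.086 against a spacing of 0.167), so the
  exact KDE of the mixture has a near-plateau between 0.3 and 0.7 and the
  *positions* of interior local maxima are unstable even at 100,000 sites.
  The outer components (0.17, 0.83) remain sharp. Calls are driven by the
  modes that do match the template; a tighter matching tolerance simply
  ignores the plateau wiggles. Numerical convolution of the exact
  binomial mixture with the 0.02 kernel puts the lowest hexaploid mode at
  0.176, not 1/6 = 0.167 — an intrinsic, depth-dependent outward shift of
  the measurement itself, worth knowing when comparing mode positions to
  the idealized $i/k$.

Low-balance positions (AB within a configurable window) are classified
against repeat and gene annotation tracks independently — a position
inside both is counted in both categories. The window defaults to
[0.05, 0.25]; 0.20 as upper bound is equally defensible and available by
configuration, since reasonable descriptions of the secondary peak differ
on where it ends, and the package surfaces rather than resolves that
choice.

## Exclusive SNVs and allopolyploid parentage

An exclusive SNV of a focal diploid group is a biallelic site where every
focal member carries the alternate allele (homozygous or heterozygous)
and every member of every other diploid group is homozygous reference.
Only the variant allele can be exclusive: if the reference allele were
eligible too, a fixed difference between two groups would be "exclusive"
to both at once, and exclusivity would no longer partition sites among
groups. Groups in which every focal member is heterozygous qualify for
the `includes_heterozygous` class; their sub-count is reported separately
so users who prefer the stricter reading can subtract it. Polyploids are
excluded from this step, and sites with missing genotypes in any involved
sample are dropped.

A polyploid *shares* an exclusive site when its genotype contains at least
one copy of the exclusive allele. Shared sites are split by the
polyploid's own zygosity (homozygous-alternate vs heterozygous) and
expressed as percentages of the polyploid's SNV totals of the same class;
this convention guarantees every percentage is a subset fraction in
[0, 100] and mirrors how genome-wide polyploid hom/het totals are used as
fixed denominators. Supplied totals override computed ones (with the
computed values still available), because genome-wide totals typically
come from a larger callable set than the sites in memory. The true
parents of a simulated allotetraploid rank in the top 2 of its column in
at least 90% of generator runs — that recovery, not any absolute
percentage, is the validated property.

## Gene diversity and ABBA-BABA

Nei's gene diversity uses the unbiased per-site form $h = \frac{n}{n-1}(1
- \sum_i p_i^2)$ with $n$ the callable allele copies (mixed ploidies pool
naturally), averaged over all callable sites; monomorphic sites contribute
zero, which is what puts genome-wide values on the ~1e-3 scale. The
`n_total_sites` argument supplies the callable-genome denominator when the
variant set holds only polymorphic sites.

The ABBA-BABA test uses frequency-weighted site patterns on derived-allele
frequencies $p_1, p_2, p_3, p_4$ (outgroup last): $\mathrm{ABBA} =
(1-p_1)p_2p_3(1-p_4)$ and $\mathrm{BABA} = p_1(1-p_2)p_3(1-p_4)$, summed
over sites, with $D = (\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+
\mathrm{BABA})$. The ancestral state is the outgroup's major allele; a
polymorphic outgroup down-weights a site by $1-p_4$ rather than discarding
it (a strict fixed-outgroup switch exists). Significance comes from a
delete-one block jackknife over contiguous site blocks (default 50 blocks,
at least 20 informative ones enforced): $Z = D/\mathrm{SE}$ with a
two-sided normal p-value, and Benjamini-Hochberg correction across trios.
Blocks stand in for the megabase-scale genomic blocks used on real data;
on simulated data without linkage they are conservative but exercised
identically. By default only trios whose (P1, P2) are sisters relative to
P3 on a guide tree are tested — the arrangement under which D tests gene
flow without presupposing it — with an exhaustive mode for completeness.

## Phylogeny

The pseudo-alignment substitutes each sample's homozygous alternate
alleles into the reference, one column per retained site, checking every
record's REF allele against the reference sequence. In nuclear mode a
site heterozygous in *any* sample is dropped — a column needs one state
per sample — with a per-sample `het -> N` masking alternative by flag;
organelle mode treats calls as haploid. Trimming retains exactly the
columns with two or more distinct non-N states — the strictest sense in
which a column can be non-informative; it is idempotent and oracle-tested
against a brute-force column scan. Distances are p-distances with
pairwise deletion of N columns; trees are neighbor joining (additive
matrices recovered exactly), with column-resampling bootstrap support
(default 100 replicates, seeded). NJ is the desk-scale tree: the trimmed
alignment is exported as FASTA or relaxed PHYLIP for external
maximum-likelihood tools, which are deliberately out of scope. The
reference itself can be included as a taxon but is off by default, since a
reference-as-outgroup can distort rooting when the reference belongs to an
ingroup lineage.

## The synthetic species complex

The generator's defaults are the study conditions every recovery property
is validated under: a 200 kb genome over 5 chromosomes (large enough for
~10-15k variant sites and 50 informative jackknife blocks, small enough
for seconds-scale replicates), 4 diploid lineages on a ladder tree
(terminal branches 0.008 substitutions/site, internal 0.004), 2
individuals per lineage, within-lineage diversity 0.005/bp, ancestral
polymorphism 0.005/bp, an allotetraploid = L1 x L2 and an allohexaploid =
tetraploid x L3 (one individual each), depth Poisson(30), read error
0.002. Sites are infinite-sites biallelic in four classes: clade-fixed
(internal branches), lineage-private fixed, within-lineage segregating
(Hardy-Weinberg), and ancestral polymorphisms whose frequencies drift down
the tree by binomial resampling with `drift_copies = 8` — chosen so a
sizeable share of ancestral variants sorts to fixation (differentiation on
the order of F_ST ≈ 0.3, consistent with lineages that also carry fixed
differences). The drifted class supplies both the incomplete-lineage-
sorting noise that calibrates the D statistic and the mixed-dosage sites
that give polyploids their full set of allele-balance peaks.

Polyploids are sampled at formation — the tetraploid founder is a diploid
draw from each parent, the hexaploid adds a third diploid draw to the
founder — plus optional post-formation private mutations; meiosis and
homoeologous exchange after formation are not modelled. Introgression
replaces the recipient lineage's allele frequency by the donor's at a
stated fraction of sites. Read depths are Poisson (zeros resampled to 1)
with binomially sampled alternate reads and symmetric error.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage and recombination (sites are
independent, so jackknife blocks are i.i.d. rather than autocorrelated),
mapping and calling artifacts (genotypes are the truth; INFO annotations
are uniformly passing, so filter behaviour is validated on separate fuzz
data), collapsed repeats (the low-balance secondary peak of real diploids
has no generative counterpart here; its handling is validated on the
call-level rules instead), multi-allelic sites and indels (fuzz-generated
in the I/O and filter tests), and any selection or biogeography.

## Validated properties and problem sizes

The test suite validates, at desk scale and with fixed seeds: exact peak
templates; ploidy recovery on 100,000-site allele-balance profiles at
depth 30 (20 seeds per ploidy, calls 100% correct, matched modes within
0.02 of $i/k$); tetraploid parent recovery over 20 simulated complexes
(top-2 ranking in >= 90%); D-statistic calibration (|Z| < 3 in >= 95% of
40 null complexes; D > 0 with Z > 3 in >= 90% of 20 complexes with 15%
introgression); brute-force oracle equivalence for filter decisions,
interval overlaps, trimmed column sets, p-distances and BH-FDR on >= 1,000
fuzz cases each; exact NJ recovery of 50 random additive 8-taxon
matrices with saturated bootstrap support on clean splits; and Nei's H
against closed forms at 1e-12. The `scripts/acceptance.R` report
recomputes the peak-template and simulated mode-position quantities from
scratch under a caller-supplied seed.

## Numerical and degenerate-input choices

Seeds are mandatory wherever randomness exists, and library code restores
the caller's RNG state. The pipeline derives per-stage seeds from the one
global seed so stages stay individually reproducible and stage toggles
cannot shift another stage's stream. Ties in ploidy scoring break toward
smaller $k$ (the conservative call). Zero-variant simulations, zero-column
alignments after trimming, empty low-balance selections and groups with
zero exclusive sites all return well-defined empty results rather than
errors; genuinely unanswerable requests (no heterozygous sites, zero
totals, fewer than 20 informative jackknife blocks, fewer than 3 taxa)
raise errors that name the condition.

## Known limitations

Ploidy calling assumes autopolyploid-style dosage mixing at heterozygous
sites and a depth high enough for the outer peaks to resolve; below ~20x
the hexaploid template degrades first. Aneuploidy is out of scope — calls
are genome-wide, not per chromosome. The sharing matrix identifies
parental *lineages*, not admixture fractions; formal f4-ratio estimation
is out of scope. The jackknife assumes many weakly dependent blocks; on
very short regions its Z is anticonservative. The NJ tree is a distance
summary for desk-scale work, not a substitute for model-based inference
on the exported alignment.
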