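---
title: "Methods: RAD-seq genotyping, DH linkage mapping and CIM in radmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RAD-seq genotyping, DH linkage mapping and CIM in radmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radmap)
```

`radmap` turns barcoded single-end RAD reads from two inbred parents and
their doubled-haploid (DH) progeny into a SNP marker panel, a genotype
matrix, a genetic map, and QTL scans. This vignette documents the models
behind each stage, the parameters that matter, the numerical conventions,
and what validation on simulated data does and does not establish.

## Read model and demultiplexing

A read is modelled as 36 nt: a 4-nt inline multiplex identifier (MID), the
6-nt SbfI remnant `TGCAGG`, 22 nt of genomic sequence, and 4 nt of
downstream filler that is never analysed. The analysed *tag* is read
positions 5–32 (1-based, inclusive): remnant plus genomic core, 28 nt. Two
conventions follow from this layout:

* SNPs can only occur at tag offsets 6–27 (0-based) — the remnant is
  invariant by construction, and the simulator, the discovery module and
  the tests all rely on that.
* Where sources disagree on whether the analysed tag is 28 or 30 nt, the
  28-nt convention is used throughout.

Demultiplexing is an exact match: positions 1–4 must equal a known MID and
positions 5–10 must equal `TGCAGG`. There is deliberately no 1-mismatch
barcode rescue — rescue would recover a few reads but distort per-sample
depth statistics that the depth filters depend on, and reads with `N` in
the barcode or remnant must never be assigned. Reads failing either check
are counted per category (`discarded_barcode`, `discarded_remnant`,
`discarded_short`), so the partition property
(assigned + discarded = input) is checkable on any input.

## Cluster depth filters and SNP discovery

Within each parent, identical tags are collapsed into clusters whose depth
is the read multiplicity. Discovery keeps clusters with depth in
**[8, 500]**, both bounds inclusive: depth 8 and 500 pass, 7 and 501 do
not. The floor suppresses sequencing-error tags (an error tag must recur
identically ≥ 8 times to survive, which at per-base error rates near
10⁻³ is vanishingly rare); the ceiling removes putative high-copy
repeats, whose collapsed clusters accumulate reads from many genomic
copies.

Parental clusters are then paired by Hamming distance ≤ 2 over the full
28-nt tag. The matcher splits each tag into 3 segments (sizes 10/9/9);
any pair within distance 2 must share at least one exact segment
(pigeonhole), so hash-joining on segments yields a candidate set that full
Hamming verification reduces to exactly the brute-force all-pairs result —
the test suite proves this equivalence against an independent
all-pairs oracle on 1000-tag instances. Classification:

* unique pair at distance 0 — monomorphic;
* unique pair at distance 1–2 — **codominant** SNP locus, with
  `snp_positions` the 0-based differing offsets;
* no partner — dominant (presence/absence) in one parent;
* any tag in a non-unique pairing — **ambiguous**, excluded.

Ambiguous multi-partner tags are excluded rather than resolved to a best
hit: multi-partner structure is exactly what paralogous or repetitive
families produce, and a wrong pairing would create a marker whose two
"alleles" are different loci. Only codominant loci proceed to genotyping;
dominant tags cannot distinguish allele absence from missing data in a DH
design and are not mapped. Locus ids are assigned as `FGX_SIM%05d` in
lexicographic tag order so that identical inputs always produce identical
panels.

## Genotype calling

Progeny reads are matched to panel alleles at Hamming distance 0 only.
Error-tolerant matching is rejected on purpose: at a 1-SNP locus a single
base error can convert one allele into the other, so distance-tolerant
matching risks allele switching, while exact matching converts errors into
(recoverable) missing data. The call rule per locus:

* ≥ `min_reads` (default 2) reads of allele A and zero of B → `A`
  (symmetric for B);
* reads of both alleles → missing (conflict), regardless of the ratio;
* anything else → missing (insufficient depth).

The strict conflict rule (a 20:1 ratio is still missing) is chosen over
majority voting because DH truth contains no heterozygotes, so *any*
opposing read is evidence of contamination, mis-clustering or error; the
cost is a slightly higher missing rate, which the mapping stages tolerate
well. The CLI exposes `min_reads` for users who want to relax the floor.
With zero sequencing error this rule makes wrong calls *impossible* —
errors can only create missingness — and the suite asserts a literal zero
wrong-call count on error-free simulations. The discovery-phase depth
window does not apply to progeny: the 8×/500× filter is a discovery
repeat/error screen, while DH genotypes are callable from 2 reads.

Expected missingness under Poisson depth λ (error 0) is
P(depth ≤ 1) = (1 + λ)e^(−λ), verified at λ ∈ {2, 4, 8}.

## Marker and line QC

* **Missing-data filter**: a marker is excluded when missing/total ≥ 0.15;
  with 93 lines, 14 missing excludes, 13 retains. The filter is idempotent
  and monotone in the threshold.
* **Duplicate lines**: two lines are duplicates when they share ≥ 50
  informative markers with zero conflicts; duplicate sets are transitive
  closures and one representative (first in input order) is kept. The
  overlap guard prevents vacuous matches between mostly-missing lines.
* **Segregation distortion**: per marker, χ² = (nA − nB)²/(nA + nB)
  against 1:1 (1 df, no continuity correction — standard at n ≈ 82–93),
  reported as the signed score −log₁₀(p)·sign(nA − nB) so that the profile
  along the map shows which parent's allele is favoured. Under a true 1:1
  null at n = 82 the discreteness of the binomial makes the exact
  flag rate at α = 0.05 slightly above nominal; the calibration test uses
  a 3-SD binomial band around 0.05 over 1000 markers, which accommodates
  this.
* **Singletons**: a call differing from the nearest informative call on
  both sides is an apparent double crossover. Over short intervals double
  crossovers are far likelier to be genotyping errors than real, so the
  call is recoded to missing when **both** flank distances are under
  `max_flank_cM` (default 10 cM) and retained otherwise. The default
  operationalises "flanks wide enough to expect recombination"; it is
  exposed as a parameter because no principled universal value exists. The
  rule knowingly erases the rare genuine tight double crossover — recoding
  to missing (never to the opposite allele) makes that cost a loss of
  information, not an error. Singleton detection needs a map, so the
  intended workflow is two-pass: build a map, recode, re-map.

## Linkage mapping

For a DH pair of markers, an individual is recombinant iff its calls
differ; with k recombinants among n pairwise-complete individuals,
r̂ = k/n and the linkage LOD is the log₁₀ likelihood ratio against
independence:

LOD = k·log₁₀(r̂) + (n − k)·log₁₀(1 − r̂) + n·log₁₀(2),

with the k·log₁₀(r̂) term taken as its limit 0 at k = 0 (so perfect
cosegregation over 100 individuals gives exactly 100·log₁₀2 ≈ 30.10) and
LOD = 0 for r̂ ≥ 1/2. Missing calls make an individual uninformative for
that pair only (pairwise-complete observation), the standard two-point
practice.

Linkage groups are connected components of the graph with edges where
LOD ≥ 5 and r̂ < 0.5; markers without any edge are reported unlinked. A
marker linked to two clusters merges them — the conservative graph
behaviour — and such bridges remain visible in the pairwise table.

Within a group, markers with pairwise r̂ = 0 collapse into bins ordered as
units. The bin order minimises the sum of adjacent recombination fractions
(SARF): a greedy nearest-neighbour chain grown from one end of the most
distal pair, refined by 2-opt segment reversals **and** or-opt single-bin
reinsertions until neither improves. The or-opt pass was added because
2-opt alone cannot repair a single misplaced marker (that move is a 3-opt
neighbourhood), and such stuck states occurred in simulation with the
found SARF strictly above the true order's. With both moves, residual
ordering failures at 20 markers / 5 cM / n = 93 are almost exclusively
cases where the *data's* SARF optimum genuinely differs from (or ties) the
true order — no SARF-based search can do better there. Orientation is
resolved by anchor markers when provided, else the lexicographically
smallest end goes first; either way the choice affects only the direction,
never lengths.

Positions accumulate Haldane distances d = −50·ln(1 − 2r̂) between
adjacent bins (r as a fraction, d in cM; r ≥ 0.5 is an error — infinite
distance). If an assembled order ever presents an adjacent r̂ ≥ 0.5 the
order is rejected and re-derived from the opposite greedy start; should
the anomaly persist (not observed at tested scales) the fraction is
clamped just below 0.5 with a warning rather than aborting a whole run.

**Validating map length.** In a finite DH population the *realised* map
length of a chromosome is itself a random variable: with n = 93 and a
95-cM chromosome, meiotic sampling alone gives the realised length a
standard deviation near 11%. The estimator-recovery checks therefore
compare estimated group lengths with the realised true lengths computed
from the simulator's recorded crossovers (its ground truth), not with the
nominal expectation — this isolates estimation error from meiosis
sampling, which no estimator can remove. Consistency in n is checked
separately (mean length error shrinks from n = 50 to n = 500).

## QTL mapping

Scans use Haley–Knott regression on expected genotype scores rather than a
mixture-likelihood EM: for DH line values at these effect sizes the two
are practically equivalent, and the regression form is deterministic,
fast enough for 1000-permutation thresholds, and exactly testable.
Genotypes are coded +1 (parent A) / −1 (parent B) at markers; between
flanking informative markers the score is the conditional expectation
under Haldane no-interference probabilities (for flanks L, R at
recombination fractions r₁, r₂ from the scanned point: P(same as both
flanks) = (1−r₁)(1−r₂)/((1−r₁)(1−r₂)+r₁r₂), and the analogous odds when
flanks disagree); with one informative flank at distance d the score
shrinks by (1 − 2r(d)); with none it is 0 and the individual is flagged
uninformative. Scores always lie in [−1, 1] and equal the hard call at
observed markers.

Composite interval mapping regresses the line-mean trait at each grid
position (walk speed `step_cM`, default 1 cM) on the local score plus
background cofactors, **excluding** any cofactor mapped within
`window_cM` (default 50 cM) of the scanned position on the same group.
Cofactors (≤ 7) come from forward-selection/backward-elimination stepwise
regression at α = 0.1 on bin-representative markers (bin members are
perfectly collinear). With zero cofactors CIM reduces exactly to simple
interval mapping — asserted in the tests by refitting both models
explicitly.

The statistic is LR = n·ln(RSS₀/RSS₁) against the cofactor-only model,
reported as **LOD = 0.217·LR** — the rounded constant conventional in QTL
software output, used verbatim rather than 1/(2 ln 10) ≈ 0.2171 so that
reported LODs match that convention. The additive effect is the
coefficient on the score (half the fitted A−B contrast); R² is
(RSS₀ − RSS₁)/TSS, the share of total trait variance attributable to the
scanned term. LOD is invariant to affine transformation of the trait.

Genome-wide thresholds come from permuting trait values across lines
(n_perm = 1000, α = 0.05 by default) and taking the empirical
(1 − α) quantile of the per-permutation maximum LOD; with a fixed seed
the threshold is reproducible bit for bit. The permutation pass re-uses
pre-computed orthonormal bases of every position's design matrix, so 1000
permutations cost two matrix products rather than 1000 scans. Declared
QTL are per-group peaks above threshold with 2-LOD support intervals
(widest contiguous run within 2 LOD of the peak, truncated at group
ends).

Replicated traits feed only heritability: QTL scans use line means, and
H² = σ²G/(σ²G + σ²e/r) with σ²e the within-genotype mean square,
σ²G = max(0, (between-MS − within-MS)/r), and r the (balanced) replicate
count. Grain yield is derived literally as GY = SN·GN·HGW on per-line
component means; because HGW is a *hundred*-grain weight the product is on
a per-hundred-grains weight scale (no division by 100), which is
documented rather than "corrected" to keep the derived trait comparable
with the source convention. The eight measured traits plus GY form the
intended trait set. Epistasis (multiple-interval models) is out of scope;
no QTL×QTL terms are fitted.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe the design the pipeline targets: 7
chromosomes × 20 tag loci at 5-cM spacing, all polymorphic, n = 93 DH
lines, 10× mean progeny depth and 50× parental depth
(negative-binomial with size 10 — parents are sequenced several-fold
deeper than progeny, as discovery requires), 0.1% per-base substitution
error, and deterministic 4-nt barcodes. DH meiosis draws the first-locus
parent at random and recombines each interval independently with the
Haldane probability r(d) = (1 − e^(−2d/100))/2 — no crossover
interference, matching the map function used downstream. Among
polymorphic loci, 70% carry one SNP and 30% two, placed uniformly in the
22 variable positions. Repeat tags (optional) are unplaced monomorphic
loci emitting copy-number-fold reads, copy number uniform in 20–100 so
they straddle the 500× ceiling at realistic depths. Phenotypes sum signed
additive QTL effects (+a for the parent-A allele), an optional polygenic
line deviation, and replicate noise scaled so the realised broad-sense
heritability hits `h2_target` exactly in expectation.

Passing tests on these simulations demonstrates internal correctness —
that each stage recovers what the generative model planted, at the stated
rates — but real RAD data differ in ways the simulator deliberately omits:
indels and structural variation in tags, quality-dependent and
position-dependent error profiles, PCR duplicates and depth correlated
with GC or fragment length, partially homologous paralog families at
intermediate distances, segregation distortion from selection, and
crossover interference. Results on real data should therefore be screened
with the QC module (distortion profile, duplicate lines, singletons)
rather than assumed clean.

## Numerical conventions and degenerate inputs

* Coordinates: tag SNP offsets are 0-based in data structures and files;
  read positions are quoted 1-based (the tag is read [5, 32]).
* `filter_clusters` bounds are inclusive on both ends; the missing filter
  excludes at ≥ threshold.
* Two-point LOD at k = 0 uses the 0·log(0) = 0 limit; r̂ ≥ 0.5 gives
  LOD 0; pairs with no informative individuals are flagged, not dropped
  silently.
* Ordering tie-breaks are deterministic (input order; improvement
  threshold 10⁻¹²), so identical inputs give identical maps.
* A constant trait yields all-zero LODs and a zero permutation threshold;
  positions with fewer residual degrees of freedom than parameters are
  skipped with `NA` LOD; rank-deficient designs fall back to the design's
  rank (a collinear score column adds zero explained variance).
* `estimate_heritability` clamps σ²G at 0 and requires a balanced design
  with ≥ 2 replicates; H² is defined as 0 when σ²G = 0.
* Problem sizes in the validation suite (20-marker groups, 50-seed
  replicates, 200 null traits, 1000 permutations) were chosen as the
  smallest scales at which the binomial 3-SD acceptance bands are
  informative.

## Known limitations

* Exact-match genotyping discards reads with any error in the tag; at very
  low depth this inflates missingness faster than a likelihood-based
  caller would.
* Connected-component grouping can chain two chromosomes through a single
  spurious high-LOD bridge at small n; the pairwise table retains the
  evidence but no automatic split is attempted.
* SARF ordering is a heuristic: it finds the criterion's optimum in
  practice at these scales, but the criterion itself can prefer a wrong
  order when sampling noise is large relative to marker spacing.
* The CIM window rule excludes cofactors by map distance only; a cofactor
  just outside the window still absorbs some linked-QTL variance.
* Paired-end reads, indels, quality-aware error models, outbred/F2
  designs, dominant-marker mapping and epistatic models are out of scope.
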