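---
title: "Methods: annotating and analysing alpha-gliadin gene arrays"
author: "gliascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and analysing alpha-gliadin gene arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
procedures each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the problem
left them open.

## The problem

α-Gliadin genes occur as tandem arrays of intronless copies at the three
homoeologous *Gli-2* loci of hexaploid wheat. Any analysis of their
variation faces four linked tasks: find the copies in an assembly,
organise them positionally into loci and subloci, characterise their
celiac-disease epitope content, and place them in an evolutionary context
(trees; codon-level selection). A fifth task is quality control: tandem
arrays are exactly where assemblers collapse near-identical paralogs or
split heterozygous alleles, and read depth is the usable evidence for both.
`gliascan` implements each task behind a small S4/functional surface, and
pairs them with a generator that plants a known truth so every stage can be
tested exactly, offline.

## Gene discovery

Discovery is seed-and-extend: exact k-mers (default `seedLen = 12`,
tiled along each query) are located on both strands with
`Biostrings::matchPDict`; co-projected seed clusters define a window, which
is aligned query-globally to the genome with fixed scores (match +1,
mismatch −1, gap opening 4, gap extension 1 per gap position — Biostrings'
convention, under which a length-1 gap costs 5). A hit is kept when its
alignment identity (matches / alignment columns) reaches `minIdentity` and
its genomic span reaches `minLen`; overlapping same-strand hits keep the
best score. Identity/length thresholds replace a BLAST e-value cutoff
deliberately: e-values depend on database size and scoring tables, whereas
(0.90, 300 bp) is reproducible anywhere. A hit is a single contiguous
genomic interval by construction; no intron model exists, which encodes the
fact that α-gliadins are intronless — a spliced gene cannot be produced,
only missed.

Two details earn their keep on gliadin sequences specifically. First, the
query's internal repeats (the repetitive domain and the polyglutamine runs)
scatter seed projections; the extension window therefore spans the whole
projected cluster, not just its left edge. Second, ORF status is *flagged*,
never silently filtered: lost start codons mark incomplete fragments, and
premature stops/frameshifts mark pseudogenes that remain biologically
informative (they still count as copies in locus tables). "Too diverged"
copies — operationalised as protein p-distance > 0.35 to the nearest query
after global alignment — are moved to a discard pile rather than deleted,
with the threshold chosen to separate the simulated gliadin family
(p-distances well under 0.1 at realistic divergence) from unrelated
prolamins.

## Locus and sublocus mapping

Clustering is one-dimensional and deliberately simple: sort candidate
midpoints, start a new cluster when the gap to the previous midpoint
exceeds `gapMb`. The default 5 Mb sits between two empirically separated
regimes — within-array spans stay under ~2.4 Mb while sublocus separations
start around 6.6 Mb — so the rule is insensitive to the exact value across
that whole interval. Naming follows the field's convention
(`Gli-{A,B,D}2`, with `-1`, `-2`, … suffixes in coordinate order only when
there are at least two clusters); positions are reported in Mb with one
decimal. Copy counts are reported as "total (intact ORF)": the published
convention of a parenthetical second count is not defined in so many
words anywhere we could find, so the table header states this package's
reading explicitly. Separations are span-gap distances (start of the later
sublocus minus end of the earlier), reported exactly and rounded to whole
Mb. Copies on unanchored scaffolds are assigned to *Gli-D2* by default
(the literature's suggestion for bread wheat); when a tree is available,
the clade label wins and a conflict flag records the disagreement.

## Epitope profiling

Scanning is exact substring matching of uppercase peptides, reporting
*every* occurrence including overlapping and repeated ones — overlap is
the biology here: the 33-mer is immunotoxic precisely because three
repeat-domain 9-mers tile it six times (1 + 2 + 3). Wildcards,
substitution tolerance and deamidation modelling are deliberately out:
a single substitution (the P→S that breaks DQ2.5-glia-α2 in A-subgenome
copies) must break the match. The epitope table is user-supplied; the
shipped default contains the four well-established DQ2.5-glia-α 9-mers and
the 33-mer, each with a provenance note, because the full canonical set
(nine epitopes in the source analyses, including p31-43 variants whose
exact sequences are not printed there) belongs in a configurable table,
not hardcoded. Profiles keep zero cells, and both plausible counting
conventions — total occurrences and genes-containing-epitope — are
emitted, since published figures do not say which was used. The 33-mer
detector reports the exact fixture count and, independently, a composite
rule (≥ 6 repeat-domain hits inside a 33-residue window, overlapping
qualifying windows collapsed into runs) so that a variant 33-mer with one
substitution outside all six 9-mers would still be noticed.

Proteins containing `*` (pseudogene translations) are scanned after
`*` → `X` conversion; `X` matches nothing, so a stop inside an epitope
destroys it, as it should.

## Alignment, distances, trees

Codon-aware alignment is protein-guided: translations are aligned and the
alignment is back-projected onto codons, so gaps always occupy whole-codon
triplets. The aligner is a deterministic center-star (center = highest
total 3-mer similarity; pairwise global alignments with fixed scores
match +4, mismatch −1, gap opening 10, gap extension 1; insertion blocks
right-aligned against the next center residue). A center-star is not a
full progressive aligner, but for intronless paralogs at ≤ 35% protein
divergence its alignments are dominated by exact residue matches, and
determinism — the same input always giving byte-identical output — was
valued over marginal alignment quality. The original analyses delegated to
MUSCLE with unstated parameters; exactly reproducing that alignment is not
attempted, and the scoring scheme here is pinned and documented instead.

Distances are Kimura 2-parameter from transition (P) and transversion (Q)
proportions, with gamma rate-variation correction at shape α (default
2.25, the published setting; `alpha = Inf` gives plain K2P). Complete
deletion at codon granularity is the default, pairwise deletion the
option. Saturated pairs (log or power argument ≤ 0) and pairs with no
comparable sites receive a flagged ceiling distance (default 5.0
substitutions/site) rather than an error, because neighbor joining needs a
complete matrix; the flags travel with the matrix so downstream users can
see which distances are caps, not estimates. Neighbor joining itself is
delegated to `ape::nj` (a standard step, not this package's
contribution), with negative branch estimates clamped to zero and logged;
bootstrap resampling is codon-granular, replicates with degenerate
matrices are skipped and counted, and supports are percentages of
successful replicates. Clade labelling walks the tree top-down and cuts
maximal subtrees in which one locus label holds a strict majority
(> 50%) of the voting (non-chrUn) leaves; leaves disagreeing with their
clade label are the flagged "outliers", and chrUn leaves inherit the clade
label without voting.

## Codon site models (M7 / M8)

The selection stage is the package's numerical core. The substitution
process is GY94 on the 61 sense codons: rates are zero for
multi-nucleotide changes and π_j, κπ_j, ωπ_j, ωκπ_j for synonymous
transversions/transitions and nonsynonymous transversions/transitions.
Codon frequencies are F3x4 estimated from the data (floored at 1e−8 and
renormalized so the chain stays irreducible when a nucleotide is absent at
some position). The ω distribution is Beta(p, q) discretized into K = 10
equal-probability categories represented by their medians — the CODEML
convention — and M8 adds a point mass at ω_s ≥ 1 with weight 1 − p0.
Likelihood is Felsenstein pruning, implemented in C++ (RcppArmadillo): per
category the rate matrix is symmetrized by √π, eigendecomposed, branch
transition matrices are spectrally reconstructed, and per-node column
rescaling guards against underflow. Site patterns are compressed to unique
columns with weights. Categories are normalized by the *mixture-average*
rate, so a single free scale multiplier on the input branch lengths is
interpretable as expected substitutions per codon under the fitted
mixture, and — importantly — higher-ω sites evolve proportionally faster,
exactly as the simulator generates them.

Cleanup before fitting follows conservative full-length rules: rows with
premature stops, frameshifts, or no terminal stop are dropped (the
terminal stop is then stripped); all-gap codon columns go; and codon
columns inside any run of ≥ 8 consecutive columns whose residues are
≥ 75% Q/P are masked as unalignable polyglutamine — these regions produce
false selection signals through alignment uncertainty, not biology.

Optimization is bounded L-BFGS-B over (κ, p, q, scale[, p0, ω_s]) from
`starts` seeded initial points (default 5; the M8 surface is multimodal in
(p0, ω_s)). A warm start from an M7 fit embeds the null at the p0 = 1
boundary with ω_s = 1, which guarantees the fitted M8 likelihood can never
fall below the M7 one — the nesting the likelihood-ratio test relies on.
Bounds are κ ∈ [0.2, 50], p, q ∈ [0.02, 50], scale ∈ [1e−4, 100],
p0 ∈ [0, 1], ω_s ∈ [1, 50]; parameters ending at a bound are recorded in
the diagnostics (identical sequences, for instance, legitimately drive the
scale to its lower bound). Non-convergence in every start is returned as a
flagged result, never a silent success.

The LRT statistic 2(ℓ8 − ℓ7) is clamped at zero and referred to χ²(2)
(M8 adds two parameters); the boundary makes this conservative, which is
accepted and stated rather than corrected. Site posteriors default to NEB
(mixture responsibilities at the MLE); a coarse-grid BEB — averaging the
posterior over a fixed (p0, p, q, ω_s) grid weighted by data likelihood,
with κ and scale held at their MLEs — is available as an option. Full
CODEML-style BEB integration is out of scope; the package's accuracy
claims for posteriors are made, and tested, via simulation recovery under
the stated harness (8 taxa, balanced tree, branch lengths 0.25), which NEB
passes. Branch lengths are taken from the input tree and rescaled by one
free multiplier rather than re-optimized per branch; this is a documented
deviation from CODEML that keeps the optimization desk-scale, and the tree
itself is always an input (Bayesian tree estimation is out of scope; the
NJ tree is offered as a fallback).

## Coverage QC

Mean per-gene depth is compared to the genome-wide median gene coverage
(the bundled default 32.23 genome equivalents is the published ONT value
for CDC Landmark). Collapsed two-copy genes expect 2× coverage,
haplotype-specific assemblies of heterozygous alleles expect 0.5×; the
thresholds 1.5× and 0.6× sit between those expectations and 1× with a
noise margin. The source analyses speak only of coverage that "clearly
deviated", so these numeric defaults are this package's choice and are
exposed as parameters. Note the asymmetry: the haplotype-specific decision
margin (0.1× of the median, from 0.5× to 0.6×) is tighter than the
collapsed one (0.5×), so exact recovery of planted statuses requires depth
noise below that smaller margin — the tests exercise the classifier in
that regime.

## The synthetic world

`generateAssembly` plants copies of a gliadin-like template CDS (signal
peptide, epitope-free repetitive domain, two polyglutamine runs, two
low-Q/P unique domains, terminal stop; 504 bp) at configured sublocus
anchors on i.i.d. uniform-ACGT background. Defaults state a desk-scale
hexaploid accession: three 12 Mb group-6 chromosomes; one array on 6A
(4 copies) and 6D (3 copies); a bipartite 6B locus (3 + 2 copies) whose
subloci sit 7 Mb apart — the real sublocus-separation regime at reduced
chromosome scale; 2% per-site divergence per copy (inside the ≤ 5% regime
where exact-coordinate recovery is expected); 35% pseudogenization (lost
ATG, internal stop, or 1–2 bp indel, one per pseudogene), matching the
intact/total ratios seen across real accessions; epitopes planted after
the substitution process (so they are retrievable from the truth
translation by construction), with the 33-mer in a D-subgenome copy — its
real subgenome — and DQ2.5-glia-α 9-mers in A and D copies; one copy each
flagged collapsed (2× expected depth) and haplotype-specific (0.5×),
because the depth simulator, not the sequence, carries that evidence —
mirroring the fact that collapse is a coverage observation, not a sequence
one. Background realism (repeat landscape, GC structure), Hi-C and
read-level simulation are deliberately absent: a green discovery test
establishes that the search finds planted genes on neutral background at
stated divergence, not that it would survive a real wheat repeat
landscape.

`simulateCodonAlignment` draws per-site ω from the continuous model
(beta, or beta-plus-point-mass), then evolves each site along the tree
under GY94 with mixture-average rate normalization — deliberately the same
normalization the fitter assumes, so calibration studies test the
inference, not a rate-convention mismatch. The fitted family uses the
K = 10 discretization while the generator uses the continuous beta; the
residual mismatch is part of what the calibration criterion absorbs.
Sequences can contain no stop codons by construction.

All randomness flows through explicit seeds; identical (config, seed)
give byte-identical artifacts, and the pipeline derives per-stage seeds
from one global seed.

## Numerical choices, in one place

* Alignment scores: DNA +1/−1, gap open 4, extend 1; protein +4/−1, gap
  open 10, extend 1 (Biostrings convention: a length-1 gap costs
  open + extend).
* K2P ceiling distance 5.0 with flags; symmetry asserted to 1e−12 in
  tests; distances cross-checked against `ape::dist.dna` (K80, gamma).
* Beta discretization K = 10, category medians; qbeta accuracy warnings at
  optimizer-explored extreme shapes are suppressed (1e−4 quantile error is
  immaterial for category medians).
* Pruning uses per-node column rescaling; per-site per-category
  log-likelihoods are kept for posteriors; the C++ path is tested to
  1e−8 against an exhaustive state-sum oracle whose transition matrices
  come from a series-based matrix exponential.
* L-BFGS-B with `factr = 1e9`, `maxit = 200`; multi-start jitter is
  multiplicative on log scale, seeded.
* NJ ties and orderings are whatever `ape::nj` produces; it is
  deterministic for fixed input, which is what reproducibility requires.

## Known limitations

* The center-star aligner can be suboptimal for deeply diverged or heavily
  gapped inputs; the selection stage's cleanup (and the divergence filter
  upstream) keeps it in its comfort zone.
* NEB posteriors understate uncertainty in (p0, ω_s) relative to full BEB;
  the coarse-grid BEB option narrows but does not close that gap.
* The LRT's χ²(2) reference is conservative at the p0 = 1 boundary.
* Coverage classification assumes depth noise below the haplotype-specific
  decision margin; with noisier depth the 0.6× threshold misclassifies
  by construction.
* The discovery oracle equivalence (and exact-coordinate recovery) is
  stated for the substitution-only regime; pseudogene indels shift
  coordinates by design and are recovered via alignment, not asserted
  against a window-scan oracle.
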