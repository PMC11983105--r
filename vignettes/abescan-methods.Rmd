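---
title: "Detecting ABE off-target edits from truncated-read signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ABE off-target edits from truncated-read signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(abescan)
library(dplyr)
```

## The signal being detected

Adenosine base editors (ABEs) are Cas9-nickase–deaminase fusions that
convert A·T pairs to G·C through a deoxyinosine (dI) intermediate on the
PAM-containing (nontarget) strand. Because polymerases read dI as G, and
because Endonuclease V cleaves the second phosphodiester bond 3′ of a dI,
libraries built from EndoV-cleaved, enriched single-stranded DNA carry a
highly specific footprint: a sequencing read whose 5′ end starts right
at the cleavage product places the edited base at its **second aligned
position**, read as a mutant call — A→G for reads aligned to the plus
strand of the reference, and T→C (in plus-strand reference coordinates)
for reads aligned to the minus strand. `abescan` detects, scores and
classifies genomic sites showing this truncated-mutant signature.

Strand handling is strictly operational: reads on the two reference
strands are tallied separately, and the "second aligned base" is counted
from the read's 5′ end in sequencing orientation — the second
reference-consuming base from the left edge for plus-strand alignments
and from the right edge for minus-strand alignments. Soft-clipped and
inserted bases never consume reference. Only R1 reads are used; the
library chemistry does not give R2 a comparable truncation signature, so
R2 is ignored throughout.

## Candidate calling: the seven-rule cascade

Candidates are seeded wherever truncated-mutant support reaches the
mutant-read minimum in at least one sgRNA(+) replicate, then audited
against seven rules whose defaults are the pipeline's published operating
points (every one is a `pipeline_config()` field):

| rule | meaning | default |
|------|---------|---------|
| i   | minimum mapping quality per contributing read | 5 |
| ii  | minimum strand depth per sgRNA(+) replicate | 5 |
| iii | minimum truncated-mutant reads and proportion of depth | 3 and 20% |
| iv  | maximum mutant reads in the untreated background | 1 |
| v   | signal present (rules ii + iii) in both replicates | — |
| vi  | not in a run of 3 consecutive >20% positions of ≥2 substitution types | 3 / 20% |
| vii | not a known polymorphism (exclusion list) | — |

Rule vi targets alignment/sequencing artifacts, which produce clusters of
mixed-type mismatches, unlike a genuine dI site whose signal is a single
strand-coherent substitution. Candidate rows keep a full pass/fail audit
column per rule, so any verdict can be recomputed from the reported
counts alone; failures are reported, not silently dropped.

Two read-count interpretations were possible for rule iii, since
"mutation number" is ambiguous between truncated-mutant reads and all
mutant reads. The cascade uses **truncated-mutant** reads (the signal
class the method is built on) for rule iii and for the site score, and
keeps the all-mutant **edited ratio** as a separate column used by the
classifier; both are in the audit TSV so the alternative reading remains
recoverable.

### The Selict score

The score of a site is the truncated-mutant fraction of strand depth,
pooled over the sgRNA(+) replicates:

$$\mathrm{score} = \frac{\text{truncated mutant reads}}{\text{strand depth}} \in [0, 1].$$

Per-replicate thresholds (rules ii–iii) are checked on each replicate
separately, while the score is computed on the pool, which maximizes its
stability without weakening the replicate-presence requirement. The exact
normalization behind the published score is not spelled out in the
protocol lineage (it cites cleavage-site scoring of the Digenome-seq
family); the fraction-of-depth definition used here is the simplest
statistic with the stated [0, 1] range and threshold behaviour, and it is
configurable.

## Binding-site search: modified semiglobal alignment

For each candidate, the window of 100 nt on each side is extracted and
the on-target sequence — the 20-nt protospacer plus the PAM pattern as
IUPAC codes (NRG by default) — is aligned against both window strands
with a fitting ("semiglobal") dynamic program: the target must be
consumed in full, window bases outside the match are free, and internal
gaps are affine with the published parameters match +5, mismatch −4, gap
open −24, gap extension −8 (interpreted per-position: a length-L gap
costs 24 + 8(L−1)). PAM positions score as a match for any base
compatible with the IUPAC code, so noncanonical-PAM binding sites surface
with an ordinary mismatch penalty rather than being excluded outright.

The alignment **penalty** is defined as $5L - S$ for target length $L$
and score $S$ — zero for a perfect match, 9 per substitution, 24 + 8(L−1)
per gap — and a binding site is retained when the penalty is below 70.
The source protocol states the <70 threshold without defining the
penalty; $S_{\max} - S$ is the only monotone transform of the stated
scoring scheme with a natural zero, and the cutoff is configurable.

Ties between equal-scoring alignments are broken deterministically:
leftmost window start, then fewest gap columns, then fewest mismatches.
A micro-check of the printed parameters: a perfect 23-nt match scores
115, one substitution 106, one 1-nt DNA bulge $23 \times 5 - 24 = 91$.

```{r align-micro}
cfg <- pipeline_config()
target <- "GAACACAAAGCATAGACTGCAGG"
win <- paste0("ACGTG", target, "TGCAT")
semiglobal_align(target, win, cfg)$score
```

## Classification

Candidates are labelled by comparing signal across the four samples:

* **cas9_dependent** — score ≥ 0.6, edited ratio ≥ 0.2, at most 1 mutant
  read in sgRNA(−), the cascade passed, and a binding site (penalty < 70)
  containing the edit. "Containing" extends `oop_flank` (20 bp) beyond
  the aligned span so out-of-protospacer edits — which the method
  explicitly reports and regresses on — remain attached to their binding
  site; no numeric span is published, and 20 bp comfortably covers the
  observed out-of-protospacer distance range while excluding unrelated
  loci. The sgRNA(−) ≤ 1 requirement uses all mutant reads, the stricter
  of the two possible readings.
* **cas9_independent** — at least 3 mutant reads in sgRNA(−) and none in
  untreated (deaminase activity without sgRNA guidance).
* **endogenous_dI** — present in both sgRNA(−) (≥ 3 mutant reads) and
  untreated (> 1 mutant read, i.e. failing the background rule): dI not
  induced by the editor. Classification runs over all candidate rows, so
  endogenous sites — which by construction fail cascade rule iv — are
  labelled rather than silently discarded, and can never leak into either
  off-target class.

Dependent calls are annotated with the protospacer position of the edit
(1 = PAM-distal, 20 = PAM-proximal; projected through the alignment, with
edits inside a DNA bulge assigned to the preceding protospacer position),
editing-window membership (default window 3–9; the published figures
shade the window without enumerating it, and 3–9 is the field's standard
ABE window), the out-of-protospacer flag with signed distance (negative =
PAM-distal side), and the edited strand: an edit on the same strand as
the protospacer orientation is a nontarget-strand edit (the canonical
deamination substrate), the opposite is a target-strand edit.

For Cas9-independent sites, the 5-mer context around the edited A (2 bp
each side, minus-strand edits reverse-complemented so the edited base is
always the central A, position 3) is tallied into a position frequency
matrix with per-column information content — an in-package replacement
for external motif-discovery software, sufficient for the fixed-width,
single-site-anchored question asked here (deaminase context preference;
a TAT preference is the expected signature).

## Edit-determinant regression

For every call with a binding site, nine features are extracted in
protospacer coordinates: mismatch and gap counts over the first 5 bp, the
first 8 bp (PAM-distal), the whole protospacer, and the seed region, plus
the PAM type (1 = NRG). The seed region defaults to positions 11–20 —
the protocol uses the term without defining it, and a ~10-nt PAM-proximal
seed is the standard Cas9 convention; it is configurable. Gap positions
for DNA bulges (extra genomic base) are assigned to the preceding
protospacer position.

`ridge_fit()` is a linear-probability ridge regression (binary outcomes
treated as 0/1, as the original analysis's ridge package does):
standardized features, coefficients $(X^\top X + \lambda I)^{-1} X^\top y$,
and analytic significance via
$\mathrm{Var}(\hat\beta) = \hat\sigma^2 (X^\top X + \lambda I)^{-1} X^\top X (X^\top X + \lambda I)^{-1}$
with $\hat\sigma^2$ on $n - \mathrm{tr}(H)$ effective residual degrees of
freedom and two-sided Student-t p-values. Whether the original analysis
standardized its features is unstated; standardization is applied here so
coefficients are comparable across count scales. $\lambda$ is chosen by
generalized cross-validation by default (the original selection rule is
unpublished) and can be fixed; at $\lambda = 0$ the fit reproduces
ordinary least squares to machine precision, which the tests assert. A
permutation mode (`p_method = "permutation"`) cross-checks the analytic
p-values, since the published analysis states only "two-sided Student's
t-test" without its variance formula. p < .01 is carried as a reporting
flag (`significant` in `tidy()`), never as a model input.

## Amplicon validation

UMI-tagged amplicon pairs (5-nt UMI on each mate) are grouped by exact
combined UMI; each group is collapsed to one consensus molecule by
per-position majority vote, with positions below 60% agreement masked to
N and UMIs containing N discarded. Exact matching replaces the original
tool chain's UMI correction; it is deterministic, and with 10-mer
combined UMIs over ≤ tens of thousands of molecules, UMI collisions and
1-error UMI splits move rates by far less than binomial noise. Rates
follow the published arithmetic: per position, raw = edited / qualified
molecules × 100; net = max(raw − matched control, 0) — the floor at zero
is a choice, as negative-rate handling is unpublished; positions need
≥ 500 consensus molecules in **both** samples to qualify, and
unqualified positions are reported but flagged.

## The simulator: what it emulates, and what it does not

Every downstream stage is testable against `simulate_run()`, which
generates (a) a pseudo-random genome (default GC 0.41, human-like);
(b) uniformly fragmenting background reads at mean depth 30× with
uniform substitution errors (0.1%) and a mapping-quality mixture (90% at
60, otherwise uniform 0–60, so the mapq filter is exercised); (c) planted
sites with ground truth: Cas9-dependent sites whose flanking sequence is
a degenerate protospacer+PAM copy with requested mismatches/bulges,
Cas9-independent sites with a TAT context, endogenous-dI sites planted
identically in all samples, and heterozygous SNPs present in every
sample's background and listed for exclusion; (d) truncated signal reads
placing the edited base at read position 2 under the strand convention
above. Replicates are independent binomial draws from the same truth, so
the replicate-presence rule has genuine stochastic behaviour. The
simulator emits already-aligned reads (positions are ground truth),
removing any external aligner dependency while still exercising every
filter.

Signal reads are emitted at `depth × signal_read_multiplier` trials per
site (default multiplier 5). The multiplier models the EndoV/streptavidin
capture step, which enriches dI-containing fragments roughly two orders
of magnitude over bulk background; without enrichment the
truncated-mutant fraction of depth could not reach the 0.6 dependent-call
threshold at any edit fraction, which is exactly why the laboratory
protocol enriches. The default is deliberately far below the measured
enrichment so that scores stay well inside (0, 1).

Not emulated: quality-score-dependent errors, indel sequencing errors,
adapters, mapping ambiguity (all reads are placed at their true
positions), R2 reads, and chromatin/accessibility effects on editing
efficiency. Passing tests therefore demonstrate the correctness of the
calling, scoring, alignment and classification logic under the stated
read model — not robustness to alignment artifacts of a real aligner,
which rule vi only approximates.

## Numerical and interface conventions

* Coordinates are 0-based half-open everywhere internally and in BED
  output; report TSVs add a 1-based `pos1` column for human readers.
* Reads failing proper-pair, primary or duplicate flags are dropped at
  ingest, mirroring the upstream sort/markdup contract; single-end
  records are treated as proper-pair R1 by convention.
* Degenerate cases: zero-depth sites are skipped (score undefined);
  empty call sets produce header-only reports; score × 1000 is clamped to
  0–1000 in BED; constant feature columns are dropped with a warning;
  background subtraction floors at zero.
* Determinism: every simulation entry point takes a seed, derived
  per-sample seeds stay below 2³¹, and `run_all()` twice with one seed
  yields byte-identical reports.
* Default problem sizes were chosen as the smallest that leave the
  binomial noise terms far from every threshold: 1 Mb genome / 30× depth
  / 20 planted sites for recovery runs, 150 kb for motif runs, 10,000
  molecules for amplicon recovery, 100 repeated designs of n = 1000 for
  the regression checks.

## Worked example

```{r example, eval = FALSE}
sg <- sgrna_spec("GAACACAAAGCATAGACTGC")
sim <- simulate_run(sg, default_site_specs(),
                    sim_params(genome_length = 100000), seed = 42)
cand <- call_candidates(sim$reads, sim$genome, sim$exclusion)
calls <- classify_sites(cand, sg, sim$genome)
count(calls, classification)
score_against_truth(calls, sim$sites)
```

On this seed the pipeline calls 14 candidates (12 passing the cascade),
classifies 7 as Cas9-dependent (the on-target plus six planted
off-targets, including the bulged and noncanonical-PAM sites), 5 as
Cas9-independent and 2 as endogenous dI, with recall and precision 1.0
for both off-target classes; the two planted SNPs are never called.

## Known limitations

* The fraction-of-depth score saturates at 1 and compresses differences
  between very strong sites; ranking within the top of the score range is
  less informative than in the middle.
* Exact-match UMI grouping slightly over-counts molecules when
  sequencing errors hit a UMI; the package discards N-containing UMIs but
  does not merge 1-error neighbours (a Hamming-1 merge is a possible
  extension).
* The linear-probability ridge model can predict outside [0, 1]; it is
  used for effect attribution, not for calibrated probability estimates,
  and no logistic variant is provided.
* Classification of sites near contig ends uses clipped windows; a
  binding site whose protospacer would extend past the contig cannot be
  found.
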