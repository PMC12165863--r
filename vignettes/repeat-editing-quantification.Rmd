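---
title: "Quantifying base-editing interruptions in trinucleotide repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying base-editing interruptions in trinucleotide repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatedit)
```

## The problem

Trinucleotide repeat (TNR) expansions — the CAG tract of *HTT* in
Huntington's disease, the intronic GAA tract of *FXN* in Friedreich's
ataxia — are somatically unstable in a length-dependent way, and instability
tracks the length of the *pure*, uninterrupted run rather than the total
tract. Base editors can install interruptions that mimic naturally occurring
stabilizing variants: a cytosine base editor acting on the CTG strand
converts CAG codons to synonymous CAA; an adenine base editor converts GAA
units to GAG, GGA or GGG. This package quantifies those editing outcomes
from amplicon sequencing, extrapolates them to full-length alleles, scores
somatic instability from fragment-analysis traces, quantifies off-target
editing from pileup counts, and compares interruption-count distributions.

## Triplet classification and read anchoring

A `repeat_spec` defines the locus: the pure triplet, an IUPAC degenerate
3-mer capturing every editing outcome, an explicit byproduct set, and the
amplicon flanks. For the CAG strategy the pattern is `YAR`
(Y = C/T, A, R = A/G), whose concrete matches are CAA, CAG, TAA, TAG; CAG is
pure, CAA is the intended synonymous interruption, and TAG/TAA — products of
rare opposite-strand deamination, which create stop codons in the
polyglutamine frame — form the byproduct set. For the GAA strategy the
pattern `GRR` yields intended interruptions GAG, GGA and GGG with no
byproduct set.

```{r}
cag_cbe_spec()
```

Reads are anchored by exact match of the 12 terminal bases of the left
flank and the 12 leading bases of the right flank. Exact k-mer anchoring
was chosen over alignment because it is deterministic, trivially testable
and adequate for amplicons whose flanks are fixed by the PCR design; an
anchor destroyed by a sequencing error demotes the read to one-sided or
unanchored status rather than corrupting the tract. With both anchors the
tract is the sequence strictly between them and a tract length that is not
a multiple of 3 raises an indel signal (repeat slippage or sequencing
indel). One-sided reads are decomposed from the anchored edge — from the
left for left-anchored reads, aligned to the right edge for right-anchored
ones — which keeps partial-tract reads from long alleles usable. Reads with
more than 20% N are discarded as unanchored, and any triplet containing an
N classifies as `other`: both choices are deliberately conservative.

Anchored reads covering fewer than 5 triplets are excluded from all
summary denominators; a per-read "edited" label over one or two triplets
carries almost no information and would dilute `f` asymmetrically. A read
counts as *edited* only when it carries at least one intended interruption;
byproduct-only reads are tallied separately, and product purity is reported
per-triplet (total intended : total byproduct) because a per-triplet ratio
is invariant to how much of the tract each read covers.

## The extrapolation model

Amplicon sequencing observes a window of W triplets of a tract of N >= W
units. From the window we measure the interrupted-triplet fraction `f`
(over all sequenced triplets), the mean interruptions per edited read `n_i`
and the mean interrupted tract fraction among edited reads `f_i`. The
per-triplet rate is taken as `p = f / n_i`, the probability that an allele
of N units carries at least one interruption is `1 - (1 - p)^N`, and the
expected interruption count in edited alleles is `f_i * N`. Observed and
estimated editing are always reported side by side, never substituted for
one another.

Two model properties matter for interpretation:

* Under independent per-triplet editing, `f` itself is the unbiased
  estimator of the per-triplet probability; the normalization by `n_i` has
  analytic expectation `(1 - (1-p)^W) / W` and coincides with `p` only in
  the sparse-editing limit (`n_i` near 1). The normalization is the right
  correction when interruptions cluster on a minority of transduced
  alleles — the regime the in vivo data occupy — but in a densely edited
  i.i.d. sample it underestimates `p`. The test suite asserts
  self-consistency at the window length in the sparse regime and only the
  direction of the bias outside it.
* Editing within an allele is not modeled mechanistically; the
  extrapolation is a stated heuristic, and the clustered simulation regime
  exists precisely to report (not assert) its behavior under violated
  independence.

N defaults to the genotyped modal repeat length of the sample, the choice
that matches how cohorts of fixed transgene length are analyzed;
uncertainty is available by bootstrap over reads
(`bootstrap_estimate()`, 1,000 resamples by default).

```{r}
spec <- cag_cbe_spec()
alleles <- simulate_alleles(2000, allele_model(modal_length = 20,
                                               p_edit = 0.02),
                            spec, seed = 1)
reads <- simulate_reads(alleles, spec, read_length = 150, seed = 2)
summ <- summarize_editing(call_reads(reads, spec), spec)
editing_estimate(summ, N = 300)
```

## Instability indices from fragment analysis

Fragment-analysis traces are (size, height) peak lists; sizes are converted
to repeat units by the user-supplied linear map `(size - flank_bp) / 3`,
because amplicon flank lengths differ between assays and no universal
constant exists. For each trace the signed change is computed against the
modal allele of a stable reference tissue (tail) of the same individual;
peaks below a relative height threshold (5% for capillary data, 10% for gel
densitometry, where the modal-height QC of 1,000 is also disabled) and
contractions beyond −40 units are discarded; and the index is the
height-weighted mean change. The threshold is anchored to the tallest peak
of the analyzed trace — the threshold's reference point is not specified
more precisely by the method this implements, and the tallest peak is the
modal peak whenever the reference allele is present. The Δ = 0 peak is
included in both one-sided modes, as the defining inequalities (Δ ≥ 0,
Δ ≤ 0) state, and contributes zero either way. Modal ties break toward the
smaller size; ties are a degenerate input and the rule exists only to make
results deterministic.

The numerators of the expansion- and contraction-mode indices sum exactly
to the both-mode numerator; the normalized indices themselves are not
additive, and the test suite asserts additivity only at numerator level.

## Off-target editing from pileups

Per-locus pileups (treated and untreated) carry A/C/G/T counts per
position. The pileup schema has no reference column, so editable positions
are defined as those whose untreated consensus base equals the strategy's
reference base (C for CBE, A for ABE; complemented for minus-strand loci).
Loci with 30 or fewer reads at any editable position are filtered;
positions whose untreated alt frequency exceeds 2.5% are excluded as
pre-existing polymorphisms. Remaining per-position frequencies combine
into a locus editing probability under position independence,
`1 - prod(1 - p_i)` — independence is an explicit modeling assumption, the
simplest rule consistent with per-position accounting. The same rule is
applied to the untreated counts, and a locus is *detected* when the
treated-minus-untreated probability exceeds 0.5% and *substantial* at 5%,
the threshold also used for consequence calling. Spacer/target mismatches
are binned PAM-proximal first: category A is protospacer positions 1–5,
B is 6–10, C is 11–20. Codon consequences use the standard genetic code:
identical codons are `none`, equal amino acids `synonymous`, a stop gained
`nonsense`, everything else (including stop lost) `missense`.

## KS comparison of interruption counts

Interruption-count distributions are compared with a two-sample
Kolmogorov–Smirnov test computed from first principles: D is the maximum
absolute ECDF difference over the union of observed values (no tie
correction — counts are discrete and the statistic is used descriptively),
and the p-value is the classical asymptotic form, obtained either in
closed form, `P = 2 exp(-2 D^2 n_i n_j / (n_i + n_j))`, or by bounded
quasi-Newton minimization of the squared inversion objective over log P
(initialized at P = 0.5, bounds (1e-300, 1]; the bounds keep `log(P/2)` in
domain). The two routes agree to 1e-6 across a (D, n) grid, and both are
capped at 1 — the raw formula yields 2 at D = 0, an artifact of the
asymptotic form. The single-exponential form tracks `stats::ks.test`'s
full-series asymptotic p-value within 10% away from p ≈ 1, which the suite
cross-checks.

## What the simulator does and does not emulate

The generator produces: alleles with configurable length distributions and
per-triplet interruption probabilities, either i.i.d. or clustered
(fixed-count per edited allele, emulating few transduced alleles carrying
several interruptions each); byproduct edits at a configurable per-edit
probability; uniform substitution sequencing errors; fragment traces with
multinomial expansion/contraction mass around a modal allele and optional
lognormal height noise; and binomial treated/untreated pileups with flagged
background polymorphisms. Every operation takes an explicit seed and runs
on a private RNG stream, so identical seeds give byte-identical outputs and
the caller's RNG state is never disturbed.

Defaults reflect the regimes the pipeline targets: 20-triplet observation
windows, per-triplet editing of a few percent, expansion mass shifts of a
few repeat units, 2.5%-scale background polymorphism and coverage in the
thousands. Not emulated — and therefore not demonstrated by passing
tests — are PCR stutter and repeat-length amplification bias in fragment
traces, quality-score-dependent error profiles, arbitrary (non-triplet)
indels, and alignment ambiguity at degenerate flanks. Whole-triplet
slippage indels exist behind a flag but are off by default, so frame errors
in the quantifier are never masked by simulation artifacts.

## Numerical and testing choices

Tolerances in the suite are derived, not tuned: closed-form identities are
checked to 1e-10–1e-12, Monte-Carlo recoveries to 3–5 binomial standard
errors at the stated sample sizes, and the KS minimization against its
closed form to 1e-6. Problem sizes (10,000 reads for rate recovery, 1,000
reads for the brute-force recount, coverage 10,000 for locus-probability
recovery) were chosen so each check is decisive in seconds on a single
core. Degenerate inputs are contracts, not surprises: empty traces, empty
samples and zero aligned reads raise explicit errors; unanchored reads are
a status; a locus with every position filtered reports an explicit status
rather than a probability of 0 masquerading as evidence.

## Limitations

The anchoring is exact-match by design and will under-recover reads whose
flank ends are error-dense; `n_i`, `f` and the edited fraction are computed
over reads, not deduplicated alleles, so PCR duplicates are not corrected;
the extrapolation model is a heuristic whose bias outside the
sparse-editing regime is characterized above; and the off-target
independence assumption ignores haplotype structure among nearby edited
positions.
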