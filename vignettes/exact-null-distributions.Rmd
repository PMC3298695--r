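---
title: "Exact motif-count null distributions over synonymous re-encodings"
author: "synmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact motif-count null distributions over synonymous re-encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(synmotif)
```

## The problem

Protein-coding sequence does double duty: it encodes amino acids, and it
carries nucleotide-level regulatory elements — exonic splicing enhancers,
RNA- and DNA-protein binding sites, microRNA seeds. Asking whether a short
motif is over- or under-represented in a set of coding sequences is
confounded by the protein: some amino-acid strings force the motif to
appear, others forbid it. The principled null holds the protein fixed and
randomizes only the synonymous codon choice.

Shuffling-based approaches sample a handful of synonymous re-encodings and
fit a parametric curve to the counts; with $\sim e^{N}$ re-encodings of an
$N$-codon input, a few dozen samples explore a vanishing fraction of the
space and the parametric form is uncontrolled. `synmotif` instead computes
the *entire* distribution of the motif copy number
$$D(X) \;=\; \sum_{\{\alpha\} \in C_A} p(\{\alpha\})\,
\delta\!\left(X - X(\{\alpha\})\right),$$
where $C_A$ is the set of all nucleotide sequences translating to the
amino-acid sequence $A$, $X(\{\alpha\})$ counts motif occurrences (all
frames, overlapping, any member of an equal-length k-mer set), and
$p(\{\alpha\})$ is a codon-usage null. The inclusive upper tail
$P(X \ge x_\mathrm{obs})$ is then an exact, non-parametric
overrepresentation p-value; underrepresentation is its complement.

## The two null models

**ICM (independent codon model).** Each codon is drawn independently from
the reference codon-usage table conditioned on its amino acid:
$p(\{\alpha\}) = \prod_i p(\alpha_i \mid A_i)$ with
$p(\alpha \mid A) = F(\alpha) / \sum_{\alpha' \sim A} F(\alpha')$, where
$F(\alpha)$ counts codon $\alpha$ in the reference.

**DCM (dinucleotide-corrected codon model).** Codon boundaries carry strong
neutral dinucleotide biases — above all CpG depletion from CG
hypermutability — that the ICM ignores, and which otherwise masquerade as
selection on motifs. The DCM is a codon-level Markov model conditioning each
codon additionally on the first base $b$ of its 3' neighbour:
$$p(\alpha \mid A, b) \;=\; \frac{F(\alpha, b)}{F(A, b)},$$
with $F(\alpha, b)$ the number of reference positions where codon $\alpha$
is immediately followed by a codon starting with $b$. Generation runs 3' to
5' because the genetic code usually fixes a codon's *first* base given the
amino acid (17 of 20 amino acids; only Ser, Arg, Leu admit two first bases),
so conditioning on the downstream first base is almost deterministic. In the
idealized code where every amino acid fixes its first base, the expected
codon and dinucleotide counts of DCM-generated sequence equal the reference
counts exactly; the package's test suite verifies this identity exactly on
the restricted amino-acid alphabet and by Monte Carlo on sampled corpora.

Boundary conventions: the 3'-most codon of a whole gene is conditioned on
$b = \mathrm{T}$, the first letter of all three stop codons, and motifs are
never sought across the detached stop codon (this avoids arbitrariness in
the stop choice). A fragment with no known 3' context uses the ICM marginal
for its 3'-most codon — the paper-style rule ("use the base 3' of the
sequence") has nothing to point at, and marginalization is the
least-assumption choice. Both conventions are applied consistently to
probability evaluation, sampling, and the dynamic program, and are covered
by the enumeration tests.

## The dynamic program

Let $l$ be the motif length and
$\Delta = \lceil (l+2)/3 \rceil$ the *span*: the maximum number of codons
one occurrence can overlap (a 6-mer can straddle 3 codons, e.g. positions
2–7 of a 9-base window). We note that the floor-based expression
$\lfloor (l-1)/3 \rfloor + 1$ sometimes quoted for this quantity
undercounts exactly when $3 \mid l$; the ceiling form is the true maximum
over the three frame offsets, and the width of the DP context must be the
true maximum for the induction to be correct.

The induction runs 3' to 5', prepending one codon per step and maintaining,
for every codon context (the $\Delta - 1$ most recently placed codons; at
least one under the DCM so the neighbour's first base is known), the
sub-normalized distribution of occurrences counted so far. Prepending codon
$\alpha$ adds $\theta$ occurrences — those *starting* in $\alpha$, the
3'-to-5' mirror of counting occurrences ending in the newest codon — and
multiplies the slice by $p(\alpha \mid A)$ or $p(\alpha \mid A, b)$. Since
at most 6 codons are compatible with an amino acid there are at most
$6^{\Delta-1}$ contexts, and in practice far fewer, because only contexts
compatible with the amino acids are enumerated. Every codon's probability
is applied at the moment it is prepended, so when the 5' end is reached the
final distribution is simply the sum of the context slices. Correctness is
anchored to the definition: the test suite requires elementwise agreement
(within $10^{-9}$; observed agreement is at machine precision) with
brute-force enumeration over all synonymous sequences on hundreds of random
instances, for both models, with and without the optimizations below.

## Sparse regions

Most motifs are *forbidden* across most of a protein: a placement is
realizable only if each covered codon's constrained positions match some
synonymous codon, and these per-codon constraints are independent, so
realizability is a cheap per-placement test, not a search. Over random
amino-acid triples, fewer than 5% of 6-mers are realizable in any 3-codon
window (the acceptance script recomputes this: at most 192 distinct 6-mers
per triple, far below the $216 \times 4 = 864$ combinatorial bound). The
sequence is therefore decomposed into *independent regions*: maximal codon
stretches such that every realizable placement lies inside exactly one of
them. The induction runs per region and the region distributions are
convolved — identical to the unsplit computation (tested to $10^{-9}$), but
much faster because excluded codons need no convolution work at all.

Under the DCM a region's 3'-most codon needs a conditioning base from
outside the region. The package scans 3' until it reaches an amino acid
with a unique first base, the stop boundary, or the open sequence end, and
propagates the first-base distribution back through any intervening
Ser/Arg/Leu codons (a $\le 2$-state chain). One subtlety: if that scan would
reach a Ser/Arg/Leu codon *inside the next region*, the conditioning base
is correlated with that region's codon choices, and treating the regions as
independent would be wrong. In that case the two regions are merged and the
induction simply runs through the gap. The merge is rare, model-independent
and correctness-neutral; the oracle-equivalence suite exercises it with
Ser/Arg/Leu-enriched random proteins.

## Combining distributions

Distributions are dense double-precision arrays over counts $0..n$;
trailing structural zeros are trimmed at finalization. Convolution is
direct polynomial multiplication by default: at motif lengths 4–7 the FFT
route is not noticeably faster and occasionally produces slightly negative
coefficients from round-off. An FFT method (via `stats::convolve`) is
available as an opt-in; it clamps negative coefficients to zero and
rescales to the exact product of the input masses. Many distributions
(regions within a sequence, sequences within a dataset) are combined
smallest-first, the hierarchical schedule that keeps intermediate arrays
small; order-invariance is a tested property. No log-space arithmetic is
used: masses here never underflow at the problem sizes the package targets
(a documented limitation for genome-scale inputs, where tail probabilities
below ~1e-300 would flush to zero).

## Statistics and conventions

For an observed count $x$: `p_over` $= P(X \ge x)$ (inclusive, the
convention matching non-parametric shuffle counting), `p_under`
$= 1 - $ `p_over`, mean and z-score computed exactly from the distribution
(the ideal that infinite shuffling would estimate), and the count ratio
$x / \mathbb{E}[X]$, reported only when the mean clears a user threshold
(default 0) because low-expectation motifs make the ratio an outlier
magnet. Exact discrete p-values are super-uniform
($P(p \le t) \le t$), verified by enumeration. Raw p-values are never
adjusted silently; the exhaustive 6-mer scan prints the Bonferroni-style
threshold $4^{-6} \approx 2\times10^{-4}$ as a reference line.

Degenerate inputs are handled explicitly: a motif impossible for the amino
acids yields the point mass at zero (so `p_over = 1`, z and ratio
undefined); a point-mass null flags the z-score as `NA` rather than
dividing by zero; unseen $(A, b)$ cells fall back to the ICM conditional
and entirely unobserved amino acids to the uniform codon distribution
(optionally replaced by a user pseudocount), keeping every synonymous
re-encoding inside the support so exact p-values remain well defined.

## The synthetic test bed

No external data ship with the package; the test suite and the acceptance
script build everything. `synthetic_reference()` emulates the one feature
of real coding sequence this method exists for: contextual dinucleotide
bias at codon boundaries. It encodes uniform random proteins 3' to 5' with
log-normal per-amino-acid codon weights, depressing C-*ending* codons
(weight $\times$ 0.2) when the 3' neighbour starts with G. The depression
acts on the third codon base deliberately: the code fixes first bases given
the amino acid, so a first-base bias would be cancelled by renormalization,
whereas third-base context is exactly what marginal codon usage cannot
express. On such corpora ICM resampling inflates CpG by ~1.3× while DCM
resampling reproduces it to ~1%, a qualitative match to the behaviour
reported for mammalian references.

The insertion benchmark follows the published design at desk scale: 20
DCM-sampled sequences of 350 codons (3'-most codon conditioned on a stop),
into $0..15$ of which one copy of a 6-mer is overwritten at a random
position (redrawn if it would create a premature stop). With 64 randomly
chosen 6-mers and one trial each, the median exact p-value declines
monotonically with the number of inserted copies and crosses $4^{-6}$ at
roughly 9–10 copies under this synthetic null. Only the qualitative shape
is asserted: the published crossing point (6–7 copies) was obtained under a
human-trained null and is not reproducible from synthetic data.

What the synthetic corpus does *not* emulate: real amino-acid composition
(proteins are uniform over the 20 letters), codon-usage correlation with
expression, higher-order (> dinucleotide) context, and selection on real
motifs. Passing tests therefore demonstrate algorithmic exactness and the
dinucleotide-correction mechanism, not biological effect sizes.

## Problem sizes used by the test suite

Enumeration oracles run on proteins of up to 10 codons with synonymous
spaces capped at $2\times10^4$ sequences (200 random instances);
segmentation invariance on 100 proteins of 10–35 codons; the Monte-Carlo
preservation check on ~10^5 sampled codons; the insertion benchmark on 64
motifs × 20 × 350 codons. These sizes keep the whole suite around a minute
on one core while leaving every code path — both models, all boundary
conventions, the merge rule, both convolution methods — covered.

## Known limitations

* Only the standard nuclear genetic code; no alternative codes or
  selenocysteine.
* Equal-length k-mer sets only; a mixed-length motif should be evaluated
  per length and combined at the interface level.
* Nulls of order higher than amino acid + boundary dinucleotide are out of
  scope by design: they would absorb genuine short-motif signal into the
  null.
* Double-precision throughout; for inputs of hundreds of kilobases the
  extreme tails of the distribution may underflow.
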