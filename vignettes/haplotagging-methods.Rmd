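---
title: "Haplotagging long reads: model, error control, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotagging long reads: model, error control, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the scoring
model and its assumptions, the error model, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The scoring model

A phased VCF partitions heterozygous variants into *phase sets*: groups of
variants whose alleles are assigned consistently to haplotypes
$h_1, \dots, h_l$ ($l$ = ploidy; 2 for the diploid case the CLI targets,
though every function is written for general $l \ge 2$). For a read $r$
overlapping $n$ phased heterozygous SNVs of one phase set, let $b_r[a]$ be
the aligned read base at variant $a$ and $e_r[a]$ the error probability of
that base.

**Assumptions.** Sequencing errors are independent across sites, uniform
over the three wrong bases, and the variant set itself is correct — errors
in variant calling, phasing, and alignment are *not* modeled. A match to
haplotype $i$ at a site is observed with probability $1 - e_r[a]$ if the
read truly derives from $i$; a specific mismatching base requires an error
to one of three wrong nucleotides, probability $e_r[a]/3$.

With a single global error rate $\varepsilon$ the likelihood of
haplotype $i$ given $k_m$ matches and $k_{n-m}$ mismatches is multinomial
(`multinomial_prob_global()`):

$$P_{h_i} = \frac{n!}{k_{n-m}!\,k_m!}\left(\frac{\varepsilon}{3}\right)^{k_{n-m}}(1-\varepsilon)^{k_m}.$$

The default mode (`log10_multinomial_prob()`) generalizes this to per-base
error rates taken from the BAM quality string via the Phred inverse
$e = 10^{-q/10}$:

$$\log_{10} P_{h_i} = \sum_{a=1}^{n}\left[x_a \log_{10}(1-e_r[a]) + y_a \log_{10}\frac{e_r[a]}{3}\right] + \log_{10}\frac{n!}{k_{n-m}!\,k_m!},$$

with indicator $x_a = 1$ on a match and $y_a = 1$ on a mismatch to the
haplotype being scored. When the error rate is constant the two forms agree
exactly; the test suite checks this equivalence exhaustively for
$n \le 10$ at relative tolerance $10^{-12}$.

Uniform priors $\beta_{h_i} = 1/l$ then give *odds-style* posteriors and
likelihood ratios in which the focal term is excluded from the denominator:

$$P(r)_{h_i} = \frac{P_{h_i}\beta_{h_i}}{\sum_j P_{h_j}\beta_{h_j} - P_{h_i}\beta_{h_i}}, \qquad
LR_{h_i} = \frac{P(r)_{h_i}}{\sum_j P(r)_{h_j} - P(r)_{h_i}}.$$

The read's score is $\mathrm{LLR} = \log_{10} \max_i LR_{h_i}$ and the read
is assigned to the argmax haplotype. These denominators are odds against
the *other* haplotypes, not a normalization; a consequence worth knowing is
that for $l = 2$ the chain collapses to
$\mathrm{LLR} = 2\,(\log_{10} P_{best} - \log_{10} P_{other})$ — exactly
twice the raw log-likelihood difference. The package implements the odds
form as specified rather than "correcting" it, and a property test asserts
the diploid closed form on 1,000 random likelihood pairs.

### Labels

* **untaggable** — the read overlaps zero phased het SNVs (or every
  overlapped variant falls in a deletion/reference skip of the alignment,
  leaving no aligned base to observe). No information exists to tag it.
* **untagged** — the read is phaseable but two or more haplotypes tie
  within $10^{-9}$ in log₁₀ LLR, or the LLR is not *strictly* above the
  threshold (default 0), or the FDR filter removed it.
* **tagged** — everything else, labeled with the argmax haplotype.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `llr_threshold` | 0 | minimum LLR (log₁₀, strict) for tagging |
| `epsilon` | estimated | global error rate; mean of per-read BAM `de` tags when unset |
| `per_base_mode` | TRUE | per-base qualities vs. global ε in the likelihood |
| `use_coefficient` | TRUE | include the multinomial coefficient |
| `fdr` | 0 (off) | target empirical FDR for the error model |
| `tie_tol` | 1e-9 | LLR tie tolerance (log₁₀) |

## The error model

Haplotagging errors are driven by sequencing errors at the overlapped
variants. Treating each haplotagging decision as a Bernoulli trial that
fails with probability $\varepsilon/3$ — deliberately ignoring the number
of variants per read, a conservative simplification, since a read with $n$
variants has error probability on the order of $(\varepsilon/3)^n$ — the
error count across $N$ phaseable reads is negative-binomially distributed
with mean $N\varepsilon/3$. To control the FDR at level $f$, the
$\lfloor N(\varepsilon/3)(1-f) \rfloor$ lowest-LLR tagged reads are
relabeled untagged. `fdr = 0` is a disable sentinel (filter skipped), not
"remove all expected errors".

Two readings of the expected-count notation are possible
($N\varepsilon$ vs. $N\varepsilon/3$); the package resolves to
$N\varepsilon/3$, consistent with the stated per-read failure probability
$\varepsilon/3$, and exposes the $N\varepsilon$ reading via
`error_model_mean = "eps"` for sensitivity analysis.

By construction the filter only converts tagged reads to untagged, never
changes a surviving read's haplotype, never touches untaggable reads, and
removes nested sets as $f$ tightens — so FNR is non-decreasing and IHR
non-increasing as the FDR is tightened, which the acceptance suite checks
across three seeds. Ties at the cut are broken by read name for
determinism.

## The engine

Primary, non-duplicate, mapped BAM records are intersected with the
variant store (an interval index over the phased het SNVs); the aligned
base at each covered variant is recovered by walking the CIGAR
(deletions and reference skips yield no observation; insertions create
none). Reads spanning more than one phase set are scored only within the
phase set contributing the most observations — cross-phase-set likelihoods
are not comparable because haplotype identity is only defined within a
phase set — and a tie between phase sets leaves the read untagged. Output
records carry the full decision as BAM tags (`HP`, `PS`, `LL`, `NV`, `MC`,
`MM`, `EP`, `YT`) so every tagging decision can be audited retrospectively.

## Numerical choices

* All probability arithmetic in log₁₀ with log-sum-exp; factorials via
  `lgamma`. Nothing overflows even for reads covering hundreds of variants
  or posterior ratios of hundreds of orders of magnitude.
* Per-base error probabilities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$: a quality-0 base has error probability 1 and
  would otherwise contribute $\log 0$; clamping makes it merely
  (almost) uninformative, which is the right behavior for a base the
  sequencer itself disowns.
* The multinomial coefficient uses each *scored haplotype's own*
  match/mismatch split $(k_m, k_{n-m})$. For complementary diploid counts
  it cancels in the ratio; when a base matches neither haplotype the counts
  are not complementary and the coefficient matters.
* Missing base qualities (`*`) fall back to the global ε for every base of
  that read.
* Degenerate inputs: an empty observation set is the untaggable path, not
  an error; `posterior_log10()` refuses $l < 2$ (the excluded-term
  denominator vanishes); a VCF with no usable record is an explicit error
  naming the problem.

## The simulator: what it emulates, and what it does not

`simulate_diploid_dataset()` produces a uniform-random reference contig,
phased het SNVs at a configurable density (default 1/1500 bp,
approximating human heterozygosity of roughly 4–5 million sites per
genome), two haplotype consensus sequences, and error-bearing reads drawn
from both haplotypes. Its defaults state a MinION-like world: read lengths
with mean 25 kb and sd 20 kb truncated to [100 bp, 1 Mb]; per-read
accuracy mean 0.98 on [0.01, 1]; substitution:insertion:deletion error
proportions 23:31:46.

Where the emulated tool chain leaves a law unspecified, the package chose
once: lengths are gamma-distributed (moment-matched, then clipped — the
natural right-skewed law for fragment lengths); per-read accuracy is a
truncated normal with sd 0.02; insertions are single-base. Base qualities
are constant per read at the Phred equivalent of the read's realized error
rate, and the realized rate is written to the `de` tag so that ε
estimation is exercised end to end.

Reads are emitted directly as *pre-aligned* BAM: since only SNVs separate
the haplotypes, consensus coordinates equal reference coordinates, and the
error-injection trace yields the true CIGAR, so no external aligner enters
the test path and truth coordinates are exact. An optional flag emits
FASTQ for genuine end-to-end runs through `map_fastq()`/minimap2.

**What a green test does not establish.** The simulator has no alignment
errors, no reference bias, no chimeras or structural variation, no
variant-calling or phasing errors, uniform variant density, and one contig
with one phase set. Benchmarks on it therefore isolate the scoring model's
behavior given correct inputs; they do not certify performance on
biological data, where those unmodeled error sources dominate the residual
error rate.

**Stress configuration for rank-based tests.** At the default accuracy
(0.98) the engine makes on the order of a handful of errors per few
thousand reads — too few for a powered rank test. The test asserting that
errors concentrate at low LLR therefore uses a deliberately harsher world
(3 kb ± 2 kb reads at accuracy 0.78), sized so that the expected number of
wrong tags (≈ per-site wrong-haplotype conversion rate
$\varepsilon_{sub}/3$ times the single-variant read count) is well above
ten. This is a power consideration, not a tuned threshold: the null being
rejected does not depend on the chosen parameters.

## Evaluation definitions

Against simulation truth: a correct tag on a phaseable read is a TP; a
wrong tag on a phaseable read is an FP; a phaseable read left untagged (or
wrongly deemed untaggable) is an FN; an untagged/untaggable nonphasable
read is a TN. A nonphasable read that received a tag would be an FP — the
engine cannot produce one (it never tags without an observation), and the
suite asserts the count is zero. Derived rates are IHR = FP/phaseable,
FNR = FN/phaseable, recall = TP/phaseable. Precision–recall curves sweep
every distinct LLR as a threshold (ties enter together, making the curve
deterministic and invariant to monotone score transforms); PR-AUC is the
trapezoid over recall, anchored at recall 0 with the first precision.

## VCF rescue

Consortium phased VCFs are sometimes spec-noncompliant in ways that break
strict parsers: string PS tags, sample columns labeled `INTEGRATION`,
genotype fields not declared in FORMAT, and malformed indel records.
`rescue_vcf()` repairs these at the text level (below the level a
compliant parser can reach): PS strings are transliterated to integers by
concatenating a per-string ordinal with a two-digit chromosome number
(X→24, Y→25, M→26; other contigs get a deterministic fallback index and a
report), originals are preserved under a new `OPS` FORMAT tag, undeclared
genotype fields are dropped, non-SNV records are removed, and the output
is coordinate-sorted so it can be bgzip-compressed and tabix-indexed
directly. The ordinal-plus-two-digit-contig scheme keeps transliterated
IDs injective within a run and 32-bit safe on toy genomes.

## Known limitations

* Indels and structural variants are never used for tagging; only SNVs.
* Non-uniform priors are supported internally but deliberately not exposed.
* The CLI is validated for the diploid case; the model itself is
  $l$-general.
* The FDR filter ranks purely by LLR; at low LLR, true and false positives
  mix, so reducing the FDR always costs sensitivity.
* Reads spanning two phase sets use only the majority phase set; the
  minority observations are discarded rather than combined.
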