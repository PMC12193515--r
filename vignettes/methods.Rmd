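---
title: "Alignment-free haplotype phasing of exonic SNPs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free haplotype phasing of exonic SNPs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphase)
```

## The problem

Allele-specific expression and splicing studies work with heterozygous
*exonic* SNPs, and gain power when the alleles of several SNPs can be
assigned jointly to the two parental chromosome copies (haplotype
phasing). RNA-seq reads are natural evidence for this: a read that covers
two SNP positions and carries one specific allele of each links those two
alleles to the same physical molecule, hence the same haplotype.
Moreover, two exonic SNPs separated by long introns on the genome can sit
a few dozen bases apart on the spliced mRNA, so transcriptome reads often
connect SNP pairs that genomic reads of the same length cannot.

The usual route to such counts is spliced alignment, which is expensive,
must be tuned to tolerate two mismatches close together (the very signal
we are after), and is complicated by genes having many transcripts.
`kmerphase` avoids alignment entirely: everything a read can tell us
about a SNP is contained in the short windows of sequence around the SNP
position, and those windows can be precomputed from the transcriptome
annotation.

## The k-mer index

For each transcript, every window of length *k* that covers at least one
heterozygous SNP is enumerated on the spliced, mRNA-sense sequence
(minus-strand transcripts are reverse-complemented, and their SNP alleles
complemented, before substitution). Enumeration is repeated per
transcript because a SNP near a splice junction has different flanking
sequence in different isoforms. Within each window, the base at every
covered SNP position is substituted with each of the SNP's two alleles —
all \(2^m\) combinations for a window covering *m* SNPs, so that reads
supporting either phase configuration of close SNP pairs are
recognisable.

K-mers are stored 2-bit encoded (A=00, C=01, G=10, T=11,
most-significant-first in 5'→3' order), so a k-mer of the default length
k = 32 fills exactly one 64-bit word; R lacks an unsigned 64-bit type, so
words cross the R boundary as 16-digit hex strings while the bit-level
work is done in C++. Values are SNP *allele codes*: SNPs are sorted by
(chromosome, position, haplotype-0 base, id), the rank in that order is
the SNP index, and allele code \(2i + b\) identifies allele *b* of SNP
*i*. Because almost every k-mer covers exactly one SNP (two SNPs must be
within k − 1 bases to share a window), the index uses two maps: the main
map stores one packed integer per key — the smallest allele code shifted
left once, with the low bit flagging that more codes exist — and only
flagged keys have an entry holding the remaining codes in the alternative
map. This keeps per-key value storage at a single integer for the common
case.

## Reads, counting and error filtering

A read is split into adjacent, non-overlapping k-mers starting at offsets
0, k, 2k, …, plus one tail k-mer starting at L − k when the read length L
is not a multiple of k; these windows jointly tile every base of the
read, so any SNP inside the read lies in at least one query k-mer. Each
k-mer is looked up; retrieved allele codes are unioned over the read (set
semantics: one read, one vote per allele). Reads may come from either
strand, so when the forward pass of a segment retrieves nothing, the
reverse complement of the whole segment is processed instead; mates of a
pair are orientation-resolved independently and their code sets unioned,
treating the pair as a single read. If a read ends up supporting both
alleles of one SNP (possible only through a sequencing error at the SNP
site), that SNP is dropped from the read as physically inconsistent.

Sequencing errors otherwise produce k-mers that either miss the index
entirely or hit it at very low frequency. A first streaming pass counts,
for every read segment, how often each index key occurs among the
segment's query k-mers — using the same forward-first orientation rule as
the query pass, so the frequencies are exactly the queryable occurrences
— and keys observed fewer than `min_count` times (default 2, i.e.
singletons) are removed before counting. We deliberately resolve
orientation at segment level rather than per k-mer: re-splitting a
reverse-complemented segment shifts the k-mer grid whenever L is not a
multiple of k, so per-k-mer reverse-complement counting would leave some
queryable keys uncounted and the filter would then delete them even on
perfect data.

Counts are accumulated per *adjacent SNP pair*: within each gene, the
exonic SNPs are taken in genomic order and only consecutive pairs are
reported, because modelling longer haplotypes multiplies the
configuration space exponentially. A read whose resolved allele set
covers both SNPs of a pair increments exactly one cell of that pair's
2×2 matrix \(C\), indexed by the two allele bits; a read covering SNPs
*i* and *i + 2* but not *i + 1* contributes nothing (strict adjacency —
a deliberate, conservative choice that loses some long-read
information). A SNP exonic in two overlapping genes would be paired
independently within each gene.

## The statistical model

After the VCF is orientation-normalized (genotype `1|0` records have
their bases swapped so every record behaves as `0|1`), the *type-1*
configuration of a pair is "haplotype-0 allele with haplotype-0 allele",
i.e. agreement with the input phasing; *type 2* is the opposite
configuration. With

\[
H = \sum_k C_{k,k}, \qquad N = \sum_{i}\sum_{j} C_{i,j},
\]

*H* given the total *N* is modelled as Binomial(N, θ), where θ is the
probability of the type-1 configuration. A Beta(α, β) prior on θ with
α = β = 0.5 encodes the expectation that a real pair is unambiguously
phased — mass piles up near 0 and 1 — and yields the conjugate posterior
Beta(H + α, N − H + β). The posterior is summarised by its mean and by
the 95% *highest density interval* (HDI), the narrowest interval holding
95% of the posterior mass. A pair is called type 1 when the mean exceeds
0.75 **and** the HDI lower bound exceeds 0.5; type 2 by the mirrored
rule (mean < 0.25 and HDI upper bound < 0.5); anything else is
undetermined. Pairs with N = 0 are not emitted.

Two properties of this rule matter in practice:

* The narrowest-interval (not equal-tailed) HDI is essential: for
  unanimous counts the posterior density is monotone increasing, the HDI
  is \([Q(0.05), 1]\), and the smallest unanimous support that passes
  the rule is H = N = 3 (`qbeta(0.05, 3.5, 0.5)` ≈ 0.556 > 0.5, while
  N = 2 gives 0.431). An equal-tailed interval would demand four reads.
* The rule is mirror-symmetric: the result for (H, N) maps onto
  (N − H, N) with the mean reflected and type 1 ↔ type 2, so neither
  configuration is privileged.

`posterior_theta()` computes the conjugate posterior analytically by
default. An MCMC mode (JAGS, 4 chains × 1000 draws by default, one
deterministic RNG stream per chain) samples the identical
binomial-with-beta-prior model; since the model is exactly conjugate the
sampler adds only Monte Carlo noise, and it is retained as a cross-check
and as the natural extension point for non-conjugate variants.

### Numerical choices

* Analytic HDI: the width of \([Q(u), Q(u+0.95)]\) is minimised over
  *u* with `optimize()`, with the endpoints u = 0 and u = 0.05 always
  included as candidates so monotone densities get their exact boundary
  interval. For the U-shaped no-data posterior Beta(0.5, 0.5) the
  narrowest interval is not unique (both boundary-anchored intervals
  tie); the left-anchored one is returned deterministically.
* Sample HDI: the narrowest window over the sorted draws, with the
  candidate-width curve smoothed by a centred running mean (span 101)
  before the argmin. The raw minimum over hundreds of noisy candidate
  widths is biased narrow; smoothing removes most of that selection bias
  while leaving the noiseless limit unchanged.
* Degenerate inputs: H > N is a contract violation and errors; N = 0
  returns the prior; k-mer windows containing non-ACGT bases are skipped
  while the SNP itself is kept (its other windows still work).
* Ties in SNP ordering are broken by (position, haplotype-0 base, id)
  so index construction is fully deterministic; identical inputs give
  byte-identical outputs (the MCMC mode is seeded per pair).

## The simulator and what the tests show

`make_toy_reference()` and `simulate_reads()` generate a fully synthetic
diploid transcriptome with per-read truth. Defaults were fixed once to
mirror a realistic paired-end short-read regime: 76 bp mates, mean
insert 152.45 bp (so mates nearly abut and a fragment spans ~152
transcript bases), 30 fragments per transcript copy per haplotype, 1%
per-base substitution error, 2–4 exons of 120–250 bp per transcript,
introns of 80–400 bp, 2–3 heterozygous SNPs per gene, genes on both
strands, and a mix of `0|1`/`1|0` VCF genotypes to exercise
normalization. A long-read mode draws single-end lengths log-uniformly
between configured bounds. The genome doubles as haplotype 0, so after
normalization every simulated pair is type 1 by construction — which is
exactly what makes recovery measurable.

Validation is two-layered:

* **Exact layer.** On an error-free dataset whose reference carries a
  *collision-freedom certificate* at the test k (no substituted k-mer
  arises from two contexts, no transcript window equals the reverse
  complement of an indexed k-mer, no SNP-free window equals an indexed
  k-mer), the count matrices from the k-mer path must equal, cell for
  cell, those of an oracle that only walks the truth table (read →
  transcript, haplotype, covered intervals) and recomputes transcript
  offsets with independent arithmetic. This is run with `min_count = 1`
  so the error filter — a no-op on observed k-mers — does not interact
  with exactness; the filter itself is tested separately.
* **Stochastic layer.** At 1% error, depth 30 and k = 16 over five
  seeds, ≥95% of pairs with N ≥ 3 must classify type 1 with zero type-2
  calls. Unit and property tests use 3–20 genes; the heavier acceptance
  checks use 20 genes (exact layer) and 5 × 50 genes (stochastic layer),
  sizes chosen so the whole suite runs in minutes on one core.

What passing these tests does *not* show about real data: the simulator
has no indels (the k-mer approach has no indel tolerance by design), no
base-quality structure, no allelic expression imbalance, uniform
coverage along transcripts, and SNP-free collision-free genomes of toy
size. On a real transcriptome, repeated sequence can make one k-mer
genuinely ambiguous between loci; such cross-context keys are merged by
code-set union, and the frequency filter plus the requirement that a
pair be supported at *both* SNPs limit, but do not eliminate, the
resulting leakage. Results on repetitive gene families should be read
with that caveat.

## Design decisions that were genuinely open

* **Coordinates** are 0-based half-open everywhere internally,
  converted only at the GTF/VCF boundaries (both 1-based inclusive on
  disk), eliminating a class of off-by-one ambiguity.
* **Strandedness**: the index lives purely in mRNA-sense space; since
  every read is queried in both orientations anyway, indexing both
  strands would double memory for no information.
* **Mixed-haplotype substitutions**: all \(2^m\) allele combinations of
  a multi-SNP window are indexed, not just the two pure-haplotype ones —
  otherwise type-2 evidence inside one k-mer would be invisible and the
  posterior could never find against the input phasing.
* **"First" allele code** in the main map is the smallest, a fixed
  deterministic choice.
* **Forward-first orientation**: if the forward pass retrieves anything
  at all, the reverse complement is not consulted.
* **Index serialization** uses an RDS dump of the two maps (sorted
  key/value arrays), the SNP table and the pair list — version-stable
  and idiomatic for an R package — rather than a bespoke binary layout.
* **CLI**: `index`, `phase` and `simulate` subcommands are exported R
  functions (`cmd_index()` etc. plus `main()`) with a thin installed
  launcher, so the shell interface and the programmatic interface are
  the same code.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `k` | 32 | k-mer length (bases); 32 fits one 64-bit word and is long enough for unique matching in large transcriptomes. Tests use 16 on toy genomes. |
| `min_count` | 2 | minimum observed k-mer frequency; 2 eliminates singleton (error) k-mers |
| `alpha`, `beta` | 0.5, 0.5 | prior Beta shapes for θ; favours decisive phasing |
| `mass` | 0.95 | HDI probability mass |
| `method` | analytic | posterior computation; `mcmc` uses JAGS, seeded |
| `draws`, `chains` | 1000, 4 | MCMC budget |

## Known limitations

Indels and structural variants are out of scope (no liftover either);
SNP-dense regions with m > 12 SNPs in one window are refused rather than
enumerated; pairs are never chained into longer haplotype blocks; there
is no multiple-testing correction across pairs; and phasing power is
bounded by SNP density and the completeness of the transcript
annotation — SNPs near unannotated splice junctions will lose some of
their covering k-mers.
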