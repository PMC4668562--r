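---
title: "Methods: structural annotation and comparative evolution of LTR retrotransposons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation and comparative evolution of LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices and limitations. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The element model

An intact LTR retrotransposon is modelled as
`TSD + LTR + internal + LTR' + TSD`: two direct long terminal repeats
flanking an internal region, the whole insertion flanked by a 4–6 bp
target site duplication created at integration. Solo LTRs — the product
of intra-element unequal recombination — are a single LTR with (ST) or
without (SnT) a TSD; intact elements likewise split into IT (with TSD)
and InT. "Complex" loci carry three or more alternating LTR/internal
segments under one outer TSD pair. Coordinates are 1-based inclusive
throughout, the native convention of R/Bioconductor ranges and of GFF3;
a single convention with no boundary conversion is the whole point, and
the GFF3 round-trip identity is tested.

## Structural detection

Direct repeats are found by exact k-mer seeding (default word 15) on
shared diagonals, chained (gap ≤ 300 bp) and extended by an X-drop scan
(match +1, mismatch −2, drop 8). Candidates must satisfy LTR length
100–3000 bp, element span 300 bp–15 kb and LTR–LTR identity ≥ 0.80 — all
configurable; these bounds are declared defaults, not inferred from any
reference tool. Where candidates share LTR copies, loci with ≥ 3 copies,
spacers ≤ 3 kb and one outer TSD pair become complex calls; other
components decompose into non-overlapping pairs, TSD-validated pairs
first. A periodicity pass catches the complementary failure mode: a
locus with identical internal spacers matches itself on a ladder of
diagonals `{P, 2P, …}`, which collapses pairwise candidates; the ladder
inside a called element is re-read as `n = max multiple + 1` LTR copies.

**TSD policy.** At the nominal boundary, L-mers immediately left and
right are compared for L = 6, 5, 4, first success wins; one mismatch is
allowed for L ≥ 5, none for L = 4 (a lone mismatch in a 4-mer means 75%
identity, indistinguishable from chance). Because X-drop extension
overshoots a repeat boundary whenever flanking bases match by chance
(≈ 25% of ends by ≥ 1 bp), a jittered search then looks for an *exact*
duplication within ± 8 bp, longer L first, with per-length Manhattan
caps on the total boundary shift (6: 8, 5: 4, 4: 2) and one-axis offsets
admitted to the full radius for L ≥ 5. The caps were calibrated on
synthetic IT/InT mixtures (4 seeds × 50 elements) to hold the chance-TSD
pickup on TSD-less elements near 7–9% while keeping IT recall ≈ 0.98;
both error directions remain and are visible in the evaluation block of
any synthetic run. Overlapping calls are resolved TSD-bearing first,
then identity, length, leftmost — a chimeric join of two neighbouring
same-family insertions can beat the true pairs on identity but never has
a TSD.

Truncated fragments without structurally defined termini are not called;
the homology stage reports only solo-LTR hits at ≥ 80% identity over
≥ 80% of a library LTR. Intact-without-TSD elements are already found by
the structural search (which never consults TSDs), so the homology stage
does not derive InT candidates separately.

## Families, superfamilies, lineages

Families are single-linkage components under the 80-80-80 rule (local
alignment of LTRs: ≥ 80% identity over ≥ 80% of the shorter LTR, ≥ 80
aligned bp). LTRs — not internal regions — are the linkage substrate so
that solo LTRs are assignable; this is a documented choice, not a claim
about any published pipeline. Consensus sequences are majority-rule
columns of a star alignment to the longest member, ties alphabetical.

Superfamilies come from the domain order in the six-frame translation of
the consensus internal region, scored against bundled INT and RT core
peptides by near-ungapped local alignment (BLOSUM62, heavy gap
penalties; a hit needs ≥ 40% of the motif's self-score): INT before RT
is Copia, RT before INT is Gypsy. Motif-free families fall through to
structural rules: internal > 4 kb → LARD; internal < 1 kb and element
< 2.5 kb → TRIM (the < 1 kb / < 2.5 kb thresholds are this package's
concretization of "very short internal, very small element";
configurable). The motif files and the 13 lineage reference RT sequences
are *synthetic stand-ins* (`*_synthetic.*` under `inst/extdata/`),
written around the canonical conserved blocks; the synthetic generator
embeds these same motifs, so classifier tests are construction-oracle
tests, and a user with access to curated references can drop in a
replacement FASTA with the same `name|superfamily` headers. Lineage
assignment is nearest-reference by Jukes–Cantor distance among
same-superfamily references, capped at 1.5, ties broken by lexicographic
reference id.

## Dating

LTR–LTR divergence uses a global affine-gap alignment (match +1,
mismatch −1, gap open −5, extend −1 — invented defaults, exposed);
columns containing a gap or N are excluded so `p` is a substitution
proportion, and `K = −(3/4)·ln(1 − 4p/3)` (Jukes–Cantor; Kimura
two-parameter behind a flag — the model choice for LTR distances is a
documented default, matching the model used for tree building). Age is
`T = K/(2r)` with `r = 1.3 × 10⁻⁸` per site per year; "aged 0 My" means
`p = 0` exactly. Age histograms (0.5 My bins) report Pearson r for
count-vs-midpoint (linear diagnostic) and log-count-vs-midpoint
(exponential diagnostic).

## Chromosomal distribution

Chromosomes are tiled into fixed windows (1 Mb, 100 kb or 50 kb tiers);
the trailing partial window is dropped, elements and genes are assigned
by midpoint, and windows with N fraction > 0.5 are ineligible (the rule
is stated for 1-Mb windows as "> 0.5 Mb N"; the proportional reading is
applied to the smaller tiers). The randomization test re-places the
observed genome-wide count uniformly over eligible windows `n_sim`
times; per-window two-sided empirical p is
`(1 + #{|sim − E| ≥ |obs − E|}) / (n_sim + 1)` and the summary is the
fraction of windows with `p ≥ α` ("consistent with random"). The uniform
placement null and the `|count − expected|` two-sidedness are this
package's interpretation; per-window p-values are reported uncorrected
by default (a Benjamini–Hochberg flag exists) to match per-window
reporting practice. Marey-map local rates: markers are reduced to the
longest non-decreasing cM series, and the rate at a window midpoint is
the least-squares slope over the nearest 7 markers, clamped at 0, in
cM/Mb. Correlations between per-window quantities are Pearson r with a
10,000-resample percentile bootstrap.

## Orthology between two genomes

For each TSD-anchored element with ≥ 50 bp flanks whose two 100-bp
junctions (50 bp flank + 50 bp element terminus) are unique in its own
genome, both junctions are searched in the partner genome (both strands,
≥ 90% identity over ≥ 90 bp, seed-and-verify). `orthologous` requires
exactly one qualifying locus per junction, on the same sequence and
strand, within twice the element length (+ 200 bp slack) — the spacing
consistency rule is this package's concretization of "unique best
match". `absent` means the 50-bp flank halves are present but the
element-side halves are not (the empty ancestral site); anything else is
`ambiguous`. For orthologous intact elements the intra-element
(LTR5–LTR3, each genome) and inter-genome (matched LTRs) divergences
feed paired two-sided t-tests; insertions predating the species split
show intra > inter. Divergence-time estimates take the modal 0.01-wide
bin of the K (or gene Ks) distribution, ties to the lower bin
(conservative: older bins span more time), converted by `T = K/(2r)`.

## Ka/Ks

Nei–Gojobori (1986) with Jukes–Cantor correction replaces codeml-style
ML: it is fully specified, dependency-free and exactly testable against
brute-force path enumeration. Site counting treats mutations to stop
codons as nonsynonymous (so S + N = 3 × codons holds identically);
difference counting averages synonymous/nonsynonymous steps over all
orderings of a codon pair's differing positions, excluding orderings
that pass through a stop codon unless all do. `ω = Ka/Ks` is undefined
at Ks = 0. At desk-scale divergences (Ks ≈ 0.02, 300 codons) per-pair
Sd is a small count, so per-pair ω ratios are noisy and upward-biased;
recovery tests therefore check mean Ks and the pooled ratio
mean(Ka)/mean(Ks).

## The synthetic generator

`plant_spec()` fixes the study conditions: counts per structural
category (including InT/SnT, which extend the three planted classes so
that all four categories exist with ground truth), LTR length 200–600
bp, internal 2–6 kb for autonomous families (TRIM: LTR 150–300 bp,
internal 0.3–0.8 kb; LARD: internal 4.2–6 kb, motif-free), TSD length
4–6, target LTR–LTR divergence K (default 0.02, the order of the
between-LTR divergence seen for young plant elements), a superfamily
profile, and a mandatory seed. Families are independent random
ancestors; members carry 1% family drift; LTR aging is one-sided uniform
substitution (inverse-JC per-site probability; indel rate 0 by default
so realized K stays measurable), and the manifest records the realized
divergence of every multi-LTR element. Insertion sites are uniform over
non-N space with a minimum separation; complex loci are planted from
TRIM families. `diverge_genomes()` retains each insertion with the given
probability, excises the rest cleanly (restoring the single ancestral
target site), and applies point substitutions *independently to both
genomes*, so inter-genome divergence is twice the per-genome level — the
function returns both mutated genomes, since the post-split model cannot
be honoured while returning only one. Gene pairs plant Poisson numbers
of stop-avoiding synonymous and nonsynonymous single-nucleotide changes
calibrated to expected NG86 (Ks, ω·Ks).

What the generator does not emulate — nested insertions, indels in aged
LTRs, recombination-mediated solo formation, assembly gaps inside
elements, GC heterogeneity — bounds what green tests show: detection and
recovery results certify the machinery on clean insertions at the stated
divergences, not performance on degraded real assemblies, where the
published pipelines also fell back to manual inspection.

## Problem sizes and determinism

Test-suite problem sizes are chosen as the smallest that make each
property sharp: detection recovery on a 5-Mb genome with 60 planted
elements; age recovery at K* ∈ {0.005, 0.01, 0.026, 0.05} with 50
elements per level; randomization calibration on 400 windows with 2,000
simulations; orthology on a 3.5-Mb genome pair at 2% divergence with 60
elements; 1,000 codon-pair cases against the NG86 enumeration oracle;
100 random additive 6–10-taxon matrices for NJ; 100 seeded forward
simulations (33 elements each, insertion 3 Mya, split 1 Mya) for the
intra/inter contrast. Every stochastic stage takes a seed derived
deterministically from one master seed (`derive_seed()`), and identical
configurations reproduce reports exactly.

## Known limitations

- Boundary placement inherits the intrinsic ±few-bp ambiguity of repeat
  ends; category confusion between IT/InT and ST/SnT at the measured
  single-digit percentage rates is the visible consequence.
- Family linkage on LTRs only will merge families whose LTRs converged
  and split families with diverged LTRs but conserved internal regions.
- The homology scanner reports only 80/80 solo hits; heavily truncated
  solos are invisible by design.
- NG86 underestimates Ks relative to ML methods at high divergence or
  strong codon bias; at the desk-scale divergences tested the
  within-15% recovery bound absorbs the difference.
- NJ trees from pairwise (not multiple) alignments perturb long-branch
  placements; lineage assignment is nearest-reference and does not
  depend on tree topology.
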