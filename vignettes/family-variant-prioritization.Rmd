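---
title: "Family-based variant prioritization: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based variant prioritization: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvar)
```

## The problem

In a cancer family carrying a known predisposing germline allele (here the
motivating case is a BRCA1 founder-mutation breast-cancer family), exome
sequencing of blood DNA from affected and unaffected relatives yields tens
of thousands of variant calls per person, almost all of them ordinary
population polymorphism or family-private neutral variation. The analytic
question is which few variants are (i) confined to the affected members,
(ii) rare or absent in population catalogs, (iii) predicted to damage the
encoded protein, and (iv) — using two-generation structure — attributable
to maternal germline transmission versus de novo origin in a daughter.
`famvar` implements that analysis as a reusable, fully tested pipeline
over standard formats (VCF, PED, BED, tab-separated annotation tables).

Everything operates on a *presence model*: genotypes collapse to
carrier / non-carrier on entry. Zygosity, phasing and genotype likelihoods
are deliberately out of scope — the family-level set logic (who shares
what with whom) is the object of study, and a hemizygous male chrX call
counts simply as "present".

## The filter cascade

Let $P(v, s) \in \{0, 1\}$ be presence of variant $v$ in sample $s$ after
caller consensus. The cascade applies six restrictions in order:

1. **Caller consensus.** $P = \bigwedge_c P_c$ over callers $c$
   (intersection, default) or $\bigvee_c P_c$ (union). "Called by both
   engines" is read as concordance; the union reading stays available via
   `filter_config(caller_mode = "union")`.
2. **Unaffected subtraction.** Drop $v$ if any control carries it, and
   also if no affected member carries it. Controls are an explicit
   `control_ids` argument rather than "all unaffected members": in the
   motivating family one prioritized variant is carried by an unaffected
   male relative, so a strict all-unaffected subtraction cannot reproduce
   the published set (see *Fixture reconstruction* below).
3. **Functional class.** Keep nonsynonymous SNVs, splicing, stop gain,
   stop loss; drop synonymous and unclassified.
4. **Rarity.** Keep $v$ iff it has no catalogued MAF (novel) or
   $\max_\text{catalog} \mathrm{MAF}(v) \le 0.001$. An absent MAF is
   *absence of evidence*, never frequency zero.
5. **Deleteriousness.** Stop gain/loss and splicing variants pass
   unconditionally. A nonsynonymous variant passes iff SIFT $< 0.05$
   (its damaging band) **or** PolyPhen-2 HumVar $\ge 0.447$ (the lower
   edge of "possibly damaging"). The published banding gives the two
   cut-offs; the OR-combination ("either program or both") is taken
   literally. A nonsynonymous variant with both scores missing fails
   conservatively, with a warning.
6. **Paternal removal.** For each sequenced father, any variant he shares
   with one of his daughters is cleared *in that daughter* (it is a
   paternal transmission, hence neither maternal-germline nor de novo);
   a variant left present only in the father is dropped. Presence in
   samples who are not his daughters is untouched.

An optional seventh stage restricts to variants whose
`sanger_confirmed` annotation flag is `TRUE`; confirmation status is only
ever consumed, never computed.

Every stage is a restriction, so the surviving set shrinks monotonically;
`run_cascade()` returns a per-stage audit (in/out counts and removed
keys). The restriction stages commute — a test on the bundled fixture
verifies that permuting stages leaves the final set unchanged — so the
published order matters only for the audit's intermediate counts.

## Inheritance classification

After paternal removal, presence of $v$ in daughter $d$ with mother $m$
admits exactly two origins:

$$\mathrm{label}(v, d) = \begin{cases}
\text{germline} & P(v, m) = 1 \\
\text{de novo} & P(v, m) = 0
\end{cases}$$

`classify_pair()` treats residual father–daughter sharing as a
precondition violation (error), not a third label. At the pair level the
germline count deduplicates across daughters — the number of *distinct*
variants present in the mother and at least one daughter — while de novo
events are counted per daughter. This, and only this, convention
reproduces the published pair counts: a variant carried by the mother but
neither daughter contributes nothing.

The dichotomy assumes complete observability (no allele dropout). The
simulator's `dropout_rate` knob exists to probe robustness, but no error
model is fitted or claimed.

## Mutation spectrum and the exact test

`classify_titv()` partitions the 12 possible substitutions into 4
transitions (A↔G, C↔T) and 8 transversions, strand-symmetrically.
`titv_stratified()` reports counts and the Ti/Tv ratio per recurrence
stratum (all variants; "common" = carried by ≥ 2 affected members;
"individual" = a single carrier), with the ratio rounded **half-up** to
one decimal to match the published presentation (base R's half-even
`round()` would print 0.25 as 0.2); raw counts always accompany the
ratio, and a stratum without transversions reports `NA`.

`fisher_exact()` is an authored hypergeometric enumeration, not a wrapper:
all tables with the observed margins are enumerated, point probabilities
are computed via `lchoose()` in log space, and the two-sided p-value is
the point-probability (Fisher) definition — the sum over tables whose
point probability does not exceed the observed one, with a $1 + 10^{-7}$
relative tolerance against floating-point ties (the same guard the
reference implementations use). The upper-tail one-sided value is
reported alongside so either convention can be inspected. The test suite
proves agreement with a direct brute-force oracle on *every* 2×2 table
with total ≤ 30 and with `stats::fisher.test()` on random tables.

A note on the motivating family: the common-versus-individual Ti/Tv table
(9/3 vs 5/6) gives a two-sided exact p ≈ 0.214 under any standard 2×2
construction. The originally reported p = 0.009 cannot be reproduced from
the printed counts and is therefore not an acceptance quantity; the
enumeration-oracle properties stand in its place.

## Interval context

Interval tracks (chromosomal fragile sites, structural-variation regions,
repeats) are stored 1-based and closed on both ends — the convention in
which the source tables print their bounds — and BED I/O converts at the
boundary (BED being 0-based half-open). Membership is point-in-interval
with both ends inclusive; when intervals overlap, the first covering
interval in track order supplies the label. Overlap uses
`GenomicRanges::findOverlaps()`, checked in tests against an independent
naive linear scan.

## The synthetic family generator

`simulate_family()` states a small world and samples from it:

| parameter | default | meaning |
|---|---|---|
| pedigree | 10 members | 4 founder sisters (3 affected), 2 marry-in fathers, 3 affected daughters, 1 unaffected son |
| `n_founder_rare_deleterious` | 10 | variants seeded heterozygous in one affected founder each |
| `denovo_mean` | 3 / child | Poisson; of the order of the motivating family's observed burden (9 events over 3 daughters); no population-scale realism claimed |
| `n_common_background` | 50 | catalogued polymorphisms, MAF ~ U(0.01, 0.5), founder genotypes Hardy–Weinberg |
| `transmission_prob` | 0.5 | per-heterozygous-parent transmission per meiosis |
| `dropout_rate` | 0 | per-call false-negative probability |
| `caller_fn_rates` | 0, 0 | two pseudo-callers ("varscan", "gatk") to exercise consensus |

Annotation scores are spiked so truth-deleterious variants satisfy the
SIFT/PolyPhen OR-rule (≈ 10% are scoreless stop gains, which pass
unconditionally) and background variants fail it *and* carry a catalogued
MAF above the rarity threshold — so each background variant is removed
for at least two independent reasons, keeping the noiseless-recovery
property insensitive to any single stage.

Design choices where the design was open: variants are placed on
autosomes only (sex-chromosome transmission rules would be dead code in
the default world, and the pipeline treats chrX keys as ordinary
presence); de novo events are generated only for members with at least
one parent in the pedigree, since for founders they would be
indistinguishable from founder variants; emitted VCF genotypes are 0/1 or
1/1 according to the simulated allele count and collapse back to presence
on read.

What a green simulator test establishes: with `dropout_rate = 0`, for any
seed, the cascade's final set equals the truth set of deleterious
variants carried by ≥ 1 affected member and no control, and every
inheritance label matches truth (tested over 20 seeds). What it does
**not** establish: behaviour under genotyping error, linkage
disequilibrium, recombination, mosaicism, or realistic read-level noise —
none of which the generator models.

## Fixture reconstruction (what ships in `inst/extdata`)

The bundled family fixture encodes the motivating study's printed
result tables as plain text. Two caveats are intrinsic to the source and
are carried, not hidden:

* The printed sharing tables and the per-variant family-frequency column
  are not mutually consistent for three variants. The full-family
  presence matrix (`family_presence_synthetic.tsv`) is reconstructed so
  that the frequency column and the sister-sharing patterns hold
  (frequency wins on conflict); the mother–daughter tables are encoded
  verbatim in a separate pair fixture (`pair_presence_synthetic.tsv`),
  and each summary is computed from the fixture that authoritatively
  describes it. Hence `_synthetic` in the filenames.
* Two variants appear in the generation-pair tables but not in the final
  set of 23; they ship only in the pair fixture.

Six additional synthetic background variants (`SYNBG1`–`SYNBG6`) are
present in the full-family matrix solely so that every cascade stage
removes at least one variant and the audit trail is non-trivial. The
structural-variation and repeat tracks use synthetic ±1 kb / ±500 bp
windows around the printed positions (the source prints membership, not
bounds); the fragile-site track uses the printed interval bounds
verbatim.

## Numerical conventions

* Ti/Tv ratios: half-up rounding to one decimal; `NA` when the
  denominator is zero.
* Exact-test tie handling: relative tolerance $10^{-7}$ when comparing
  point probabilities.
* Interval membership: closed on both ends, first-hit label on overlap.
* Variant keys: `chr`-prefixed chromosome dialect, upper-case alleles,
  1-based positions; normalization is idempotent; indels pass through as
  written (no left-alignment — the motivating data are SNVs).
* Randomness: `simulate_family()` is a pure function of its `sim_config`
  (including the seed); the ambient RNG state is saved and restored.

## Known limitations

* Presence-only model: no zygosity-aware checks (e.g. Mendelian
  inconsistency detection) and no genotype-likelihood de novo calling.
* `control_ids` must be chosen by the analyst; the package does not
  decide which unaffected members are appropriate controls (penetrance
  judgments are scientific, not mechanical).
* Multi-allelic records are split per alternate allele without claiming
  fidelity to any particular caller's convention.
* The deleteriousness rule consumes SIFT/PolyPhen-2 scores; it never
  computes them.
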