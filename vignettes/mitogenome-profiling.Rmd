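---
title: "Profiling circular mitogenomes: organization, composition, codon usage and ka/ks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling circular mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoprofile)
```

## Scope and model

Insect mitochondrial genomes are compact circular molecules of roughly
16 kb carrying 13 protein-coding genes (PCGs), 22 tRNAs, 2 rRNAs and one
AT-rich control region, distributed over the heavy (H) and light (L)
strands. The descriptive stage of a mitogenome study asks four questions,
and `mitoprofile` answers each with explicit, testable arithmetic:

1. **Organization.** How tightly are genes packed? For adjacent features in
   coordinate order (wrapping last-to-first on a circle) the junction gap is
   `start_downstream − end_upstream − 1`: negative values are overlaps,
   positive values intergenic spacers. All coordinates are 1-based inclusive
   (GenBank convention); an origin-spanning feature has `end < start` and
   its span is computed modulo the genome length.
2. **Composition.** Strand asymmetry is summarized by
   `AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)`, computed for
   the whole genome, the concatenated sense-strand PCGs, each codon
   position, and the tRNA/rRNA classes.
3. **Codon usage.** Relative synonymous codon usage is
   `RSCU = n · c / Σ_family c`, the observed count divided by the count
   expected under uniform usage within the codon's synonym family of size
   `n`, under the invertebrate mitochondrial genetic code (NCBI
   translation table 5: `AUA` = Met, `UGA` = Trp, `AGR` = Ser, stops only
   `UAA`/`UAG`, hence 62 sense codons and an 8-member Ser family).
4. **Selective pressure.** Pairwise `ks` and `ka` follow the
   Nei–Gojobori (1986) counting method — the algorithm behind the ka/ks
   output of classical population-genetics software such as DnaSP — with
   the Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)·p)`.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `code_id` | 5 | NCBI genetic code; 5 is the invertebrate mitochondrial code. Overridable everywhere. |
| `include_stops` (composition) | `TRUE` | whether PCG composition rows include the (complete or incomplete) stop codon. Published composition tables rarely state this; totals consistent with full annotated CDS lengths imply inclusion, so that is the default, exposed as a switch. |
| `exclude_stop_mutations` (NG86) | `TRUE` | mutations creating stop codons are removed from site denominators and pathways through stops are discarded — the common NG86 convention; a toggle is provided. |
| `reference` (`taxon_mean_rates`) | `NULL` | per-taxon means are over **all** pairwise comparisons by default; a designated-reference mode is available because published per-species tables rarely state their averaging protocol. |

Two biological edge cases are treated as data, not errors: nonstandard
start codons (e.g. the `CGA` start of `cox1` in many beetles) are reported
with a conformity flag, never "corrected"; and truncated stop codons (`T`
or `TA`, completed by polyadenylation, as in `cox2`) are classified as
incomplete stops and excluded from codon counting.

## Numerical choices

* Junction arithmetic is integer-exact; the largest-spacer tie is broken by
  first occurrence in genome order.
* The control region takes part in junction computation (the annotation
  tiles the full circle) but is excluded from strand counts, which cover
  the 37 genes only. Reported overlap/spacer ranges are over whatever
  junctions exist, including those flanking the control region.
* Skews are undefined (NA, flagged) when the denominator is zero; ambiguous
  bases (`N` runs from partial control regions) are excluded from all
  numerators and denominators so an unsequenced gap cannot bias
  composition.
* Displayed percentages are rounded **half-up** to one decimal to match the
  convention of published composition tables; full precision is retained
  internally.
* Pathway averaging enumerates the `k!` substitution orderings per codon
  pair (`k ≤ 3`). If *every* ordering passes through a stop codon the
  average falls back to all orderings rather than erroring, so one
  pathological pair cannot invalidate a whole gene comparison.
* `ps ≥ 3/4` (saturation) makes `ks` undefined; such pairs are excluded
  from per-taxon means and counted, not raised.
* `ka/ks` is reported as NA when `ks = 0` (division by zero is never
  performed).

## What the synthetic generator emulates — and what it does not

`generate_genome()` reproduces the *stated world* of a typical carabid
mitogenome: the ancestral insect gene order with 37 genes + control region,
the published lengths, strands and junction gaps (29 bp of overlap in 11
junctions, 116 bp of spacer in 16 positions by construction), genome-wide
A+T of 0.804, in-frame PCGs with annotated start/stop codons and no
internal stops. Because stop codons are AT-rich, rejecting them while
sampling codons depresses realized A+T below the target; the generator
inverts this bias analytically (solving `E[A+T | not stop](p') = target`
for the protein-coding regions), so the realized genome-wide A+T stays
within the binomial noise band (±0.01 at 16.6 kb) of the target.

It does **not** emulate: real codon-usage profiles (bases are sampled
independently within codons, so RSCU rankings of synthetic genomes are
*not* comparable to real ones), tRNA/rRNA secondary structure, indels,
rearrangements, or position-specific composition gradients. A green test
on synthetic data therefore establishes the *arithmetic* of the pipeline,
not the biology of any particular genome.

`evolve_cds()` evolves tips independently from one ancestor (a star tree):
proposed single-base changes are uniform over positions and bases,
accepted with probability 1 (synonymous) or ω (nonsynonymous), and
rejected if they create a stop. Under uniform proposals the per-site
synonymous and nonsynonymous proposal rates are equal, so the NG86
estimate of ka/ks converges on ω at low divergence. Defaults (300 codons,
6 taxa, 0.25 proposals per codon per branch, ω = 0.1) put pairwise
synonymous divergence near the low end of real mitogenome comparisons,
where the proportion-based estimator is near-unbiased; at high divergence
NG86 is known to compress distances and no recovery guarantee is made.

## Design decisions taken where the design was open

* **Published organization tables as input.** The bundled *Amara aulica*
  table (GenBank MN335930) is annotation-only; its `OVL/ITS` column is
  retained for cross-checking but every junction value is recomputed from
  coordinates — printed summaries are outputs here, never inputs.
* **Strand vocabulary is H/L**, matching mitogenome literature; GenBank
  `complement()` maps to L. The control region carries no strand.
* **tRNA labels are not reconciled**: a row labelled `trnV(tac)` with
  anticodon column `UGC` keeps both verbatim (`label` vs `anticodon`),
  since deciding which is right is curation, not parsing.
* **NG86 rather than an ML codon model** is the one defensible
  reconstruction of "ka/ks as computed by DnaSP v5"; ML dN/dS is a
  non-goal.
* **The nucleotide sequence of MN335930 is not redistributed.** Checks that
  need it (whole-genome skews of 0.025/−0.179, the top-5 codon ranking)
  look for a user-fetched `extdata/MN335930.fasta` and fail with an
  explanatory message otherwise; everything derivable from the printed
  coordinate table runs offline.

## Known limitations

* The GenBank reader covers the mitogenome subset only (no `join()`
  locations, no qualifiers beyond `/gene`, `/product`, `/anticodon`).
* Only adjacent-pair overlaps are summarized, matching the single OVL/ITS
  column of organization tables; nested or three-way overlaps are visible
  to the audit oracle but not aggregated.
* Per-taxon mean ka/ks across a 49-genome alignment depends on an
  averaging protocol that published tables usually leave unstated; results
  here are reproducible but not guaranteed to match any specific published
  per-species table.
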