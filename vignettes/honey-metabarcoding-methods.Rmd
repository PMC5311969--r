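---
title: "Methods: honey DNA metabarcoding from reads to foraging statistics"
author: "honeyforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: honey DNA metabarcoding from reads to foraging statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(honeyforage)
```

## The problem

Honey contains pollen and other plant debris from the flowers that honey
bees visited. Sequencing a universal plant barcode marker (such as the
chloroplast *rbcL* region) amplified from honey-derived DNA, and matching
the reads against a taxonomically annotated reference library, yields a
semi-quantitative picture of which plants each colony foraged on. Paired
with a floral survey of the landscape around the apiary, it supports
use-versus-availability questions: how many of the genera in flower did the
bees actually use, did detections track flowering phenology, and were the
dominant forage plants native or horticultural?

`honeyforage` implements that pipeline end to end: paired-read merging, a
local-alignment search with hierarchical taxonomic assignment, a regional
checklist filter, composition and diversity summaries, survey joins, and
the small-sample statistics the design calls for. A synthetic-data
generator with known ground truth makes every stage testable offline.

## Read processing

Reads arrive as 2 x 300 bp mate pairs spanning an amplicon of roughly
450-600 bp, so the mates overlap in the middle.

**Quality trimming** is a 3' windowed trim: blocks of `window` bases
(default 4) anchored at the 3' end are removed while their mean Phred
quality is below `threshold_q` (default 20). The stride equals the window,
so the rule is deterministic and cheap; it reproduces the intended
behaviour on mixed-quality tails (a read ending in four quality-10 bases
loses exactly those four). The window anchors at the 3' end, so the 5'-most
block may be shorter; a uniformly bad read trims to empty and is then
rejected at the merge stage.

**Merging** reverse-complements mate 2 and scores every overlap length from
`min_overlap` (default 20) to the shorter read length as matches minus
mismatches, keeping the best score with ties broken toward the longer
overlap (more supporting positions). The merge is rejected when no overlap
is admissible or when the best overlap's mismatch fraction exceeds
`max_mismatch_fraction` (default 0.1). Disagreeing positions take the
higher-quality base; agreeing positions keep the higher quality; an exact
quality tie keeps the mate-1 base and records the minimum quality, so
consensus qualities never overstate the evidence.

**Length filter**: only merged amplicons strictly longer than 450 bp enter
the analysis ("over 450 bp" is read strictly, so 450 drops and 451 keeps).
Per-sample accounting enforces `pairs_in = merged + rejected` and
`merged = kept + length_filtered` at every stage.

The defaults (window 4 / Q20, overlap 20 / 10% mismatch) are the common
amplicon conventions; they are configuration, not results-critical, and the
tests exercise them explicitly.

## Reference search

Each merged read is scored against every library sequence with
score-only Smith-Waterman dynamic programming (match +1, mismatch -2,
affine gaps costing `gap_open + L * gap_extend`, defaults -2/-2), the
reward/penalty family of megablast-style searches. Raw scores are reported
alongside bit scores `S' = (lambda * S - ln K) / ln 2` with the published
ungapped constants for +1/-2 scoring (lambda 1.28, K 0.46). The transform
is strictly monotone, so the set of top hits is identical under raw and bit
scores; ties are decided on exact integer raw scores.

The exhaustive engine doubles as the oracle. The default engine is a
seeded accelerator: an 11-mer index selects candidate references sharing at
least one exact k-mer with the read, and each candidate is aligned in a
diagonal band around its seed k-mer diagonals (padding 25 diagonals on each
side). With substitution-dominated error the optimal alignment lies on the
seed diagonal, and the test suite asserts hit-for-hit equality between the
seeded and exhaustive engines on simulated reads at the study error rate. A
read sharing no k-mer with any reference is left unassigned rather than
force-matched. No identity or coverage cut-off is applied by default;
optional thresholds exist but are off, matching a top-bit-score protocol.

## Taxonomic assignment

Tied top hits are collapsed to their distinct (species, genus, family)
triples and assigned at the lowest common rank: one species gives a
species-level call; several species of one genus a genus-level call;
several genera of one family a family-level call whose label is the sorted
constituent genus names joined with "/" (e.g. `Cotoneaster/Crataegus/Malus`)
so group labels are deterministic; hits spanning families are unknown.
Reference entries with an empty species field are genus-level vouchers and
coarsen a tie accordingly. Reads with empty hit sets count as unknown in
the identifiable-fraction denominator, which is computed over all
length-filtered reads.

The **regional checklist filter** re-expresses the study's manual
"recorded in the region" screen as a deterministic rule applied after
assignment: a species-level label is retained if the species or its genus
is on the checklist, a genus-level label if its genus is, and a family
group if *any* constituent genus is. Removed taxa take their reads out of
the composition denominator and are logged with read counts.

## Composition and diversity

Counts become percentages of the checklist-retained, identifiable reads
per hive x month. Pooling across samples defaults to summing read counts
and recomputing proportions (consistent with read-level statements about
pooled data); an unweighted mean of proportions is available as an option
since the pooling rule for a published figure is not always stated.
Major forage taxa are those strictly above 1% of reads; exactly 1.00% is
minor. Richness is the count of taxa with reads. Diversity is the
Gini-Simpson complement `D = 1 - sum(p_i^2)`; the complement form is the
only one consistent with published spring-honey values in the 0.6-0.85
range rising with evenness.

## Survey analysis

A survey is a set of (zone, month, taxon-in-flower) records with fixed
zone areas. Availability reduces survey taxa to genera (first label token)
and maps genera to families through the reference taxonomy; the combined
month is the union. Genera-per-m2 density is the per-zone distinct-genus
count over the zone area. Use-versus-availability counts how many honey
genera (species-level labels contribute their genus, family groups every
constituent genus) appear in the month's availability set, and reports the
integer percentage rounded **half away from zero** — the only integer
rounding consistent with printed pairs such as 18/80 -> 23% and
45/360 -> 13%. Area of occurrence sums the areas of zones where any
species of the taxon's genus flowered that month, an approximate
distribution measure. Phenology concordance flags taxa detected in honey
in months when they were not in flower; a taxon never recorded in flower
but present in honey is flagged as carry-over (stored honey from an
earlier season, the classic autumn-ivy-in-spring-honey case).

## Statistics

All tests are deterministic given their inputs.

* **Spearman rank correlation** ranks with average-rank ties and takes the
  Pearson correlation of the rank vectors; p-values use the t
  approximation for n > 8 (the regime standard packages print at n of a
  few dozen) and full permutation enumeration for n <= 8.
* **Mann-Whitney U** reports the exact two-sided p by enumerating all
  C(n1+n2, n1) group labelings (exact through total n of 12, covering
  three-hives-per-month designs) together with the tie-corrected normal Z
  without continuity correction, since published small-sample tables often
  print the Z regime; the exact p is the headline.
* **Fisher's exact test** handles r x c tables by recursive enumeration of
  all tables with the observed margins under the multivariate
  hypergeometric, summing the probability of tables no more probable than
  the observed one (with a 1e-7 relative tolerance for floating-point
  ties, the convention of standard implementations). Totals are capped at
  500; beyond that the error message suggests simulation. For 2 x 2 tables
  this equals the hypergeometric closed form, which the tests assert on
  random tables alongside `stats::fisher.test`.
* **Bonferroni** is plain multiplication by the family size, capped at 1,
  applied across hive pairs x months in the concordance analysis.
* Between-hive concordance correlates per-hive abundance vectors over the
  union taxon list (absent taxa as zero), so every pair shares one n.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated:

* **Reference library**: one ancestral amplicon per family drawn uniformly
  over {A,C,G,T}; genus ancestors substitute each site independently with
  probability `d_genus` (default 0.06); species with `d_species` (default
  0.02, zero allowed for the identical-congenerics limit). Congeneric
  sequences are therefore more similar than confamilial ones and
  cross-family identity sits at the ~25% random baseline. `d_family`
  (default 0.25) bounds expected cross-family divergence and is validated
  for the ordering `d_family > d_genus > d_species`. Defaults give 6
  families x 3 genera x 2 species = 36 references of 550 bp — desk-scale,
  so the exhaustive engine is tractable as an oracle.
* **Reads**: per pair, a taxon is drawn by its true proportion, a reference
  of that taxon uniformly; mate 1 is the first 300 bp of the amplicon and
  mate 2 the reverse complement of the last 300 bp, so perfect merges are
  550 bp with a 50 bp overlap and pass the >450 filter (a short-amplicon
  option below 450 exists to exercise rejection). Per-base qualities are
  drawn from a two-point mix around the Phred equivalent of the error rate
  with the mixing weight chosen so the expected per-base error equals the
  nominal rate exactly, and each base is substituted with its own
  quality-implied probability (uniform over the three alternatives).
  Substitution-only by default, which keeps merge and assignment truth
  exact. Everything is deterministic given the seed; the taxon draw is the
  first RNG use so tests can replay it.
* **Mixtures**: each sample is a ten-taxon geometric mixture
  (`p_i` proportional to `0.5^i`), a few-dominant-taxa profile in which
  the leading taxon holds ~50% of reads and the tail crosses the 1% line,
  so the major/minor split is non-trivial. All hives share a month's
  mixture; the second month's ranking is a rotation of the first's, so
  both months remain geometric while monthly compositions differ.
* **Survey**: 20 zones summing to 34.2 ha with lognormal-ish areas and
  habitat classes dominated by grassland. Mixture taxa flower in both
  months (so detections are phenology-concordant by construction);
  remaining library taxa get random windows. Checklist statuses make
  mixture taxa native or near-native and the remainder mostly
  horticultural, emulating the major-native / minor-horticultural
  contrast.

What the generator does **not** emulate: PCR and plastid-copy-number
abundance biases, chimeras, indel sequencing error, primer read-through,
and quality-score autocorrelation. Passing recovery tests therefore shows
the informatics recovers the DNA mixture actually sequenced, not that
read proportions equal pollen proportions in real honey — the standard
caveat for semi-quantitative metabarcoding.

## Validation sizes and numerical choices

The recovery study used by the tests and the acceptance script is 3 hives
x 2 months x 10,000 read pairs at per-base error 0.005 — large enough that
binomial noise on a 50% taxon is ~0.5 percentage points, well inside the
2-point recovery bound, and sized to run comfortably on one CPU. Oracle
equivalence suites use a few hundred reads against the full default
library. Proportions must sum to 100 within 1e-6; mixture proportions to 1
within 1e-9; alignment ties are exact integer comparisons; Fisher ties use
the 1e-7 relative tolerance noted above. Degenerate inputs fail loudly:
zero retained reads, empty libraries, desynchronized taxonomy, conflicting
zone areas and unknown months are all hard errors naming the offender.

## Known limitations

* Reproducing published per-hive statistics requires the corresponding
  per-hive proportion table, distributed as an external supplementary
  dataset; `analyze_proportion_table()` reproduces monthly pooled Simpson
  values and between-hive correlations from it when supplied, and its
  acceptance test reports honestly as failing when the file is absent.
* The seeded engine's banded extension is a heuristic; its equality with
  the exhaustive engine is asserted empirically at the simulated error
  rate, not proven for arbitrary indel-rich input (set `band_pad = -1` to
  align candidates with full Smith-Waterman, or use the exhaustive
  engine).
* One cell of the published use-versus-availability table (20 of 96
  printed as 20%) is inconsistent with every integer rounding rule that
  reproduces the other 23 cells; the package reports the rule's value
  (21%).
* r x c Fisher enumeration is exponential in principle; the n <= 500 guard
  keeps it to the table sizes this design produces.
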