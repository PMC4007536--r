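---
title: "Methods: inferring TE family activity and life-cycle stage"
author: "telifecycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring TE family activity and life-cycle stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable element (TE) families move through a life cycle inside a host
genome: a family arrives (by horizontal transfer or in-genome divergence),
proliferates, accumulates inactivating mutations, and eventually becomes a
genomic fossil. For a single sequenced genome — here modelled on a protist
with a compact genome and a three-stage life cycle (adherent amoebae,
free-floating cells, aggregates) — the family's position in that cycle can
be read from four signals:

1. **Identical paralogous copies.** Distinct genomic inserts with identical
   sequence have had no time to diverge; their presence is direct evidence
   of very recent transposition.
2. **Intra-element LTR identity.** The two long terminal repeats (LTRs) of
   an LTR retrotransposon are identical at integration and then diverge as
   a molecular clock; near-100% identity dates an insert as young.
3. **Site-frequency shape, via Tajima's D.** A recently expanded family is
   a star genealogy: most variants are rare and D is negative. A family
   with multiple diverged, simultaneously active lineages (population
   substructure) carries intermediate-frequency variants and D can turn
   positive.
4. **Copy-age profiles.** Terminal branch lengths of a per-copy tree proxy
   insert age; copies at or above 0.05 substitutions/site are counted as
   old inserts.

Stage-resolved RNA-seq adds a regulatory axis: per-family read counts per
life-cycle stage, tested for stage specificity.

The package implements the full chain — terminus discovery in genome
sequence, reconstruction of individual inserts from target-site
duplications (TSDs), structure classification (full-length element, solo
LTR, truncated), diversity statistics, copy-age profiling and expression
tests — plus a synthetic-data generator that plants families with known
histories so every stage can be validated against ground truth.

## Insert reconstruction from TSDs

Integration duplicates the target site, leaving the same short sequence
immediately 5' and 3' of the insert. The two termini of one insert are
therefore paired by requiring that the `tsd_len` bases ending the 5'
terminus's upstream flank equal the `tsd_len` bases starting the 3'
terminus's downstream flank.

Terminus matches come from a seeded ungapped scanner (`scan_genome`): exact
`seed_len`-mers anchor candidate diagonals, each diagonal is scored +1 per
match / −1 per mismatch, and the maximal-scoring segment is reported when
it reaches `min_identity` over at least `min_cov` of the query. Both
strands are searched; minus-strand flanks are re-oriented so all downstream
logic is strand-agnostic. Queries are capped at 300 bp, which is ample for
terminal repeats and keeps the diagonal set small.

One numerical subtlety matters: the maximal-scoring segment sheds terminal
mismatches, so a diverged copy's hit can end a few bases inside the true
terminus. Flanks are therefore anchored at the *full query projection*
(the whole query laid along the hit diagonal), not at the trimmed segment —
otherwise the TSD would be masked by element sequence for exactly the
older, more diverged copies the analysis cares about.

Pairing is greedy in element orientation (genomically left-to-right on the
plus strand, right-to-left on minus): each 5' hit is offered only its
nearest downstream 3' hit within `max_span` (default 15 kb, generous for
multi-kb LTR elements). TSDs are locally unique at realistic lengths, so
greedy nearest-neighbour pairing reproduces unique-context pairing; a lone
LTR hit whose own upstream-flank tail equals its downstream-flank head is a
solo LTR. Everything else is emitted `unpaired` — the pipeline never
guesses a structure it cannot support with a duplication.

When the family's TSD length is unknown it is inferred (`infer_tsd_len`):
for each candidate insert the longest k in 2–12 bp with a flank
duplication, then the modal k across inserts (ties resolved to the smaller
k for determinism). The 2–12 bp scan range covers the lengths seen across
DNA-transposon and retrotransposon superfamilies (2 bp TA targets through
9 bp). The pipeline bootstraps this from a provisional proximity-only
pairing, then re-pairs with the inferred length.

## Diversity statistics

For each family, one analysis sequence per insert is sliced at the full
query projection, so the set is positionally aligned by construction on
indel-free data: one LTR per insert for LTR families (the 5' LTR of a
full-length element, the lone LTR of a solo), the 3' terminus for non-LTR
families, the 5' ITR for DNA families. Terminus hits covering less than
90% of the query are excluded: a partially truncated terminus would drag
flanking DNA into the alignment and flood it with spurious singletons.

Gap handling defaults to **complete deletion**: every column containing a
gap or N is removed before anything is computed, so π, k and S always
refer to the same site set. An alignment with no clean column yields an
explicit "insufficient sites" condition and is reported n/a, never 0.
Pairwise deletion is available for π only.

With n sequences and usable length L: k is the mean pairwise difference
count over all n(n−1)/2 pairs, π = k/L, and S counts polymorphic usable
columns. Tajima's D follows the standard constants
(a₁ = Σ1/i, a₂ = Σ1/i², b₁, b₂, c₁, c₂, e₁, e₂) with
D = (k − S/a₁) / √(e₁S + e₂S(S−1)), undefined (reported empty) when S = 0
or n < 4 (Tajima 1989, *Genetics* 123:585).

Significance uses Tajima's scaled-beta approximation. D is bounded by the
all-singleton and balanced-intermediate extremes,
Dmin = (2/n − 1/a₁)/√e₂ and Dmax = (n/(2(n−1)) − 1/a₁)/√e₂; a beta
distribution rescaled to [Dmin, Dmax] with mean 0 and variance 1 has
total shape s = −(1 + Dmin·Dmax) and shapes p = −Dmin·s/(Dmax−Dmin),
q = Dmax·s/(Dmax−Dmin) (solved directly from the two moment constraints).
The two-tailed p is 2·min(P, 1−P) of the rescaled CDF, starred at
0.05/0.01/0.001. For sample sizes so small that the variance constraint is
unsatisfiable the code falls back to a normal approximation.

"Identical paralogous copies" is the number of sequences belonging to any
exact-identity group of size ≥ 2 (so five copies of which three are
identical score 3, and two pairs score 4), computed on the analyzed
terminus region in canonical discovery orientation.

## Copy ages

Per-copy trees use Jukes–Cantor distances, d = −¾·ln(1 − 4p/3) on
pairwise-complete sites, with saturated pairs (p ≥ 0.75) capped at 3
substitutions/site and flagged, followed by Saitou–Nei neighbor joining
(via `ape::nj`). Negative branch estimates are clamped to zero with the
deficit moved to the sibling branch, preserving path lengths. Distance-NJ
terminal branch lengths are a deliberately light-weight proxy for
likelihood branch lengths: the downstream quantity is only the coarse
≥ 0.05 substitutions/site old-insert classification and the box-summary
shape (median, quartiles, 1.5 × IQR whiskers, outliers), both of which are
insensitive to the tree method at that resolution. Numeric branch lengths
from other tree methods will differ; only the classification is treated as
comparable.

## Expression

Reads are assigned by the same seeded ungapped machinery against family
consensus sequences (seed 10 bp, every offset, both strands); a read goes
to the family with the best identity ≥ 0.80 covering ≥ 80% of the read,
and reads tying across families are dropped. The thresholds mirror the
genome scan and are deliberately permissive: a read from a copy 8%
diverged from its consensus plus 1% sequencing error still has to be
counted, while a chance cross-family match at ≥ 80% identity over ≥ 48 bp
is effectively impossible for unrelated consensi.

Heatmap cells are per family × stage sums over the three replicates,
normalized by the single global maximum cell; a second matrix rescales
log10(x+1) to [0, 1] (zeros exist, so the offset is required; the rescale
pins the minimum at 0). No library-size normalization is applied by
default — the analysis normalizes only by the global maximum.

Stage specificity is a one-way ANOVA per family (3 stages × 3 replicates,
df 2 and 6); families passing α = 0.05 get an unpaired pooled-variance
t-test (df 4) between the two stages with the highest combined expression,
and an `elevated_stage` is declared only when that also passes α. A
constant family has no defined F and is reported not significant. No
multiple-testing correction is applied by default, matching the
per-family reporting convention; the gate-then-test design is itself
conservative (measured false-elevation rate ≈ 0.02 on 1,000 null
families).

The activity–expression link is a plain Pearson correlation between
per-family read totals and identical-copy counts, on untransformed values.

## What the generator emulates — and what it does not

`simulate_family` draws copies as i.i.d. descendants of a family founder
under a simplified clock: a copy of age t substitutes each site
independently with p(t) = 1 − exp(−μt), uniformly to the three
alternatives. LTR copies duplicate the founder LTR at insertion, after
which the two LTRs mutate independently — so expected intra-element
divergence is ≈ 2μt for small μt, the closed form the recovery tests use.
Ectopic recombination converts an FLE of age t to a solo with probability
1 − exp(−ρt), retaining the 5' LTR (a fixed convention so truth tables are
deterministic). Non-LTR copies are 5'-truncated with probability q at a
uniform breakpoint. Copy loss removes intact elements at per-time rate
`loss_rate` while solo LTRs are exempt: solos are near-neutral relics,
which is precisely what lets old cohorts become solo-enriched and drives
π(solo) > π(FLE). Insertion histories are bursts (age, count) or a
constant-rate Poisson process; a `subfamily_split_age` > 0 derives copies
from one of two founders that diverged at that age, generating the
positive-D substructure regime.

`plant_genome` inserts each copy at a site drawn per target preference —
uniform, TA dinucleotides only, or GC-weighted at positions 1 and 5 of the
target k-mer (weight 1.8 per G/C, chosen so a GC-balanced background gives
≈ 68% GC at the preferred positions, the enrichment scale seen in
chromoviral target sites) — duplicates the `tsd_len` target bases, and
records exact truth intervals. Placements are non-overlapping with a
minimum spacing so flanks stay clean. `simulate_reads` draws per
family/stage/replicate counts from a negative binomial (the field's
standard overdispersed count model) and samples reads uniformly from
copies on either strand with independent substitution errors.

Deliberately **not** modelled: indels (alignment-free truth by default;
gapped-input handling is tested on crafted alignments instead), selection,
nested insertions, insertion-site epistasis, genealogy within a burst
(copies are star-shaped by construction), and any biology of the
life-cycle stages beyond their expression means. Consequently, passing
recovery tests demonstrates the inference machinery is correct on data
satisfying its assumptions — it does not demonstrate robustness to
alignment error, nested or fragmented inserts, or non-clocklike evolution
in real genomes.

## Numerical and design choices

- Coordinates are 1-based inclusive throughout, internally and in reports
  — the native convention of R and Bioconductor ranges; mixing conventions
  is the classic source of off-by-one errors.
- Ambiguity codes other than N are mapped to N with a warning; N columns
  are treated as gaps by the statistics.
- Seeded scanning: seed 12 bp, identity ≥ 0.80 over ≥ 50% of the query,
  flanks 20 bp. These stand in for "default parameters" of a
  similarity-search tool at desk scale and are all config-exposed.
- Overlapping same-query hits are merged keeping the higher identity; ties
  break to the leftmost start, making scans deterministic.
- Exact TSD matching by default; `tsd_mismatch = 1` tolerates one mismatch
  for older inserts whose TSDs have mutated, at the cost of occasional
  false pairs.
- Demo problem sizes: 200 kb background, three families (~55 copies),
  ~10,000 reads across 9 stage/replicate sets; regime checks use 41
  replicate families of 24–40 copies and the calibration set 1,000 null
  families. These sizes give stable medians and binomial intervals while
  keeping a full validation run in the tens of seconds.
- Every stochastic stage takes an explicit integer seed and the pipeline
  derives per-stage seeds from one master seed, so identical configs give
  byte-identical outputs.

## Known limitations

- Ungapped extension cannot recover termini containing indels relative to
  the query; such hits shorten or split and may fail coverage.
- Greedy nearest-neighbour pairing can mis-pair when two inserts of the
  same family coincide within `max_span` *and* share a TSD by chance;
  collisions are flagged rather than resolved.
- Nested and fragmented inserts are out of scope; the assembler reports
  the pieces it can justify and leaves the rest `unpaired`.
- NJ branch lengths are not ML branch lengths; quantities finer than the
  0.05 subs/site threshold should not be read off these trees.
- A TSD length reported for a family with fewer than three recovered
  duplications is per-insert only; the modal family length is withheld.
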