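---
title: "Methods: chromosome-specific KASP markers and introgression-segment calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome-specific KASP markers and introgression-segment calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introKASP)
```

# Scope and model

`introKASP` models the computational side of building a chromosome-specific
KASP genotyping platform for wheat × wild-relative introgression breeding
and of turning genotype matrices into a catalog of homozygous introgression
segments. The wet-lab portions (DNA extraction, PCR, cytology) are out of
scope; where the original workflow used production tools at cluster scale
(read mapping with BWA, calling with BCFtools, homology search with BLASTn,
primer design through the PolyMarker service), this package substitutes
documented desk-scale stand-ins that preserve the decision rules, and it
validates those rules on synthetic genomes with planted ground truth.

The genetic setting: the recipient is hexaploid (subgenomes A, B, D), the
donor tetraploid (Aᵗ, G), with Aᵗ homoeologous to A and G to B. In a
*ph1* background a donor-carrying bivalent pairs and recombines
homoeologously; Aᵗ–A pairs more readily (≈ 0.70) than G–B (≈ 0.30). A
marker is *chromosome-specific* when its assay amplifies one locus of one
wheat chromosome, and *subgenome-specific* when its donor allele is
diagnostic for Aᵗ or G chromatin.

# The KASP-suitability filter

Candidate SNPs (donor vs recipient) pass a fixed, ordered rule chain; the
first violated rule is the single recorded reason:

1. homozygous alternative genotype (`NOT_HOMOZYGOUS`),
2. read depth **strictly** greater than 10 (`LOW_DEPTH`),
3. alternative fraction exactly 1.0 (`IMPURE_ALT`),
4. at least 50 bp from both chromosome ends (`EDGE_OF_CHROM`),
5. every flank position within 50 bp (SNP itself excluded): no
   read-supported indel (`FLANK_INDEL`), depth **strictly** greater than 5
   (`LOW_FLANK_DEPTH`), reference-base fraction ≥ 0.80
   (`FLANK_POLYMORPHIC`).

Interpretation choices where the prose admitted more than one reading, all
configurable through `filter_thresholds()`:

* "greater than 10"/"greater than five" are strict inequalities; the
  percentage thresholds (80%, 97%) are inclusive.
* "no indels" is the strictest per-position reading: a single read showing
  a deletion spanning, or an insertion anchored at, a flank position fails
  the site.
* the flank reference fraction is computed over base calls only
  (deletion-spanning reads excluded from the denominator;
  `flank_frac_counts_dels` includes them).
* sites within 50 bp of a chromosome end fail (`EDGE_OF_CHROM`): a KASP
  assay needs both flanks. Candidate depth is post-filter, post-dedup
  depth, matching the pipeline order (filter → dedup → pileup → call →
  suitability).
* flank rules are evaluated rule-major (indels at every position, then
  depth, then fraction), making reason codes deterministic.

The candidate caller itself is a declared stand-in: a position with a
single non-reference base supported by ≥ 2 reads becomes a candidate;
positions with two such non-reference bases are flagged multiallelic and
excluded. Externally produced VCFs (with GT/DP/AD) can be substituted via
`read_vcf()`.

# Chromosome-specificity screen

Each passing SNP's 101-bp reference context (reference base at the centre)
is searched against the whole recipient genome by exact 16-mer seeding
followed by banded local alignment (match +1, mismatch −1, gap open −2
including the first gap base, extend −1). Hits need ≥ 61 aligned columns
(60% of the query) and identity is measured over aligned columns — this
mimics default local-alignment behaviour while barring trivially short
high-identity fragments. Seed length 16 is safe at the decision boundary:
a 101-mer copy with ≤ 3 mismatches always contains an exact run of
⌈(101 − 3)/4⌉ = 25 ≥ 16 bases. The SNP fails with `OFF_TARGET` if any
non-self hit reaches 97% identity, and with `NONUNIQUE_CONTEXT` if no
self-hit is recovered at all. Whether the original 97% rule also imposed an
alignment-coverage requirement is unknown; ours (≥ 61 columns) is explicit
and configurable (`search_params()`).

# Assay design

Primer conventions are KASP-typical rather than sourced: allele-specific
primers grow 5′-ward from the SNP (3′ terminus = the allele) from 18 nt
until the Wallace Tm 2(A+T) + 4(G+C) lands in [58, 62] °C (or 30 nt is
reached → design failure); the common primer sits on the reverse strand
3′-ward of the SNP under the same Tm window with a product of 40–120 bp.
An assay is `specific` only if each primer footprint is unique in the
genome at the 97% threshold — the equivalent of requiring a single matching
contig from an automated design service. Thermodynamic nearest-neighbour
Tm, dimer checks and fluorophore tails are out of scope.

# Segment calling and the catalog

Within a chromosome's ordered markers, maximal runs of homozygous-donor
calls become homozygous segments; heterozygous runs are recorded but
excluded from the homozygous catalog and all summary statistics. A single
no-call flanked by the run state is bridged (two consecutive no-calls
break the run; both behaviours configurable), and a heterozygous call
always terminates a homozygous run. Single-marker segments are retained by
default (`min_markers = 1`) because genuinely small introgressions may rest
on one marker.

Every segment carries three nested intervals:

* **inner** — first to last supporting marker (minimal),
* **outer** — extended to the midpoints towards the nearest flanking
  non-donor markers, or to the chromosome end where there is none
  (chromosomes whose every marker supports the run extend end to end),
* **bound** — the maximal interval consistent with the flanking non-donor
  markers (previous marker + 1 bp to next marker).

The published convention for drawn segment extents is not stated; we use
*outer* for catalog extents and coverage (end-extension is required for
whole-chromosome substitutions to cover 100%). Note that the guarantee
*inner ⊆ true block ⊆ X* can only hold universally for X = *bound*: a true
junction may lie beyond the midpoint of the flanking interval, so the
bracketing property and its tests are stated on *bound* while *outer*
remains exactly the midpoint convention.

Unique segments are equivalence classes of homozygous segments by
(chromosome, exact support-marker signature) — the only equivalence
faithful to marker resolution, since two lines with the same signature are
indistinguishable by the panel. Names follow the field's scheme:
`{donor chromosome}.{recipient genome letter}{ordinal}` with ordinals
assigned within each (donor chromosome, recipient letter) by ascending
outer start (ties: outer end, then larger signature); whole-chromosome
classes are named by the donor chromosome alone (e.g. `4At`). The donor
chromosome of a segment is the recipient homoeologous group joined to the
majority subgenome among its subgenome-specific supporting markers, so a
segment on 3D supported by G-specific markers is called 3G chromatin. Ties
or absent specific support set `ambiguous_donor` and fall back to
recipient homoeology (A → Aᵗ, B → G, and — arbitrarily, flagged — D → Aᵗ);
resolving such cases cytologically is out of scope.

Coverage per donor chromosome is the union of its unique segments' outer
intervals, each projected onto fractional coordinates of the recipient
chromosome that carries it (interval/length on [0, 1]), × 100. For a donor
chromosome whose segments all lie on one recipient homoeologue this equals
interval-union length over chromosome length; the fractional projection
extends the definition consistently when one donor chromosome recombined
with several recipient chromosomes of different lengths (e.g. 3G into 3B
and 3D). The genome-wide figure is the mean over donor chromosomes
weighted by the primary recipient homoeologue's length.

Genotypes can come from a 0/1/2/NA matrix or from endpoint-fluorescence
points: a nearest-centroid stand-in seeded by control wells, with a
relative no-call margin (default 0.2) and a no-template-control guard. It
emulates the decision structure of endpoint-genotyping software, not its
clustering algorithm.

# The packaged tables

Two tables are shipped verbatim as fixtures and validated at load:
per-chromosome marker counts (21 rows; per-row set sums equal row totals;
column sums equal the printed totals: 250/30/51/149/480 markers and
182/275/23 specificities) and the per-IL segment list (98 rows; each row's
declared count equals its label-list length; one row represents two
genotypically identical lines and expands to give 99 lines).

One internal inconsistency of the source tables is preserved rather than
patched: the per-IL table sums to 182 Aᵗ + 127 G = 309 homozygous segment
occurrences, while the accompanying prose quotes 183 and 126 (same total).
All other published statistics — 309 occurrences, 89 unique Aᵗ segments
plus the 4Aᵗ whole-chromosome substitution, 74 unique G, 19 G.D, 2 At.D,
per-line min 1 / mean 3.1 / max 8 — reproduce exactly from the table. The
package reports what the table yields.

# The synthetic world

`make_genomes()` builds a recipient (groups × A/B/D, equal-length
chromosomes) and a donor whose Aᵗ/G chromosomes are mutated copies of
their A/B homoeologues. Default divergence is 0.005 (Aᵗ–A) and 0.0075
(G–B): substitution densities that give a comfortable marker supply on
20-kb toy chromosomes while preserving the ordering "Aᵗ closer than G".
Planted classes make filter behaviour decidable:

* **CLEAN** sites are isolated by construction: ≥ 101 bp from any other
  planted edit, outside duplicated regions, and away from chromosome ends
  by a margin (up to 700 bp) that also clears the sequencing coverage ramp.
  This is deliberate: the acceptance property "precision = recall = 1.0 on
  CLEAN variants" defines CLEAN as *KASP-clean truth*, which a site inside
  another site's flank, or in partial end coverage, is not.
* **NEAR_INDEL** sites get a 1–3-bp donor indel 5–45 bp away;
  **FLANK_POLYMORPHIC** sites come in pairs 10–40 bp apart;
  **REPEAT_REGION** sites sit inside a block duplicated elsewhere in the
  recipient at ≈ 99.5% identity; **LOW_DEPTH_REGION** sites sit in regions
  the read simulator thins to ~15% of target coverage.

`simulate_reads()` emits pairs already placed at their true recipient
coordinates — read mapping is deliberately not re-implemented, because
every downstream rule acts on alignments, not on a mapper. Pair count is
exactly `round(coverage × total_length / (2 × read_len))`; fragment starts
are stratified (even spacing with half-a-stride uniform jitter), emulating
the near-uniform coverage of a PCR-free library and keeping local depth
close to target — under fully independent placement, Poisson fluctuation
alone would push ~1% of clean sites below the depth thresholds, which
would misrepresent what the filter (as opposed to the sequencing lottery)
does. Donor reads are built by walking the per-chromosome edit table, so
CIGARs encode the planted indels. A configurable junk fraction carries
MAPQ < 10, unmapped/supplementary flags, improper pairing or positional
duplicates to exercise the alignment filters.

The breeding simulator is a two-strand meiosis: a donor-carrying bivalent
pairs with probability taken from the scheme (defaults Aᵗ–A 0.70, G–B 0.30
from the cited pairing frequencies; Aᵗ–D 0.02 and G–D 0.10 are *invented,
tunable stand-ins* — no quantitative D-pairing rate is published — chosen
so D-genome recombinants arise at roughly the observed proportions), and a
paired bivalent undergoes exactly one crossover at a uniform position
(optional second crossover by configuration), always transmitting a
recombinant product. Consequently the gamete junction frequency equals the
pairing probability — the simplification drops the 4-chromatid bundle, in
which only half the products of a single exchange are recombinant.
Transmission bias (e.g. preferential 2G transmission) is rejection
sampling over whole gametes with per-donor-chromosome multipliers,
normalised by the maximal product. No recombination interference, gene
conversion, or molecular *Ph1* mechanism is modelled; donor karyotype
rearrangements (the configurable translocation option) exist at the
sequence level only and the breeding simulator refuses translocated
donors.

What a green synthetic test does establish: the filter chain implements
its thresholds exactly (boundary tests), recovers exactly the planted
CLEAN set under stated coverage, assigns the documented failure reason to
each planted confounder class, and the segment caller brackets every true
block between its inner and bound intervals with no false segments. What
it does not establish: behaviour on real 17-Gb wheat data, mapper
artefacts, base-quality effects (no quality model is simulated), realistic
repeat families, or the published 36,001 → 6,957 attrition counts, which
require the full-scale data and are explicitly substituted by the
property-based criteria above.

# Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally and in BED;
  SAM, VCF and the marker map are 1-based on disk; writers/readers enforce
  and round-trip the conventions.
* All randomness descends from one seed through deterministic child seeds
  per stage (`child_seed`), so any stage can be re-run in isolation and
  identical configurations are byte-identical, including output files.
* The local-alignment primitive (and the brute-force windowed
  Smith–Waterman oracle in the tests) is `Biostrings::pairwiseAlignment`;
  the seed-and-extend strategy, clustering, merging and all decision rules
  are package code. Oracle and implementation share only the alignment
  primitive, not the search.
* Duplicate removal keeps, per (chrom, pos, strand, mate position) key,
  the record with the lexicographically smallest read id — an arbitrary
  but deterministic tie-break.
* Greedy gap filling processes the widest over-target gap first (ties:
  leftmost), inserting the candidate nearest the gap midpoint (ties:
  smaller position); gaps above target without candidates are reported
  unfilled. The panel's "average distance" is the mean adjacent gap
  (chromosome ends excluded); a one-marker chromosome reports its length
  as the max gap.

# Known limitations

Equal-length chromosomes; no accession-level donor variation (the
sequenced and the crossed accession are treated as one genome); fragment
lengths are fixed at the mean; genotyping error is not modelled in the
truth oracle (use the fluorescence caller with noisy points to study
call-level noise); segment naming ignores donor translocations, exactly as
the field's labelling does, so a label records where chromatin landed and
which subgenome it came from, not donor-internal rearrangement history.
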