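---
title: "Annotating small RNAs in nucleomorph genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating small RNAs in nucleomorph genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmsrna)
```

# Scope and conventions

`nmsrna` annotates small RNA genes — C/D box snoRNAs, spliceosomal
snRNAs, and orphan sRNAs — in miniaturized, gene-dense genomes such as
algal nucleomorphs, starting from a genome FASTA, a GFF3 annotation of
protein/rRNA/tRNA genes, and pre-mapped sRNA read intervals (BED6, with
the score column reused as read multiplicity). Read trimming and
alignment are out of scope; inputs are mapped intervals.

Two conventions hold everywhere inside the package and are converted
only at format boundaries: intervals are 0-based half-open, and
sequences are uppercase RNA over `{A,C,G,U,N}` (DNA `T` is converted on
read; IUPAC ambiguity codes other than `N` are replaced by `N` with a
warning, because degeneracy belongs in search patterns, not in
subjects; an `N` in a subject always counts as a mismatch).

# Locus calling

Stranded, per-library coverage is accumulated from multiplicity-weighted
read intervals. Candidate loci are maximal runs where the pooled
(all-library) depth reaches `depth_min` (default 3), after merging
sub-threshold gaps up to `gap_max` (5 nt). Ends are trimmed to the
outermost positions with depth at least `end_frac` (0.1) of the run's
peak, a reproducible stand-in for the end delineation that is done by
manual inspection in practice. A locus is retained only if

* every library contributes at least `support_min` (3)
  multiplicity-weighted overlapping reads — expression in all libraries,
  including the Terminator-exonuclease (TE) treated one;
* it is not fully contained in a CDS/rRNA/tRNA gene;
* it does not overlap an rRNA or tRNA gene at all (degradation
  fragments of stable RNAs dominate sRNA libraries, so any overlap is
  disqualifying);
* it is at least `min_locus_len` (16) nt long.

These defaults are package choices standing in for manual curation and
are all exposed as parameters. Partial overlap with protein-coding
genes is expected in nucleomorphs (13–43 nt overlaps at locus ends);
overlaps are reported in transcript orientation (`overlap5`/`overlap3`,
swapped on the minus strand). Unstranded reads are rejected because
that orientation is meaningless without strand.

Cap status: TE treatment degrades 5′-monophosphate RNAs and spares
capped ones, so the ratio *r* of TE to untreated reads-per-million at a
locus separates the classes; *r* ≥ 0.5 is capped-like, *r* ≤ 0.2
monophosphate-like, otherwise ambiguous. Normalization is per-library
reads-per-million because library sizes differ by design.

One consequence of the strict "all libraries" rule is worth noting: a
monophosphate-like locus keeps only ~5% of its reads in the TE library,
so at the default depth (mean 200 reads/locus, hence ~10 TE reads) it
occasionally draws fewer than `support_min` reads there and is dropped.
This is faithful to the rule, and it is why locus recall on synthetic
data is asserted as ≥ 0.90 rather than 1.0.

# Degenerate pattern search

The search engine aligns an IUPAC pattern against every subject start
position under three *independent* budgets — mismatches, insertions
(extra subject bases), deletions (skipped pattern bases) — matching
PatScan semantics, where the budgets are stated separately rather than
as a summed edit distance. A degenerate pattern letter never consumes
budget when the subject base is in its class. Insertions are restricted
to the interior of the alignment: a leading or trailing insertion would
merely shift the match, producing redundant hits.

Per start position the engine reports the alignment minimizing total
edits, breaking ties by fewer indels, then by the leftmost end. The
core is a small C++ dynamic program over reachable budget states
(bitmask over the ≤ 64-state budget lattice), which keeps genome-scale
scans fast; its correctness is established in the test suite against an
independent min-mismatch dynamic program on hundreds of random
instances.

The composite `find_two_helix_candidates()` searches a subject for the
reverse complements of two partner-RNA helix sequences (each under its
own budgets — whether budgets apply per helix or jointly is not
standardized, so per-helix is the default, which is the conservative
reading), separated by a spacer of 20–120 nt (the spacer bounds are
package defaults; no published value exists) that must fold into a
hairpin. The hairpin check is combinatorial, not thermodynamic: a pair
of antiparallel complementary substrings (Watson–Crick plus G·U), each
≥ `min_stem` (5) bp, separated by ≥ `min_loop` (3) unpaired bases. The
topological constraint is what the rule requires; folding energies are
deliberately out of scope.

# C/D box snoRNAs and the K-turn register

Box motif sets default to C: {RUGAUGA, AUGAUGA, AUGAUG, AUGAUU,
GUGAAG}, D: {CUGA, AUGA}, C′/D′: {UUGA, AUGA} — the canonical
consensus plus the noncanonical variants observed in nucleomorph
snoRNAs. A candidate requires a C box starting within 12 nt of the 5′
end, a D box ending within 12 nt of the 3′ end, a candidate length of
50–250 nt, and a valid K-turn. An internal D′ box with a C′ box 2–12 nt
downstream is optional (the C′ motif is shortened in several
nucleomorph snoRNAs; the spacing bound is a conservative envelope since
spacing conventions are cited without numbers). No terminal closing
stem is required — the rule set never invokes one.

The K-turn register pairs C-box positions 3–6 with D-box positions 4–1
(1-based from each motif's 5′ end). This register is reconstructed from
three worked box pairs rather than copied from a published table —
it is the only register consistent with all three:

* canonical `AUGAUGA`/`CUGA`: sheared G–A pairs at (C3,D4) and (C4,D3),
  U–U at (C5,D2), Watson–Crick G–C at (C6,D1);
* `AUGAUU`/`AUGA`: the two substitutions are compensatory, restoring a
  Watson–Crick U–A pair at (C6,D1);
* `GUGAAG`/`CUGA`: the 5′ G is the eukaryotic purine consensus at an
  unpaired position, and A–U replaces U–U at (C5,D2).

Validity requires exactly the two sheared G–A pairs, a Watson–Crick
(C6,D1), and (C5,D2) ∈ {U–U, Watson–Crick}; a C–U pair there
invalidates, mirroring the biochemical evidence that it abolishes
L7/Snu13 binding. A 7th C-box nucleotide is treated as bulged and never
pairs; both 6- and 7-nt C boxes are accepted because the bulge-vs-absent
question cannot be resolved from sequence alone.

Guide windows are the ≤ 20 nt immediately 5′ of the D and D′ boxes,
truncated at the nearest upstream box so guides never overlap boxes.

# The +5 rule and target prediction

A guide of length *L* slides along each target; a window is accepted
when it forms an antiparallel, contiguous (bulge-free) duplex with at
least *L*−1 paired positions (Watson–Crick + G·U), at most 1 mismatch
and 2 G·U pairs, and a strictly Watson–Crick pair at the +5 position.
The methylated nucleotide is the target base paired with the guide base
at offset 5 counting the box-adjacent base as offset 1 — with the
antiparallel register, 0-based position `target_window_start + 4`.
Bulged duplexes are a known limitation of this first version; the
published duplex figures show contiguous pairing, and strict defaults
deliberately under-call relative to permissive target predictors. Every
emitted site is re-checkable against the +5 invariant, and the suite
does so.

Cross-species transfer uses a multiple alignment of the target RNAs:
bijective maps between ungapped positions and alignment columns
translate a site to a reference species; a site is *conserved* when its
column carries an experimentally characterized reference site, and the
guiding snoRNA is flagged a *homolog* when additionally the two guides
are ≥ 70% identical in a 3′-anchored comparison — a sequence-identity
stand-in for covariance-model homology, which is out of scope.
Reference tables are snOPY-style TSV; nothing is fetched from the
network.

# Spliceosomal snRNA rules

Each called locus can be evaluated under each kind; the mandatory rules
are:

* **U1** — within the first 12 nt, a window whose reverse complement
  matches the donor consensus GUAAGU exactly (the 12-nt window is a
  package choice standing in for figure geometry).
* **U2** — the branch-point interaction motif (default `GUAG`) in the
  5′ half, plus ≥ 2 intermolecular helices with U6 of ≥ 6 bp. The
  canonical description has three U2:U6 helices; under a contiguous-run
  model helices Ia/Ib frequently merge, so ≥ 2 is the faithful
  relaxation. ("Intramolecular" in some descriptions of U2:U6 helices
  is read as intermolecular, which is what the structures show.)
* **U4** — two helices with U6 of ≥ `u4_helix_min` (10) bp with a
  hairpin folding in the inter-helix spacer. The U4/U6 helices are
  extensive (11 and 16 bp in the cryptophyte pair), while short WC+G·U
  runs against a ~100-nt U6 arise by chance: the expected number of
  6-bp-compatible runs between random 120-nt and 68-nt sequences is in
  the tens, so a 6-bp threshold would make the rule vacuous. At 10 bp
  random 120-nt sequences fail the U4 architecture in > 99% of draws
  while the genuine helices pass with margin. A K-turn-style note on
  the stem-flanking bases is reported but is descriptive, not
  mandatory.
* **U5** — loop I `UGCCUUUUACY` within ≤ 6 mismatches, flanked by a
  stem of ≥ 4 pairs. Six mismatches in an 11-nt motif is
  near-saturating — on its own it matches somewhere in almost any
  sequence — so the discriminative power rests on the flanking-stem
  requirement, which is a package addition and is flagged as such.
* **U6** — `ACAGAGA` present plus an Lsm-style 3′ U-tract (≥ 4 U in the
  last 10 nt).

An Sm/Lsm-site consensus (default regular expression `[AG]AU{4,6}G`,
configurable) is searched in the 3′ third for every kind and reported,
but never vetoes: no published consensus is stated for these genomes,
and inventing a hard rule would be worse than reporting evidence.

In the pipeline, U6 is detected first (its rule needs no partner), and
the detected U6 — or a user-supplied one — serves as the pairing
partner for the U2/U4 rules. When several detectors fire on one locus
the documented precedence is snoRNA > snRNA > orphan, with the conflict
recorded; in practice the conflicts observed are snoRNA loci that also
clear the near-saturating U5 loop rule.

**Branch points.** For an intron ending in AG, motif occurrences
(default `DURAU`, D = A/G/U; classical `YURAC` as fallback) whose 3′
end lies 2–6 nt from the intron 3′ end are tested: an adenosine within
the motif is bulged out, and the call stands if the remaining bases of
a window covering the motif pair contiguously (Watson–Crick) with a
substring of the U2 branch-point region — longer pairings are preferred
and may extend beyond the 5-nt motif, exactly as branch-point helices
do. The 3′-most valid motif (and within it the 3′-most valid A) is
returned, matching the observed positional bias. A census utility
counts motif-bearing introns for survey-style summaries.

# Differential expression

Reads are assigned to loci when ≥ 50% of the read interval overlaps
(same strand), multiplicity-weighted. CPM divides by library size; TPM
additionally by locus length, each library rescaled to 10^6. The
light/dark contrast excludes TE-treated libraries — the treatment is a
biochemical selection, not a biological condition — and requires ≥ 2
replicates per condition. A locus is differentially expressed when
|log2FC| ≥ 1.3 and BH-adjusted FDR < 0.05; these thresholds are
preserved exactly.

The default engine is the edgeR negative-binomial exact test with TMM
normalization and tagwise dispersion — the standard engine for
small-count sRNA designs. A Welch t-test on `log2(CPM + 0.5)` is
available (`method = "welch"`) and is the simpler reference
implementation, but at 2–3 replicates with ~30 loci its power is far
below the exact test's (a 6-fold induction at dispersion 0.1 survives
BH correction in only ~a quarter of replicate sets under Welch, versus
essentially always under the exact test), so the exact test is the
default. Under the exact engine the reported fold change is computed on
TMM-scaled CPM: a strongly induced locus inflates its libraries' totals
and would otherwise depress every other locus's raw-CPM fold change by
~0.2 log2 units, inflating false flags near the threshold. The
pseudocount of 0.5 guards fold changes against zeros.

# The synthetic study

The generator emulates a nucleomorph-like study at toy scale, and its
defaults are the study conditions: a 120-kb genome over 3 chromosomes;
80 CDS genes of 450–1200 nt with geometric intergenic spacers of mean
130 nt (minimum 20 nt); one rRNA set (SSU 1500, LSU 2900, 5.8S 160 nt);
20 C/D snoRNAs (~30% carrying the noncanonical box variants) whose D
and D′ guides are exact reverse complements of random rRNA windows, so
every planted +5 site is known and self-consistent; the five snRNAs;
5 orphans, the first induced 6-fold in darkness; and one 34-nt
truncated snoRNA pseudogene lacking the C′/D boxes, planted silent as a
detector negative control. A fifth of the expressed sRNA genes overlap
a flanking CDS by 13–43 nt; the overlap is realized by extending the
CDS annotation interval over the sRNA end, leaving the genome residues
— and hence the planted RNA sequence — untouched, which is equivalent
for every interval-based rule. Libraries follow 2 conditions ×
2 replicates (3 in the DE validation experiments) plus one TE-treated
library; counts are negative binomial (mean 200 reads/locus, dispersion
0.1, Poisson at dispersion 0); TE retention is 0.9 for capped and 0.05
for monophosphate loci; read lengths are 18–76 nt with geometric 5′/3′
end offsets (p = 0.15), half the reads anchored at each locus end; and
uniform background reads at 10% of the pooled calling threshold test
the noise-rejection rules. All draws flow from one seeded generator, so
a run is reproducible from its seed.

Two deliberate design choices in the generator: the snRNA sequences are
*fixed*, hand-designed sequences carrying exactly their kind's defining
elements — spliceosomal snRNAs are strongly conserved, and fixed
sequences make the truth classes well-defined at every seed; and orphan
loci are rejection-sampled until they fail every detector, which is
what "orphan" means as a ground-truth class. Planted snoRNAs are
re-detected by the package's own assembler before being accepted, which
enforces the guide/box self-consistency invariant at generation time.

What passing on synthetic data does *not* show: the generator has no
sequencing errors, no adapters, no multi-mapping ambiguity (the
question of once-vs-fractional counting of multi-mappers is deferred to
the data producer; the BED dialect carries pre-collapsed counts), no
empirical read-length or 5′-offset distributions (the geometric model
is a stand-in, exposed as configuration), and planted guides are
perfect complements, so duplex thresholds are not stressed by divergent
real guides. Results on real libraries will degrade in proportion to
how far those assumptions are violated.

# Numerical and degenerate-input choices

Ties in pattern matches resolve to fewer indels then leftmost end;
box selection in snoRNA assembly takes the 5′-most C (longest match at
that position) and 3′-most D; branch-point ties resolve 3′-most;
helices nested inside a longer helix on both molecules are not reported
as distinct; zero-length pattern matches are excluded; an empty TE
library gives zero signal (not NaN) in cap inference; a zero-variance
Welch contrast returns p = 1 (equal means) or 0; all-zero count columns
are an error in normalization. Genome generation validates that the
requested features fit (`genome too small` otherwise), and spacer
drawing reserves the minimum gap for all remaining elements so layout
cannot overflow.

# Problem sizes in the test suite

The suite validates oracle equivalence on 200 random instances per
primitive (subjects ≤ 200 nt, budgets ≤ 2; helix pairs ≤ 80 nt), runs
the full default study at seed 42, Monte-Carlo checks cap-status
inference (200 simulations) and the dark-locus detection rate (100
re-simulated replicate sets at 3 replicates/condition), and uses a
40-kb reduced configuration for module-level simulation tests. These
sizes were chosen to exercise the asymptotic behaviour of each rule
while keeping a full run to a few minutes.

# Known limitations

* Guide–target duplexes are bulge-free; permissive, bulged duplex
  models would call more (and less certain) sites.
* H/ACA snoRNAs and pseudouridylation are out of scope (nucleomorph
  genomes appear to lack that machinery).
* The U5 rule's specificity rests on the flanking stem, not the
  near-saturating loop motif.
* Locus boundaries are an end-trim heuristic, not a transcription
  start/termination model.
* Homolog flags rest on guide identity, not covariance models.
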