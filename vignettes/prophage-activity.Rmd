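---
title: "Identifying prophages and measuring their packaging activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying prophages and measuring their packaging activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prophactr)
```

# The problem and the measurement model

A lysogenic bacterium carries one or more prophages integrated in its
chromosome. After induction, an *active* prophage produces particles
that package DNA; sequencing the DNA that survives nuclease treatment
of the lysate (particle-protected DNA) and mapping it back to the
chromosome turns "which loci still make particles?" into a coverage
question. Two packaging modes leave different signatures:

* **Specific packaging** — a functional temperate phage packages its
  own genome. Reads pile up on one locus; coverage elsewhere is
  limited to residual host DNA.
* **Random packaging** — PBSX-like defective phages package ~13 kb
  fragments of the host chromosome indiscriminately. Reads spread over
  the whole genome, modulated only by DNA abundance (origin-proximal
  regions are over-represented in replicating cells).

`prophactr` implements the full workflow: candidate prediction from
phage-protein homology, boundary evidence (GC deviation, flanking
direct repeats), protein-based classification, and coverage-based
activity statistics, plus a generator of synthetic ground-truth data.

# Coordinates and genome model

All coordinates are 1-based and fully closed (GenBank convention): a
region `start..end` has `end - start + 1` bases. This convention is
pinned by the published PBSX-like region BLi_Pp2, whose printed
coordinates 1,317,754–1,345,262 reproduce its printed size of
27,509 bp only under 1-based inclusive arithmetic:

```{r}
pp <- dsm13_prophages()
pp[pp$label == "BLi_Pp2", ]
region_length(1317754, 1345262)
```

BED input/output is converted at the boundary; internally everything
is 1-based inclusive. GC content is `100 (G+C) / (A+C+G+T)`; `N`
bases are excluded from numerator *and* denominator so assembly gaps
cannot bias the value (a choice that matters only for draft genomes).

For the other published regions the printed sizes refer to the
sequence *between* the insertion repeats and are therefore smaller
than the coordinate span; the package reports the span and the repeat
coordinates separately and does not attempt to reproduce those printed
sizes.

# Candidate prediction

Prediction follows the classical hits-per-prophage / hit-spacing
parameterisation:

| parameter | default | meaning |
|---|---|---|
| `min_aa` | 50 aa | minimum ORF protein length |
| `min_similarity` | 30 % | full-length similarity cutoff for a hit |
| `max_spacing` | 5,500 bp | maximum midpoint gap within a cluster |
| `min_hits` | 5 | minimum hits per candidate |

ORFs are maximal open reading frames on both strands (starts
`ATG/GTG/TTG`, stops `TAA/TAG/TGA`, bacterial code, alternative starts
reported as `M`; the longest ORF per stop is kept). Each ORF protein
is searched against the phage protein database with an exact shared
4-mer seed gate (at least two distinct seeds) before any alignment is
attempted; this keeps the all-vs-all comparison tractable while being
a conservative superset of a BLASTP prefilter at this scale. The
original tool's BLAST E-value criterion (0.5) is replaced by the
workflow's own downstream cutoff — at least 30% similarity on the
full-length alignment — so a single score governs both prediction and
classification. Hit spacing is measured midpoint-to-midpoint, which is
robust to ORF length, and clustering is strand-agnostic because
prophage genes lie on either strand.

# Alignment and classification

"Full-length alignment" means a global (end-to-end) Needleman–Wunsch
alignment of both sequences, never a local hit. The engine is an
affine-gap Gotoh dynamic program (Rcpp) under BLOSUM62 with gap open
10 and gap extension 0.5; a gap of length $L$ costs
$10 + 0.5\,L$, end gaps included. On the traceback:

* identity = % of alignment columns with identical residues,
* similarity = % of columns whose residue pair scores positive in
  BLOSUM62.

Similarity is the workflow's currency: hits below 30% are discarded,
and inter-region comparisons are binned into the reporting classes
none (0–25], low (25–50], medium (50–75], high (75–100], with scores
above 30 flagged significant. Because co-optimal alignments exist, the
aligner canonicalises the argument order before the traceback so that
identity and similarity are exactly symmetric in the two sequences.
Best-hit ties are resolved deterministically (higher raw score, longer
subject, lexicographic subject id), which makes classification
invariant under database record order. The top-phage fraction of a
region is computed over *all* region proteins, including those with no
surviving hit. Proteins with no shared 4-mer seed in a partner region
are reported as class `none` without attempting an alignment.

The tests verify the engine against two independent oracles: the
dynamic-programming aligner in Biostrings (same penalties) and a
brute-force memoized recursion on short pairs.

# Flanking direct repeats

Integration by site-specific recombination leaves direct repeats
(attL/attR) at the prophage boundaries. The detector aligns the
500 bp windows centred on each boundary and reports the best ungapped
match with length ≥ 15 bp and at most 10% mismatches. "Best" is
defined in the trimmed-alignment convention: among match-anchored
windows (first and last position matching), the pair with the most
matching positions wins, ties going to fewer mismatches and then
position. A pure longest-window criterion would systematically absorb
flanking mismatches and report a planted exact repeat as a longer,
mismatched one; anchoring on matches keeps the reported repeat tight.
Even so, a repeat planted in random sequence is occasionally extended
by a coincidentally matching adjacent position — that is a property of
the sequence, not an error, and the exhaustive substring-pair oracle
in the test suite agrees with the detector on such cases. Output uses
the conventional `"61 -6 bp"` notation (length, then mismatch count).

# Coverage, NPKM and activity statistics

Only uniquely placed reads contribute to depth: records flagged
secondary or supplementary, or with mapping quality 0 (the common
multi-mapper convention), are excluded; unmapped reads are counted but
add nothing. Depth is accumulated over reference-consuming CIGAR
operations only.

NPKM (nucleotide activity per kilobase per million mapped nucleotides)
normalises a region's coverage for both region length and sequencing
depth:

$$\mathrm{NPKM} = \frac{\text{aligned nt in region} / \text{region
length in kb}}{\text{total aligned nt} / 10^6}.$$

Windows tile the genome from base 1; the final partial window keeps
its true length in the kb normalisation, which makes the kb-weighted
sum of all window NPKMs exactly $10^6$ — a conservation identity the
tests check numerically.

The signal-to-noise report uses mean per-base depth: signal over the
union of prophage bases, noise over the complement. The published
description ("counting the number of reads and dividing them by the
respective region size") conflicts with the same source's definition
of base coverage; the per-base-depth reading is used because it makes
the published table internally consistent — for every row,
$\text{noise\%} \times \text{ratio} = 100$ exactly before rounding:

```{r}
tab <- dsm13_coverage_summary()
within(tab, {
  ratio <- round(signal / noise, 1)
  noise_pct <- round(100 * noise / signal, 1)
})
```

**Active-region calling.** The background is the *median* of
per-window mean depths over windows not overlapping any candidate
region — median, not mean, so an origin-proximal coverage ramp or a
single hot locus cannot inflate it. A region is active when its mean
depth is at least 10× background; when genome-wide noise% exceeds
20%, all calls carry the `random_packaging_suspected` flag. The two
thresholds sit in the wide gap the published data show between
random-packaging-dominated runs (ratios 2.3–2.6, noise 38–43%) and
specific-packaging runs (ratios ≥ 24.5, noise ≤ 4.1%); both are
exposed as arguments.

# What the simulator emulates — and what it does not

`simulate_genome()` builds an i.i.d. background at the host GC
(default 46.2%), resamples each prophage interval at its own GC,
plants a direct repeat at the interval boundaries (right copy carrying
a configured number of substitutions), and inserts a cassette of
mutated phage genes back-translated with synonymous codons weighted
toward the region's target GC (so cassettes do not erase the GC
signature). `simulate_particle_reads()` draws one read per packaged
fragment: fragments come either uniformly from the designated locus
(specific mode; fragment length defaults to the region length —
headful packaging of the phage's own genome) or genome-wide with a
linear origin-proximity bias (random mode; mean 13 kb, the PBSX
packaging unit). The bias decays monotonically from the configured
fold at position 1 to 1× at the far end of the map; random-mode
fragments wrap around the circular chromosome so the bias is not
distorted by edge effects. Reads (default 100 nt) carry i.i.d.
substitution errors (default 1%, capped at the 2% a mapper
tolerates), and a configurable fraction (default 5%) of reads is
free host DNA drawn uniformly. Everything is deterministic in
`(config, seed)`.

Deliberately not modelled: indel and quality-profile error models,
paired ends, circularly permuted pac/cos packaging, in-situ
replication of induced prophages (the declining coverage tail
downstream of an active locus seen in real inductions), and
multi-contig assemblies. Passing tests therefore demonstrate correct
recovery under clean, known-truth conditions — not robustness to
every artefact of real libraries.

# Reference scenarios and problem sizes

Two desk-scale scenarios define the validation conditions (both:
500 kb chromosome, 50,000 single-end 100 nt reads, 1% errors, 5%
background DNA):

* **Specific packaging** (`specific_packaging_config()`): one 40 kb
  prophage at 230 kb. Evaluation adds six 40 kb decoy regions
  (`decoy_regions()`); the caller should mark exactly the planted
  locus active (sensitivity and specificity 1 across 20 seeds).
* **Random packaging** (`random_packaging_config()`): seven 31 kb
  prophage-like loci clustered in the origin-proximal 46% of the
  chromosome, packaged as 13 kb fragments with a 4-fold linear origin
  bias. This geometry was chosen analytically so that roughly 40% of
  packaged DNA originates outside the prophage loci: with loci
  covering fraction $p$ of the map and a linear $B$-fold bias, the
  expected in/out coverage ratio is
  $(B - (B-1)p/2) / (B - (B-1)(1+p)/2)$, about 1.8 for $p = 0.43$,
  $B = 4$ — the modest enrichment regime of a random packager, in
  which no locus should be called active and the random-packaging
  flag should always be set.

These sizes keep the whole validation (40 simulations plus property
suites) in the low minutes on a single core while leaving each
scenario's expected behaviour far from the decision thresholds.

# Known limitations

* Single-genome scope; comparative analyses (wild type vs deletion
  mutants) are done by running the activity analysis per SAM and
  joining the per-region tables.
* The classifier reports phage- and family-level votes only; deeper
  taxonomy is out of reach of best-hit voting on sparse databases.
* No statistical significance is attached to enrichment ratios; the
  workflow reports ratios, as the underlying method does.
* The in-silico PCR uses exact primer matching; primers with
  mismatches or degenerate bases find no sites.
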