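---
title: "Calling tRNA-derived fragments: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tRNA-derived fragments: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfcall)
```

## The biological model

tRNA genes are transcribed by RNA polymerase III into a precursor carrying
a 5′ leader and a 3′ trailer. Maturation removes both (RNase P and RNase Z
respectively), splices introns where present, and adds the untemplated
`CCA` to the 3′ end. Each processing boundary can release a stable small
RNA:

* a **tRF-5** begins exactly at base 1 of the mature tRNA;
* a **tRF-3** ends exactly at the mature 3′ end and therefore carries the
  added `CCA` — a sequence feature absent from the genome at that position;
* a **tRF-1** is the released trailer: it begins at the first base after
  the RNase Z cleavage site and ends within the Pol III termination signal,
  an encoded run of ≥ 4 U (T in the genome).

These precise ends are what distinguishes tRFs from the continuum of
degradation products that any abundant RNA sheds. `trfcall` turns the three
end rules plus an enrichment filter into a calling procedure.

One base of ambiguity exists in the literature for the tRF-1 5′ end
(discriminator base vs the first base after cleavage); since the reference
trailer here starts immediately after the annotated gene end, tRF-1s are
defined to start at trailer offset 0.

## Reference construction

Per tRNA gene the search space is the pair *(mature+CCA, trailer)*:

* mature = genomic span, introns spliced, reverse-complemented for minus
  strand genes, uppercased, U→T;
* `CCA` is *always* appended. If the genomic 3′ end already reads `CCA`
  (possible in bacteria, where CCA can be template-encoded) a per-gene
  warning is raised, since appending would duplicate it; the behaviour is
  deliberately not changed silently.
* trailer = the 50 nt genomically downstream in transcription orientation
  (truncated only at contig ends). 50 nt covers known Pol III terminator
  distances.

All internal coordinates are 0-based half-open; files are read and written
in their native dialect (BED 0-based, gtRNAdb-style 1-based) behind an
explicit flag.

## Exact mapping and genome exclusivity

A read counts as placed only if it matches a reference segment along
**100 % of its length with 100 % identity**. That criterion is exact
substring matching, so the implementation enumerates every substring of
every segment at the read lengths present and matches by hashing — fully
deterministic, no alignment heuristics, and verified in the test suite
against a brute-force all-positions scan on 10,000 randomized trials. The
index size grows with segment length × number of distinct read lengths,
which is negligible at tRNA scale (~125 nt per gene).

Reads are normalized (uppercase, U→T) before matching; reads containing
`N` cannot satisfy a 100 %-identity match and are excluded from mapping but
retained in the library total. Default mapped-length bounds are 14–40 nt,
the usual small RNA insert range.

A read that also occurs in the genome *outside* tRNA loci is discarded:
with exact matching, such a read cannot be attributed to tRNA processing.
Both strands are searched (deposited libraries are not reliably stranded).
Loci are extended by the trailer length downstream, so a trailer read is
not its own "outside" hit; a read hitting two different tRNA loci and
nowhere else is kept and reported with both parents, without splitting its
count. A heuristic aligner (e.g. BLAST at 100 %/100 %) would express the
same criterion; the exact-match search is preferred because it is
bit-reproducible and dependency-free.

## Site filtering: separating tRFs from degradation

Only three positions per gene can yield a call — mature offset 0
(tRF-5), mature end (tRF-3), trailer offset 0 (tRF-1). Everything else is
"internal" background. At each candidate site:

* **Dominant-read rule** (default threshold 0.80, configurable): the most
  abundant sequence must carry ≥ 80 % of the site's reads; failing that,
  the top two together may. Sites failing both yield nothing. Ties break
  by longer sequence, then lexicographically. The greedy one-or-two
  resolution has a documented boundary behaviour: at a high threshold a
  site can call two reads (top-1 alone fails, top-2 jointly passes) where
  a lower threshold calls only the top read, so strict monotonicity in
  the threshold holds for the top-ranked read and for site survival, not
  for the companion read. In shallow libraries the top-two branch can
  also call a trimmed companion alongside the planted read — visible in
  the differential example below.
* **Minimum site count** (default 2): a singleton read cannot be tested
  against an 80 % rule in any meaningful way, so singletons are not
  called.
* **Region concentration** is computed per gene (fraction of mapped reads
  on the three regions; empirically > 90 % in clean data) but is an
  *advisory* QC flag only: the hard rule is positional, concentration
  below 0.90 flags the gene without rejecting its calls.

## Naming

IDs are sequential per class in discovery order — 5001, 5002, … for
tRF-5s; 3001, …; 1001, … — held in a persistent registry so a sequence
keeps its number across libraries and runs; identical sequences from
multiple parent genes are a single record. Discovery order within a run is
fixed and documented: libraries in input order; within a library by parent
gene order in the annotation, then region (5′, 3′, trailer), then
abundance. Length subclass letters (tRF-5: a/b/c around 15/22/31 nt, bin
edges 18 and 26; tRF-3: a/b around 18/22 nt, edge 20) are appended only
when a parent gene carries two or more distinct tRFs of the class; tRF-1
lengths are set by terminator distance and carry no letter. The "~" nominal
lengths are the field's; the bin edges are this package's (midpoint)
choice, configurable. tRF-1 calls are annotated with a terminator flag:
TRUE if an encoded T-run of ≥ 4 overlaps the window [end − 4, end + 2]
around the fragment's 3′ end.

## Quantification and group comparison

RPM = count × 10⁶ / library total, where the denominator is the total
read count of the trimmed input library (configurable to mapped-only; the
total-reads convention is computable without the genome and matches common
practice). RPM is rendered to 2 decimals in TSV and kept at full precision
in JSON. The expression matrix has one row per tRF ID and one column per
library, zeros for absences.

Group comparison reports per-tRF group-mean RPMs, a detection filter
(> 20 RPM in at least one group mean, configurable to per-library
variants), and log₂((mean_B + 1)/(mean_A + 1)) — the 1-RPM pseudocount
stabilizes fold changes of barely detected fragments. **No p-values are
reported**: the design this mirrors has two replicates per group, where
formal inference would be decorative. Class summaries give median log₂
fold change and up/down/flat counts at |log₂FC| ≥ 1 per class.

## The synthetic world

The simulator states an explicit, fixed world rather than a tunable one:

* ~72-nt genes with 50-nt trailers, placed with random 40–80 nt spacers on
  a random contig, alternating strands (so strand-aware extraction is
  always exercised); a TTTT tract is written under each planted tRF-1 3′
  end.
* Planted fragments at the three canonical positions with set weights;
  the default scenario plants eight tRFs on six genes, including
  same-parent length pairs so subclass lettering is exercised.
* **Noise model**, shaped to reproduce real pileup phenomenology:
  `trim_fraction` (default 0.10) of each planted tRF's reads are 1–3 nt
  3′-shortened copies (nucleolytic nibbling at the dominant fragment);
  `noise_fraction` (default 0.05) of the library is uniform internal
  fragments of 14–30 nt (random degradation). Expected site dominance is
  therefore ≥ 0.85, comfortably above the 0.80 rule.
* Optional **decoys**: exact intergenic copies of planted sequences, which
  the exclusivity filter must drop.
* Optional **background pool**: non-tRNA reads (random 20–24-mers mapping
  nowhere on the reference) that inflate the RPM denominator only. Real
  small RNA libraries are dominated by non-tRF species; without this pool
  a strong tRF-1 induction renormalizes the denominator so heavily that
  observed fold changes compress far below the true induction and
  tRF-5/-3 appear spuriously down. The differential scenario therefore
  uses background weight 80 against 20 planted (tRF-5/-3 weight 1 each,
  tRF-1 weight 0.005 each, ten tRFs per class, 2 × 10⁵ reads per library,
  two libraries per group), which keeps denominator drift below ~20 %
  while leaving tRF-1 baselines comfortably above the 20 RPM detection
  line.

What a green recovery test establishes: under dominant planted fragments
with ≤ 15 % combined trim+internal noise, the caller returns exactly the
planted set with correct classes, parents and subclasses. What it does not
establish: behaviour under adapter contamination, sequencing error
(simulated reads are error-free), tRNA modifications causing RT stops or
misincorporation, or references with near-identical paralogous loci beyond
the exact-duplicate case (which is covered).

## Numerical and degenerate-input choices

* Coordinates: internal 0-based half-open everywhere; conversion only at
  file boundaries.
* Empty references and empty alignment sets flow through and yield empty,
  correctly-typed tables; a zero library total is a hard error (RPM
  undefined).
* A read spanning an entire mature+CCA satisfies both end rules and is
  labelled tRF-5 (documented tie-break; such reads exceed normal insert
  bounds anyway).
* Seeds: every simulation entry point takes an explicit seed; per-library
  seeds derive from the master seed by small integer offsets.

## Known limitations

* 5′ leader fragments and stress-induced tRNA halves are out of scope, as
  is seed-based family grouping.
* The exclusivity filter assumes a complete genome; unassembled paralogs
  invisible to it could let a non-exclusive read through.
* ID stability across species is not coordinated; registries are per
  species.
* With two replicates per group the comparison module is descriptive; any
  inferential claim needs more replicates and a count-based model.
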