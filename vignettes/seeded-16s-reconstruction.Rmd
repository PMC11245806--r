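---
title: "Seeded reconstruction of 16S rRNA genes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded reconstruction of 16S rRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

`seedrecon` reconstructs near full-length 16S rRNA genes by anchoring
shotgun metagenome read pairs to amplicon OTU centroids ("seeds") from the
same samples. The method rests on three assumptions:

1. **Co-sequencing.** Amplicon and shotgun libraries come from the same
   DNA, so an abundant amplicon OTU implies its source genome is abundant
   in the metagenome reads of that sample.
2. **A 99% OTU radius captures one genome's 16S variants.** Bacterial
   genomes carry several rRNA operons whose 16S copies differ slightly;
   clustering at 99% keeps those copies in one OTU while still separating
   most species.
3. **Careful read curation beats assembler cleverness.** The failure mode
   of 16S recovery from short-read metagenomes is the mosaic: conserved
   regions recruit reads from many taxa and the assembler stitches
   chimeric genes. The method therefore pushes its stringency into *which
   pairs enter each bin*, and keeps the assembly itself conservative.

### Recruitment model

Each mate is aligned locally to each seed (affine-gap Smith–Waterman;
match +2, mismatch −3, gap open 5, gap extend 2 — a blastn-like scheme).
Identity is defined as matches / alignment columns with gap columns
counting as mismatches, i.e. the blast `pident` convention. A hit
survives if:

* identity ≥ `min_identity` (default **98%**, one point below the
  clustering radius, so reads from minority 16S copies of the same genome
  are still collected);
* alignment length ≥ `min_aln_len` (default **50 nt**; excludes spurious
  short local hits — there is no canonical value for this cutoff, so it is
  exposed as a parameter);
* the **geometry rule** holds: the alignment covers the whole read (up to
  `read_cover_tol` = 5 nt), or it abuts a seed terminus (within
  `end_tol` = 5 nt) with every unaligned read portion longer than the
  tolerance hanging *off* that terminus. Reads that stop partway inside
  the seed are exactly the conserved-region strays that seed mosaics, and
  are discarded.

A pair's matched set is the union of seeds hit by either mate; the pair is
assembled as a unit, so multiplicity is counted per pair. Sets larger than
`max_matches` (default **3**) are discarded; otherwise the pair goes to
the matched seed with the largest amplicon relative abundance in its own
sample (ties to the lexicographically smallest seed id, making runs
deterministic). "Matches equally well" is interpreted as *all
geometry-passing matches compete*: the cap-and-abundance procedure is
defined purely by match counts and abundance, and a score-tie-only rule
would leave most multi-matches unresolved.

An exact k-mer prefilter (`prefilter_k` = 15) skips mate–seed pairs that
share no 15-mer. At 98% identity a 150 nt read has at most 3 mismatches,
so by pigeonhole some exact run of ≥ 37 nt — hence a 15-mer — always
survives; the prefilter is lossless at the default thresholds, and an
exhaustive mode exists for verification.

### Seeded assembly

The seed is a trusted backbone: never edited, only extended. At each step
the extender aligns mates to the current contig terminus (k-mer anchored,
`k` = 31), takes the reads whose alignments overhang the end, and appends
the per-position majority base while (a) support ≥ `min_cov` (default
**3** reads) and (b) the dominant base outweighs the runner-up by
`branch_ratio` (default **3**). On ambiguity the extension *halts* rather
than forks — conservative truncation is preferred to mosaic risk. Both
ends alternate until neither grows or `max_len` (1700 nt) is reached.
Contigs ≥ `min_report_len` = **800 nt** (more than half a full gene;
boundary inclusive) are reported. An optional hook runs an external
seeded assembler per bin instead; it is not exercised by the test suite.

### Chimera model

Reported contigs are screened with a deliberately simplified two-parent,
single-crossover model: per-position match profiles against every parent
(end-gap-free global alignments), best single-parent identity I1, best
spliced identity I2 over ordered parent pairs and crossover points scanned
every 10 nt. A contig is flagged when I2 − I1 ≥ 2 percentage points and
the two parents are themselves ≤ 97% identical. This is uchime-inspired
but is *not* a reimplementation of vsearch's verdicts; parents should be
length-comparable to the query (the pipeline uses the reported contigs as
each other's parent pool).

### Evaluation definitions

Two identity definitions coexist deliberately: recruitment uses *local*
identity (can a read plausibly belong to this seed's gene?), while
reconstruction success uses *end-gap-free global* identity of contig vs
truth gene (does the whole reconstruction match?). A pair is *correct* if
its provenance genome equals the genome of its assigned seed —
genome-level, so recruitment across 16S copies of one genome is correct,
and for multi-copy genomes whose copies straddle the OTU radius,
cross-copy recruitment still counts as correct.

## The simulator: what it emulates, and what it does not

`simulate_community()` builds genomes around a single 16S template of
alternating conserved (90 nt) and variable (50 nt) blocks. Conserved
blocks are shared by all genomes; variable blocks are substituted per
genome at a rate drawn uniformly from 0.04–0.15, spreading inter-genome
16S identities over roughly 88–97% — inter-species distances, with the
closest pairs approaching congeneric similarity. Each genome carries 1–3
copies (≥ 99% mutually identical, substitution rate 0.002 between
copies) embedded verbatim in a random backbone ≥ 20× the gene length, so
most shotgun reads are non-16S. Per-sample abundances are i.i.d.
exponential draws, normalized; *low-diversity* samples first raise the
draws to the power 3 (exponent tempering preserves the exponential origin
while letting the top genomes dominate, matching the "most abundant
species dominate" description of low-diversity samples).

Shotgun fragments are drawn proportionally to abundance × genome length,
insert ~ Normal(300, 30) truncated at 280 nt, mates are the fragment ends
(mate 2 reverse-complemented), with substitution errors only (indel rate
is a parameter defaulting to 0). Amplicons are emitted as already-merged
~440 nt products of a fixed window (offsets 420–860 of the gene, with the
window boundaries inside conserved blocks, as real V3–V4 primers are);
per-base amplicon error defaults to 0 because seeds stand for *denoised*
OTU centroids, and amplicon error mainly inflates dereplication. The same
per-sample abundance vector drives both libraries, which co-sequencing
implies. Every read header carries `genome=<id>` (and `locus=<copy>` when
the fragment overlaps an rRNA locus), so recruitment can be scored
exactly.

The simulator does **not** model realistic Illumina quality profiles, PCR
chimeras, indel-rich error modes, or inter-genome identities above ~97.5%.
Consequently, passing tests demonstrate the *logic* of the method —
separability, threshold behaviour, coverage-to-length scaling — on clean,
controlled communities; they do not certify performance on real
environmental data, where closer 16S pairs, uneven coverage and chimeric
amplicons all make recruitment leakage worse.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| clustering `identity` | 0.99 | fraction | one-genome 16S radius |
| `min_identity` (recruit) | 98 | % | correct reads drop beyond 98 when errors are present |
| `max_matches` (m) | 3 | seeds | recovers conserved-region pairs at modest incorrect cost |
| `min_aln_len` | 50 | nt | excludes spurious short local hits |
| `end_tol`, `read_cover_tol` | 5, 5 | nt | slack in the geometry rule |
| `prefilter_k` | 15 | nt | lossless at 98% / 150 nt |
| assembly `k` | 31 | nt | anchor specificity vs error tolerance |
| `min_cov` | 3 | reads | consensus support per extended base |
| `branch_ratio` | 3 | ratio | halt-on-ambiguity threshold |
| `min_report_len` | 800 | nt | > 50% of a full gene, inclusive |
| success identity | 99 | % | reconstruction success criterion |

## Design choices that were genuinely open

* **OTU abundance statistic.** Seeds are ranked by *maximum* per-sample
  relative abundance, matching the sample-selection walk (which pairs each
  top OTU with the sample where it peaks); a mean would blur exactly the
  per-sample dominance the walk exploits.
* **Order of novelty filtering.** The pipeline filters known seeds before
  top-K selection by default (`filter_known_first`), since the novel ones
  are the reconstruction targets; the reverse order — keep the top K
  regardless, as a sanity check against references — is a flag.
* **Recruitment from raw reads.** Reads are recruited without quality
  filtering; all filters act on alignment identity, and the 98% threshold
  already rejects error-heavy alignments. Quality strings are carried
  through to the bins untouched.
* **Pair-level multiplicity.** Collection, binning and assembly are all
  pair-level, so the cap counts seeds matched by *either* mate and the
  pair moves as a unit.
* **Built-in extender instead of an external assembler.** The method's
  novelty is read curation, not assembly; any competent seeded assembler
  suffices, and a self-contained extender keeps every result verifiable
  offline. The external hook remains for users who want it.

## Numerical and degenerate-input behaviour

Identity of an empty alignment is `NA` and never passes a threshold.
Empty bins fail with reported length 0 (the y = 0 dots of the
pairs-vs-length picture). Chimera pools with fewer than two usable parents
return `clean` by definition. All ties — centroid founding order,
assignment, crossover scan — break lexicographically or by fixed scan
order, so identical inputs give byte-identical outputs; `run_all()`
records an md5 manifest and rerunning a configuration reproduces it
exactly. Thread count is not a parameter of any numerical path.

## Problem sizes

The package's own studies run at desk scale, chosen so a full simulation,
recruitment and assembly cycle completes in minutes on one CPU: 10–20
genomes, 2–8 samples, a few thousand read pairs per sample, with 150 bp
shotgun pairs and 2000 amplicons per sample. Every size is a parameter;
the same code paths scale to larger communities linearly in reads ×
candidate seeds (the k-mer prefilter keeps the candidate set small).

## Known limitations

* Conserved blocks flanking the amplicon window recruit short
  terminus-overhang alignments from related genomes; under the
  multiplicity cap with abundance tie-breaking a few percent of assigned
  pairs can be misassigned (the acceptance script computes this rate —
  `m3_incorrect_pct` — on every run). Strict uniqueness (m = 1) removes
  them at the cost of correct pairs, mirroring the method's own
  uniqueness-vs-abundance trade-off.
* Reconstruction reach from recruitment alone is bounded by the insert
  length: only pairs with a mate touching the seed are collected, so a
  single round of recruitment extends roughly one insert beyond each seed
  end. Full-length recovery needs the deeper bins that abundant taxa
  provide.
* The chimera model scans a single crossover; interleaved multi-segment
  mosaics are out of its reach (they are instead prevented upstream by the
  geometry rule and halt-on-ambiguity extension).
* Identity from the affine-gap aligner depends on the scoring scheme; the
  shipped scheme is blastn-like, and other schemes shift identities by
  fractions of a percent near thresholds.
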