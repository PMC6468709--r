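---
title: "Detecting conserved intronic sequences: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved intronic sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscover)
```

## The problem

Orthologous protein-coding genes keep recognisable exons across all
vertebrates, while their introns are usually re-edited to the point where
no alignment survives. The interesting exceptions are conserved intronic
sequences (CISs): intronic segments that remain alignable between species
separated by hundreds of millions of years — zebrafish versus chicken,
mouse and human spans roughly 400 million years, chicken versus the two
mammals roughly 310, mouse versus human roughly 100. Some CISs are
exonized in particular transcript variants, and single-nucleotide
differences between related species can create or remove stop codons in
the resulting reading frames. `ciscover` implements the detection rule,
the conservation accounting, and the codon-level analyses as one tested
pipeline, and ships a simulator that generates orthologous families with
known planted truth so the pipeline can be validated end to end.

## The detection model

A candidate segment must survive four filters.

**Corresponding introns.** Reference transcripts are chosen to have
superimposable exon–intron arrangements, so introns correspond by ordinal
position. When two species' reference transcripts differ in exon count
(for example one species fuses two exons), `correspond_introns()` aligns
the exon-length vectors globally — similarity of exons with lengths $a$,
$b$ is $-|\log(a/b)|$, gap penalty 1.0 — and pairs introns whose upstream
exons are aligned. The log-ratio score makes the pairing insensitive to
uniform length scaling, and the gap penalty of 1.0 means an exon is left
unpaired whenever no partner within a factor of about $e$ in length is
available. These two constants are pipeline choices; the published
procedure only states that reference transcripts were selected to be
superimposable.

**Local alignment.** `local_align()` is a seed-and-extend aligner in the
BLAST mould: exact-match words (default length 11) outside masked
intervals, grouped by diagonal, extended in both directions by banded
(half-width 40) affine-gap dynamic programming under an X-drop rule
(cutoff 30). Scoring defaults are the classic nucleotide-BLAST values
(match +2, mismatch −3, gap open 5, gap extend 2, a gap of length $L$
costing $5 + 2L$); the original analysis used the NCBI pairwise BLAST
service without reporting parameters, so the classic defaults are the
natural reconstruction. All sequences are held in transcription
orientation and only same-orientation alignments are ever computed, which
implements the Plus/Plus requirement by construction; reverse-strand hits
would have been discarded anyway. `N` bases never match and never seed.
The unit tests hold the extension to account against an independent full
Smith–Waterman dynamic program (Biostrings): with an exhaustive word size
of 4 the seeded aligner reproduces the exact optimum on ≥ 95% of random
60-nt pairs (the word size is lowered there because the short optimal
alignments of unrelated 60-mers rarely contain an exact 11-mer; band and
X-drop stay at their defaults).

**Low-complexity masking.** `mask_low_complexity()` is a DUST-style
filter: for a 64-nt window the score is
$\sum_t c_t (c_t - 1) / 2 \,/\, (w - 2)$ over the window's
overlapping-triplet counts $c_t$, and windows scoring above 2 are merged
into maximal masked intervals. Masked positions are excluded from seeding
but may be crossed by extension, so a conserved segment flanking a
microsatellite is still reported in full.

**Significance.** Each alignment's E-value is
$E = K m n e^{-\lambda S}$ with $m$, $n$ the full intron lengths. For
ungapped scoring, $\lambda$ is the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$, found by bisection to 1e-9.
Gapped constants have no closed form, so the pipeline uses
`empirical_evalue_calibration()`: 500 pairs of i.i.d. random sequences of
length 500 are aligned under the full scheme and the null score
distribution is fitted to the extreme-value form by the method of
moments (fixed calibration seed 101, bootstrap standard errors). Two
checks keep this honest: with gap penalties driven to infinity the
empirical $\lambda$ lands within 10% of the analytic ungapped value, and
the number of null alignments reaching $E \le 0.1$ matches its Poisson
expectation $N(1 - e^{-0.1})$ within three binomial standard deviations.
The significance threshold is $E \le 9 \times 10^{-10}$, **inclusive** —
an alignment at exactly the boundary is kept. At that threshold, random
3-kb intron pairs would need a score around 60, far above anything the
null produces, which is what makes zero false calls on unrelated introns
an achievable requirement rather than a tuning outcome.

**Order consistency.** When several alignments link one intron pair they
must appear in the same order in both introns. `chain_order_consistent()`
computes the maximum-weight subset whose query and subject start
coordinates both increase strictly, by weighted
longest-increasing-subsequence; weight is the number of aligned anchor
nucleotides, and ties prefer the upstream-most chain so output is
deterministic.

## Accounting

Conserved-nucleotide counts are **anchor-side unions** over all surviving
alignments, per target: each anchor position counts at most once even
when several alignments overlap it, which matches the per-target counting
style of the published tables. Percentages are
$100 \cdot \text{conserved} / \text{total intron pool}$, rounded half-up
to three decimals — the printed precision of those tables. Note that the
published zebrafish-anchored table contains two cells (chicken 0.273,
human 0.254) that are inconsistent with the stated denominator
(100·1287/472,638 = 0.272 and 100·1209/472,638 = 0.256); the package
implements the stated rule and reproduces the self-consistent cells.
Counting on the anchor side is not symmetric once alignments contain
gaps, so reports always state the anchor. Multi-species CIS calls are the
maximal runs of anchor positions covered in *every* target; runs shorter
than `min_cis_len` (default 30 nt) are discarded. Published CISs are ~100 nt
and longer, and no explicit floor was stated; 30 nt guards against spurious
micro-intersections while staying well below any reported segment.

The headline comparison — human versus mouse conservation of the chicken
intron pool — uses a two-sided Pearson chi-square test on
$((x_1, n-x_1), (x_2, n-x_2))$ without continuity correction, with
Fisher's exact test whenever an expected cell is 5 or fewer (the
chi-square approximation is excellent in the half-million-nucleotide
regime and any standard choice gives $p \ll 0.01$ there; the method used
is recorded in the result). Treating the two proportions as independent
samples of size $n$ is a simplification — both are fractions of the same
chicken pool — and is noted in the output.

## Exonization and codon analyses

`exonization_status()` intersects a CIS with each transcript variant's
exons and emits an event when at least half the CIS is expressed or the
overlap reaches 30 nt (the original description is qualitative; these
thresholds are package choices and are configurable). The expressed block
is checked for the canonical `AG` immediately upstream and `GT`
immediately downstream, the signature of a cleanly spliced supernumerary
exon. Reading frames follow the +1/+2/+3 convention: frame $+k$ starts at
offset $k-1$ of the segment. `translate_frames()` uses the standard
nuclear genetic code (all study species are vertebrates); codons
containing `N` translate to `X`. `detect_stop_skip()` compares two
pre-aligned sequences codon by codon after removing gapped columns and
reports every aligned codon where exactly one species has a stop —
the TAA→TTA and TAA↔TGG patterns seen between human/gorilla and
chicken/mammal transcripts. Frameshifting indels are reported separately
by `detect_frameshift_indel()` as gap runs of length ≢ 0 (mod 3); the
codon comparison does not re-thread frames across an indel, because the
two analyses answer different questions (changed residue versus changed
frame).

## The simulator

`simulate_family()` builds an ancestral gene per locus from random exon
(120–200 nt) and intron (2.5–3.5 kb) segments, plants conserved segments
(150–400 nt, whole codons) at random intronic positions, and evolves every
segment independently down the fixed tree
`(zebrafish,(chicken,(mouse,human)))` with branch lengths proportional to
400/310/100 million years. Substitutions follow Jukes–Cantor; per-feature
rates are chosen so the deepest species pair reaches ~70% identity in
exons, ~80% in planted CISs, and ~30% (near the 25% saturation floor) in
background introns. The 80% CIS identity figure sits between the reported
cross-vertebrate exon conservation (~70%) and the near-perfect identity
of the longest published intronic alignments, giving planted segments
that are clearly detectable yet far from trivial. Indels (Poisson events,
geometric lengths, rate 1e-4 per site per unit time) occur only in
background intron sequence: planted CISs and exons stay indel-free so
that truth coordinates and reading frames remain exact, which is what
lets the planted stop-skip and frameshift events be checked for *exact*
recovery. Background introns are evolved from a common ancestor rather
than drawn independently, so borderline similarity arises naturally and
genuinely stresses the E-value threshold. Canonical `GT`/`AG`
dinucleotides are written at every intron boundary. One global RNG stream
per simulation, seeded from the configuration, makes every family a
deterministic function of its seed.

Optional features plant: a tandem-duplicated 120-nt segment pair
(evolving at CIS rate, so the copies end ~80% identical — the situation
where one gene carries two ancient copies of what was once a single
sequence); a transcript variant that exonizes the first planted CIS with
`AG`/`GT` flanks; a stop-skip (human `TAA` versus mouse `TGG` at a
central codon, after removing chance stop differences between those two
copies so the planted event is the only one); and a single-nucleotide
insertion in the human copy of the last planted CIS. Stop-skip and
frameshift are deliberately assigned to different CISs whenever two or
more exist.

What the simulator does **not** emulate: real splice-site strength beyond
the boundary dinucleotides, base-composition drift between lineages,
rate heterogeneity along introns, transposon insertions, or anything
about the actual SLC25 sequences. Passing the planted-truth tests
therefore demonstrates that the machinery is correct under the stated
evolutionary model at desk scale, not that the pipeline would reproduce
database-scale counts on real genomes — those depend on the exact
sequences and alignment build used.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; GFF3 and the exported HSP
  report use the 1-based closed convention of those formats.
* Zero-length inter-exon gaps produce no intron (abutting exons model
  exon fusion).
* Percentages round half-up (away from zero), not banker's rounding, to
  match printed-table arithmetic such as 37.465 → 37.
* Equal-weight chains prefer the smaller anchor start-coordinate sum;
  equal-score HSPs order by coordinates — all output is byte-identical
  across reruns.
* The λ bisection requires a negative expected pair score and refuses
  schemes without one; empirical calibration refuses degenerate
  all-equal null scores.
* Self-alignment for duplication detection excludes seeds within 20
  diagonals of the main diagonal and requires disjoint copies.
* Problem sizes in the validation suite (five genes × six 3-kb introns,
  ten simulated families, 200 oracle pairs, 500 calibration replicates)
  were chosen as the smallest configurations at which all planted-truth
  and statistical checks are stable across seeds.

## Known limitations

* Gapped E-values rest on an empirical extreme-value fit; moment
  estimation on discrete scores has a small bias (the Poisson check
  bounds its practical effect).
* Intron correspondence uses exon lengths only; it will mis-pair introns
  between paralogues whose exon architectures coincide by chance.
* The exonization frame is reported relative to an annotated CDS start
  and is `NA` for transcripts without one; the package classifies
  transcript structures but never predicts them.
* Conservation accounting is anchor-side; anchor→target and
  target→anchor counts differ in the presence of gaps, exactly as in the
  published tables.
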