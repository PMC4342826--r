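---
title: "Methods and design of primarytx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of primarytx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`primarytx` annotates a bacterial primary transcriptome from two
stranded RNA-seq read-start profiles: a 5′-enriched library whose read
starts accumulate at transcription start sites, and a
whole-transcriptome paired-end library whose combined mate pairs trace
contiguous transcription. This vignette explains the models and
procedures, the parameters that matter, what the synthetic benchmark
does and does not show, and the design choices made where the design
was genuinely open.

## Coordinate conventions

All coordinates are 1-based and fully inclusive, on both strands
(`start` is always the leftmost base, as in GFF3). "Downstream" and
"previous position" are always meant in the direction of transcription:
the previous position of a plus-strand TSS at *p* is *p − 1*, of a
minus-strand TSS *p + 1*. A 5′-UTR length is the distance from the TSS
to the first base of the start codon, so a TSS sitting on the start
codon itself has length 0 and is classified as a (leaderless) utr-class
TSS, not as intragenic.

## TSS calling

A genomic position is called automatically when three criteria hold:

1. its read-start count exceeds the background threshold *T*
   (default 6, strict);
2. the ratio of its count to the previous position's count exceeds *R*
   (default 6, strict). A previous count of zero passes: a step from
   zero reads is the sharpest possible accumulation, and a ratio with
   zero denominator is otherwise undefined;
3. a same-strand protein-coding translation start lies 0–*X* nt
   downstream (default 500). Candidates failing only this rule are
   retained and routed to the novel-transcript path rather than
   discarded.

Manual curation of the original procedure is replaced by three
deterministic, auditable surrogates, each logged with position and
reason by the pipeline driver:

* **Rescue**: a position failing exactly one of (1)/(2) by at most
  `rescue_margin` reads (default 1) is added back when the
  whole-transcriptome coverage is at least `min_whole_tx_support` at
  each of the 20 positions starting at the putative TSS — the coverage
  confirms a transcript. The 20-nt window starts at the TSS itself
  because a transcript includes its first base.
* **False positives**: a candidate is flagged when its count is below
  `fp_peak_fraction` (default 0.5) of the maximum in a surrounding
  `fp_window` (default 50 nt) *and* at least three other positions in
  the window also exceed *T*. This operationalizes the qualitative
  "uneven gradient of accumulated read starts" rule; both
  sub-parameters are exposed because the qualitative rule admits more
  than one reading.
* **Stable RNA removal**: candidates whose nearest downstream
  same-strand feature within *X* is an rRNA or tRNA gene are removed
  (processed 5′ ends of stable RNAs are not primary TSSs).

The bookkeeping identity `automatic − false_positive − stable_rna +
rescued = final` is asserted in the tests.

## Classification, 5′-UTRs, novel transcripts

Classes are assigned with precedence utr > intragenic > antisense >
intergenic. The utr class requires a downstream TLS within *X* and the
TSS to lie outside all same-strand CDS bodies; a TSS inside gene A that
is also within *X* of gene B is therefore intragenic (the precedence
decides a case the classification scheme leaves open). Antisense
status consults, besides opposite-strand gene bodies, the detected
5′-UTR intervals and 3′-UTRs estimated by the same coverage extension
used for novel transcripts; classification is therefore two-pass.

The 5′-UTR median is the lower of the two central values for an even
count (so the reported median is always an observed length); the
histogram uses 5-nt bins 1–5, 6–10, …, 496–500 plus a final >500 bin,
and "near-leaderless" means a length below 10 nt.

Novel transcripts are delineated by extending downstream from the TSS
while whole-transcriptome coverage stays ≥ 1, tolerating uncovered gaps
of at most 5 nt (configurable; the choice is ours — the source
procedure is silent) and emitting only transcripts longer than 20 nt.
Intragenic sense TSSs in the first half of a CDS propose the nearest
in-frame ATG/GTG/TTG at or downstream of the TSS as a corrected start,
provided it precedes the CDS midpoint.

`feature_length()` offers the inclusive convention (|Δ| + 1) and a
bare-difference compatibility mode, because published feature tables
mix the two conventions; the package computes, it does not adjudicate.

## Motif discovery

`em_find_motif()` is a ZOOPS expectation-maximization search: each
sequence carries zero or one motif occurrence; the E-step computes
posteriors over all offsets and "no site", the M-step re-estimates the
position weight matrix with a per-base pseudocount (default 0.25), the
site prior γ, and — optionally — a shared offset distribution. The
objective it maximizes (and reports as a non-decreasing trace) is the
observed-data log-likelihood plus the Dirichlet penalty of the
pseudocounts.

Three design choices deserve explanation:

* **Position prior.** With `position_prior = "right"`, the offset
  distribution, indexed from the 3′ end of each sequence, is learned
  alongside the motif. Upstream windows are anchored — at the TSS for
  promoters, at the TLS for RBS elements — and the element-to-anchor
  spacing is the biologically constrained quantity, so the anchored
  prior is the correct model and sharpens localization substantially in
  A+T-rich windows where spurious hexamer matches abound. The default
  remains the classical uniform ZOOPS.
* **Seeding and refinement.** Restarts are seeded from the most
  frequent subsequence plus randomly sampled subsequences; after a
  short scoring pass the two most promising runs are converged and the
  winner refined over ±3 column shifts. All randomness flows through
  the `seed` argument; identical seeds give identical models.
* **Background.** The 0-order background is estimated from the input
  windows (appropriate for a low-G+C genome where a uniform background
  would be wrong) but shrunk 9:1 toward uniform, so a degenerate input
  composition cannot absorb the motif entirely.

`find_promoter_elements()` searches the −10 over full 70-nt windows,
then the −35 over the subsequence upstream of each −10 site. Because
both elements compete for one EM objective, the first-found motif is
identified geometrically: if its median spacer to the TSS exceeds
14 nt — outside the 4–10 nt range core −10 elements occupy — it is
taken to be the −35 and the −10 search is repeated downstream of its
sites. Spacers count the bases strictly between elements (and between
the −10 and the TSS). Consensus strings are case-coded with
frequencies relative to **all** analyzed sequences (upper case > 80 %,
lower case > 40 %, else `n`), so sequences without a confident site
weaken the consensus, as they should. The report of base frequencies
downstream of the −10 (the discriminator region) is descriptive only.
For RBS analysis each gene contributes one sequence; with several TSSs
per gene the longest 5′-UTR is used (the source procedure says "once"
without naming which) and genes with UTRs of 9 nt or shorter are
excluded.

## Operon inference

Adjacent same-strand genes are joined when at least `bridge_threshold`
(default 4) paired fragments bridge the junction, where bridging means
the fragment covers both the last base of the upstream gene and the
first base of the downstream gene — a fragment inside the gap alone
connects nothing. Overlapping same-strand genes are bridged by any
fragment covering the junction point. Intervening opposite-strand
genes neither bridge nor break a chain. Transitive joining yields
maximal chains (primary operons, members ordered in transcription
direction); utr-class TSSs at non-first members define suboperons as
suffixes of the member list. The "functionally related" manual
addition becomes an explicit optional rescue: a junction exactly
`functional_rescue_margin` fragments short is joined when both genes
share a supplied label, and the join is flagged. Genes in no chain are
monocistronic if any fragment overlaps them, untranscribed otherwise.

## Abundance (log-RPKM)

For a feature, over the *N* positions carrying at least one same-strand
read start, x̄ is the arithmetic mean of ln(read starts); R_norm =
e^x̄·N; the reported value is R_norm / (length_kb · mapped_reads/10⁶).
*N* counts covered positions, not feature length: the formula's side
condition ("if at least one read was mapped") makes ln 0 impossible,
and dividing the geometric mean by feature length would penalize sparse
coverage twice. The alternative reading is available by noting that
R_norm and *N* are both reported per record. Classes are
lower-exclusive: (0, 16] low, (16, 160] middle, (160, 1600] high,
> 1600 very high; exactly 0 is untranscribed. Totals are per replicon;
comparing abundances across replicons is deliberately unsupported.

## The synthetic benchmark

`sim_params()` fixes the study conditions; all defaults were chosen
once, from the stated experimental quantities where they exist:

* fragment sizes uniform on 100–800 nt; read-pair combining distance
  1 kb; 5′ peak rate 50 with Poisson noise over a Poisson background of
  0.2 read starts per transcribed position plus a small genomic floor
  (0.005) mimicking residual processed 5′ ends;
* 5′-UTR lengths: a 26–35 nt peak (22 %), a log-normal right tail
  (median ≈ 55 nt, capped at 450), and 0.5 % near-leaderless leaders of
  2–9 nt;
* spacers: −10↔TSS uniform on 4–10 (mean 7), −35↔−10 triangular on
  15–19 peaked at 17, RBS↔TLS uniform on 5–10 (mean 7.5); extended −10
  TG planted in 33 % of promoters (and chance TGs at that position
  scrubbed elsewhere, so the planted fraction is exact);
* planted element conservation mirrors the printed conservation of the
  real motifs: a strong TAtaaT-like −10 (0.9 caps, 0.65 middle), a weak
  ttgaca-like −35 (0.70 first half, 0.46 second), an aGGaGg-like RBS;
  start codons drawn at 75.5/13.9/10.6 % for ATG/TTG/GTG; genome
  composition A+T ≈ 61.4 %;
* operon sizes 1–8 (45 % single genes, mean ≈ 2.1), genes 600–1200 nt,
  intra-operon gaps 20–60 nt; every junction topped up to a planted
  bridging depth of 6 + Pois(2) fragments after natural sampling;
* four expression tiers (15/45/30/10 %) with whole-library read-start
  rates 0.016/0.1/0.8/5 per transcribed position and a nominal library
  size of 2 × 10⁶ mapped reads. The stored profile is the mapped
  subset on the simulated replicon while `total_mapped` carries the
  nominal size — this keeps per-million normalization meaningful and
  places tier values near the geometric centers of the four abundance
  classes (≈ 8/50/380/4500), so tier recovery measures classification,
  not luck at the class edges;
* a few tRNA units with their own strong TSS peaks act as decoys for
  the stable-RNA filter.

What the benchmark does **not** emulate: sequencing error and quality,
condition mixtures (the real libraries pool many growth conditions),
overdispersion beyond Poisson, RNA secondary-structure effects on
library preparation, processed-RNA 5′ ends other than a uniform floor,
and operon structure that varies across conditions. Passing recovery
tests therefore shows the procedures are correct and well-calibrated
under their own assumptions — not that real libraries meet those
assumptions.

Problem sizes used by the tests and the acceptance script: 100
transcription units (the stated benchmark size) for TSS/operon/
abundance recovery; 20 EM replicates × 3 motifs at 200 windows for
consensus recovery; 400 planted promoter windows for spacer means; 100
random 10-kb profiles for the brute-force oracle comparison. The full
suite runs in about two minutes on one CPU.

## Numerical conventions and degenerate inputs

Percentages are rounded half away from zero to one decimal (base R
rounds half to even and disagrees on exact ties with every printed
percentage we checked). Strict inequalities apply to *T* and *R*;
boundary values fail. EM convergence is |Δobjective| < 1e-6 with at
most 500 iterations; PWM columns always sum to 1 thanks to the
pseudocounts. Empty profiles, featureless strands, fragmentless
genomes and zero-length extension results all return empty-but-typed
objects rather than errors; a zero `total_mapped` and a feature outside
the replicon are errors. Ties in operon chains cannot arise (junction
support is integer and thresholds strict); ties in the EM restart
selection resolve by restart order, which the seed fixes.

## Known limitations

* The false-positive heuristic is one operationalization of a
  qualitative rule; its two sub-parameters change the flagged set.
* The EM searches one motif per call; composite promoters with
  alternative sigma-factor classes would need per-class runs.
* 3′-end delineation reflects coverage continuity only — terminators
  are not modeled, so 3′-UTR estimates are bounded by `max_extension`.
* Abundance values depend on the supplied `total_mapped`; with the
  default (sum of stored counts) the per-million scaling is only as
  meaningful as the completeness of the profile.
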