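---
title: "Detecting trans-splicing and 5' hairpins in long-read cDNA soft-clips"
author: "clipsl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trans-splicing and 5' hairpins in long-read cDNA soft-clips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In nematodes, most mRNAs mature by *trans*-splicing: a short spliced
leader (SL) donated by an snRNP replaces the transcript's original 5'
end. In *C. elegans* the SL1 family marks genes adjacent to their own
promoter while SL2 variants mark downstream genes of operons, so the
SL carried by a read is biologically informative. Because the SL is not
genome-encoded, a full-length cDNA read aligned against a transcriptome
leaves the SL in the 5' *soft-clip* (CIGAR `S` bases), together with the
polyA tail at the 3' end.

Nanopore direct-cDNA libraries of trans-spliced transcriptomes have a
peculiarity that `clipsl` both models and exploits. SLs carry a
self-complementary 5' stem (a 5' GG pairing with a central CCC). During
the second-strand synthesis step this stem lets the first-strand cDNA
fold back on itself and self-prime, outcompeting the strand-switching
primer. The resulting hairpin molecule passes the pore as one read:
first the cleanly base-called antisense strand, then the fold-back and
a poorly base-called sense-strand copy. Seen in reference orientation,
such a read is

```
[low-quality antisense copy][partial antisense SL][SL] | aligned body | polyA
\------------------ 5' soft-clip ------------------/
```

Three consequences follow, and each is a measurable signature: the
library is overwhelmingly antisense; 5' soft-clips are hundreds of
bases long instead of the ~80 nt expected from adapters; and the mean
base quality steps down sharply at the alignment start. Genes that are
*not* trans-spliced mimic the same artifact through an endogenous 5'
terminal hairpin: a short self-complementary stem at the transcript
start that also self-primes. Distinguishing SL-terminated from
hairpin-terminated 5' ends, per read and per gene, is the point of the
analysis.

## The method

**Per-read classification.** For each primary alignment the window of
up to 100 nt immediately upstream of the alignment start is extracted
from the soft-clip. Each SL of the repertoire is aligned to the window
semi-globally (the SL end-to-end, window flanks free; match +1,
mismatch -1, gap -2 per base). If the score reaches the per-length
threshold the SL is detected; otherwise 2 nt are trimmed from the SL's
5' end and the scan repeats until the truncated SL would drop below
7 nt. A match is **confident** when its score exceeds 9 *or* it ends
within 2 nt of the alignment start - the proximity clause keeps
heavily degraded SLs that sit exactly where an SL belongs. The best
confident detection names the read; a best-score tie across SL1 and
SL2 is `SL.X`, a tie among SL2 variants `SL2.X`.

Antisense reads with no confident SL are probed for an endogenous
hairpin: the 15-mer spanning positions -13..+2 relative to the
alignment start (13 clip bases + 2 aligned bases) is reverse
complemented and aligned locally against the first 30 bases of the
reference transcript at the alignment start; 12 of 15 identity columns
validate the hairpin. The remaining antisense reads are
`unidentified`; SL-negative sense reads cannot be probed
(`sense_untested`).

**Gene level.** Reads are aggregated per (gene, alignment start). At
each gene's dominant start (most reads, ties to the 5'-most
coordinate), the SL fraction over SL + hairpin + unidentified reads
classifies the gene as trans-spliced (fraction > 0.5), hairpin, or
unidentified; genes under 20 reads are low-coverage. Sites with at
least 10 confident family-unambiguous reads get an SL2 ratio
SL2/(SL1+SL2), banded at >0.60 (SL2-favored) and <0.40 (SL1-favored),
and are related to the strand-aware distance from the trans-splice
acceptor to the closest upstream coding gene. Well-expressed genes
(>= 100 reads) with under 10% SL detection are flagged as
endogenous-hairpin candidates.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| upstream window | 100 | nt | SL must abut the alignment start; longer windows only add noise |
| scoring | +1/-1/-2 | score | k substitutions in a length-L match score L-2k, so thresholds read as mismatch budgets |
| detection threshold T(L) | L-4 (L>=14), L-2 (L<14) | score | two-substitution budget at informative lengths; see below |
| trimming | step 2 down to 7 | nt | recovers SLs whose 5' end was lost to the quality drop |
| confident match | score > 9 or end <= 2 nt | - | two-tier logic: strong evidence anywhere, or weak evidence exactly in place |
| stem probe | -13..+2 (15 nt) | nt | the terminal stem spans the alignment boundary |
| hairpin rule | >= 12 of 15 | columns | tolerates two to three errors across the stem |
| hairpin search window | 30 | nt | terminal hairpins are terminal |
| SL2 site threshold | 10 confident reads | reads | ratio stability |
| SL2 bands | >0.60 / <0.40 | ratio | sites are strongly favored by one family |
| gene call | 20 reads, SL majority 0.5 | - | coverage floor and majority rule |
| low-SL flag | >= 100 reads, < 10% SL | - | hairpin candidates must be well expressed |

All constants live in one flat list, `pipeline_params()`, and every one
can be overridden.

**The short-length threshold.** The detection threshold is the one
knob the method description leaves genuinely open. A constant slack
(T(L) = L-4 at all lengths) makes the required fractional identity fall
from 91% at 22 nt to 75% at 8 nt, and a 6-of-8 match placed freely in a
100-nt window is common enough by chance that, in long antisense
soft-clips, short truncations of some SL are regularly "detected" and -
when they land near the alignment start - confidently so, masking
genuine hairpin reads. Tightening the budget to one substitution below
14 nt keeps truncated-SL recovery while cutting that false-positive
channel; the suite measures the confident false-positive rate on
SL-free windows (under 5%).

**Confidence as the classification gate.** Weak, non-confident
detections are recorded in the output but do not name the read. This is
the same two-tier logic the confident-match rule encodes; without the
gate, zero-noise recovery cannot reach 100% because chance truncated
matches are unavoidable in 100-nt windows.

**Hairpin matching side.** The stem probe can be matched against the
read's own aligned bases or against the reference transcript. The
read-side variant sounds attractive ("errors affect both sides
consistently") but is wrong for sequencing errors: the probe and the
aligned prefix are distant parts of one sequencing pass, their errors
are independent, and read-side matching therefore exposes the 12-of-15
rule to the error load of both segments instead of the probe alone.
The package defaults to reference-side matching
(`hairpin_target = "reference"`); `hairpin_target = "read"` switches
the behaviour for sensitivity analysis, and the acceptance suite's
noisy-recovery targets are met with the default.

## The synthetic experiment

The simulator (`sim_config()`, `generate_reference()`,
`simulate_reads()`, `emit_oracle_alignments()`) makes the whole
analysis testable without external data. Its defaults are the study
conditions: 95% of cDNAs become hairpin molecules (antisense reads),
per-base error rates 5% on the first strand and 15% on the second,
mean qualities Q14 aligned vs Q7 in the soft-clip, second-strand copies
of 200-600 nt (antisense 5' clip median ≈ 420 bp), operonic genes
placed ~100 ± 10 nt behind their neighbour, 12.5% of genes carrying an
endogenous hairpin instead of an SL, and SL weights of 93% SL1 / 7%
SL2 with SL2.1 at 21% and SL2.8 at 15% of the family. Reads per gene
are Poisson with mean 200 in the analysis scripts (50 genes ≈ 10,000
reads); the acceptance suite uses 2,000 reads for the zero-noise check
and ~2,400 for the noisy check - sizes chosen to keep sampling error
well below the tolerances being asserted.

Design choices inside the generator:

* **Molecule construction.** The second strand is a sense copy starting
  just past the fold-back (after position 13 of the SL, i.e. right
  behind the central CCC paired with the terminal GG-derived CC, or
  past the stem of a hairpin transcript), so the reference-oriented
  clip reads: antisense body copy, partial antisense SL, full SL. The
  copied antisense SL fragment's length is the SL length minus the
  fold-back offset (9 nt by default); nothing constrains its real
  distribution tightly, so it is a single configurable offset.
* **Hairpin transcripts** start with GG and carry CC at positions
  12-13, a minimal 2-bp stem that makes the -13..+2 probe a perfect
  15/15 reverse complement at zero noise.
* **Errors** are 40% substitutions, 30% insertions, 30% deletions - the
  canonical R9.4 Nanopore decomposition - applied per segment at the
  strand's rate. Alignment endpoints are anchored (no deletion of the
  first/last aligned base, no insertion before the first), so oracle
  CIGARs are well formed.
* **Qualities** are drawn per base from a Normal around the segment
  mean (SD 3), clamped to [2, 41]: this reproduces the observed quality
  step without modelling pore kinetics.
* **Rejection sampling.** Transcripts are resampled until (a) no full
  SL or reverse complement occurs in them and (b) the canonical
  zero-noise upstream window of the gene's reads yields no spurious
  confident detection under default parameters. Because every
  shorter-copy window is a suffix of the canonical window, one check
  per gene suffices. This is what makes zero-noise recovery exactly
  100% rather than "almost always".
* **Determinism.** All randomness flows from the config seed through an
  isolated RNG scope; identical configs give byte-identical FASTA,
  GFF3, FASTQ, truth TSV, and SAM files.

What the simulator does **not** model - and what passing tests
therefore do not show about real data: basecaller-specific error
profiles and homopolymer behaviour, chimeric or PCR artifacts,
truncated or degraded 5' ends (all simulated reads are full length, so
each gene has a single true start site), supplementary alignments
inside long soft-clips, expression-level variation across genes
(uniform Poisson coverage; the real SL1/SL2 read shares are
expression-weighted), introns (transcripts are intronless, so genomic
and transcript coordinates are trivially related), and real *sls* gene
sequences (the repertoire is synthetic, 22-mers with the SL1-like
GG…CCC motif and pairwise Hamming distance >= 10, because mutual
distinguishability - not the exact sequences - is what the method's
correctness depends on).

## Numerical choices and degenerate inputs

Semi-global score ties break toward the smallest target end
coordinate; the best-detection tie order is score, then matched
length, then end offset, then SL name. The local hairpin aligner
maximises (score, identity columns) lexicographically, so the reported
`matched_nt` is deterministic among co-optimal alignments; this is also
what the brute-force oracle computes. Empty upstream windows yield no
detection; clips shorter than 13 nt yield no stem probe, and such
antisense reads are `unidentified`. Aligned regions shorter than the
probe bound `matched_nt` from above. Gene tables conserve read counts
exactly, and raising the SL-majority threshold can only shrink the
trans-spliced set (monotonicity is asserted in the suite). Affine gap
costs are supported (`gap_open`/`gap_extend`); with the default equal
costs the aligners take a single-matrix fast path, and a one-pass DP
over the reversed SL scores all truncations at once.

## Limitations

The confident-match gate trades a small loss of sensitivity for
precision; reads whose only evidence is a weak distal match stay
unclassified. SL2.X reads count toward family totals but cannot enter
variant profiles. The upstream-distance calculation uses annotated
gene edges, not experimentally determined 3' ends. On real data the
classifier consumes transcriptomic alignments only; spliced genomic
alignments are out of scope.
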