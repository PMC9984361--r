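# clipsl

Quantitative analysis of spliced-leader (SL) *trans*-splicing from
long-read direct-cDNA alignments, for transcriptomics researchers
working with nematodes (or any trans-splicing species) and Oxford
Nanopore direct-cDNA libraries.

## The science

In *C. elegans*, mRNA maturation replaces the transcript's 5' end with
a ~22-nt spliced leader: SL1 for genes adjacent to their promoter, SL2
variants for downstream genes of operons. The SL is absent from the
reference, so in a transcriptomic alignment of a full-length cDNA read
it sits in the 5' soft-clip, immediately upstream of the alignment
start.

SLs carry a self-complementary stem (5' GG pairing with a central CCC).
During direct-cDNA library preparation this stem self-primes the
second-strand synthesis, producing hairpin cDNA molecules whose
second strand is base-called poorly. The library consequently shows an
extreme antisense strand bias, very long low-quality 5' soft-clips
(antisense copy of the transcript + partial antisense SL + SL), and a
sharp base-quality step at the alignment start. Non-trans-spliced
mRNAs mimic the artifact with an endogenous 5' terminal hairpin.

`clipsl` implements the full analysis:

* **soft-clip SL detection** - semi-global alignment of each SL
  (progressively 5'-trimmed in 2-nt steps down to 7 nt) against the
  100-nt window upstream of the alignment start; a match is confident
  when its score exceeds 9 or it ends within 2 nt of the alignment
  start; ambiguous best-score ties are classed SL.X / SL2.X;
* **endogenous hairpin calling** - the -13..+2 stem probe (13 clip
  bases + 2 aligned bases), reverse complemented and locally aligned
  at the transcript start; >= 12 of 15 identity columns validate the
  hairpin;
* **read metrics** - strand bias, soft-clip length statistics, and the
  per-offset mean base-quality profile centred on the alignment start;
* **gene summaries** - per-(gene, start) class counts, SL2/(SL1+SL2)
  ratios with the >0.60 / <0.40 bands, strand-aware distances to the
  closest upstream coding gene, trans-spliced/hairpin gene calls at
  the dominant start (>= 20 reads, SL majority), and the >= 100 reads /
  < 10% SL flag for hairpin candidates;
* **a synthetic experiment** - a deterministic simulator of the hairpin
  artifact (reference + annotation + SL repertoire + reads + truth +
  oracle alignments) so the entire analysis runs and is tested without
  external data.

## Worked example

The analysis is organised as numbered scripts over the package
functions; each step reads the previous step's files from `results/`:

```sh
Rscript analysis/01_simulate.R 1      # synthetic experiment, seed 1
Rscript analysis/02_read_metrics.R    # strand bias + quality profile
Rscript analysis/03_classify_reads.R  # per-read 5'-end classes
Rscript analysis/04_gene_summary.R    # gene calls, SL2 ratios, flags
```

With seed 1 this prints, along the way:

```
9937 reads over 50 genes -> results/sim
Strand bias: 95.2% antisense / 4.8% sense
Antisense 5' soft-clips: median 419 bp (IQR 320-519)
Mean base quality: Q7.1 in the soft-clip vs Q14.0 aligned
SL1 carries 81.9% of confident SL reads
Top SL2 variants within the family: SL2.1 22%, SL2.8 15%
Recovery vs truth: 95.3% SL family, 90.5% hairpin reads
50/50 genes have >= 20 reads; 88.0% are mostly trans-spliced
8 SL2-favored sites; median upstream distance 102 nt; 100% within 200 nt
6 genes flagged as well-expressed with <10% SL detection
```

Reading these numbers: the simulated library shows the hairpin-cDNA
signatures (antisense dominance, ~420-bp soft-clips, the Q7 vs Q14
quality step); the classifier recovers the SL family of 95% of noisy
SL reads and 90% of hairpin reads; at gene level 88% of genes are
called mostly trans-spliced, SL2-favored start sites sit ~100 nt
downstream of their upstream neighbour (the operon signature), and the
six simulated endogenous-hairpin genes are exactly the well-expressed
genes with marginal SL detection.

The same machinery runs on real data: `run_pipeline()` takes a
transcriptomic BAM/SAM, a transcriptome FASTA, a GFF3 annotation and an
SL repertoire FASTA, and writes the full set of TSV tables plus a
manifest.

```r
library(clipsl)
res <- run_pipeline("aln.bam", transcriptome = "txome.fa",
                    gff = "genes.gff3", sl_fasta = "sls.fa",
                    outdir = "out")
head(res$gene_calls)
```

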