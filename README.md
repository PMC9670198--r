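# iestools

Analysis of programmed DNA elimination in *Paramecium* from gapped read
alignments.

During sexual development in ciliates, the developing somatic macronucleus
precisely excises tens of thousands of short, TA-bounded Internal Eliminated
Sequences (IESs) from the germline genome. `iestools` implements the
computational analyses used to characterize this process from short-read
sequencing of the developing macronucleus (anlagen), aligned to a
germline-inclusive "MAC+IES" reference:

* **Retention scoring.** For each IES, reads supporting retention at the
  left (`a`) and right (`b`) boundary and reads carrying the excision
  junction (`c`) give the IES retention score

  `IRS = (a + b) / (a + b + 2c)`,

  running from 0 (complete excision) to 1 (complete failure to excise). The
  factor 2 compensates for retained reads being countable at both
  boundaries.

* **Excision-event detection and classification.** Deletion/skip gaps in
  the alignments (CIGAR `D`/`N`) that are TA-bounded like canonical IESs are
  classified against the annotation as `CORRECT` (exact interval),
  `ALT_INTERNAL` / `ALT_EXTERNAL` / `ALT_OVERLAPPING` (alternative TA
  boundary pairs), or `CRYPTIC` (no annotated IES). Headline statistics
  follow the read-based definitions
  `alt% = 100·alt/(alt + correct)` and `cryptic% = 100·cryptic/all reads`,
  with excised-length histograms (1-bp bins), the mass of the suppressed
  "forbidden" length peak (window 32–38 bp), and boundary-offset
  distributions.

* **Nucleosome density.** Properly paired nucleosomal reads with outer
  distance in [100, 175] bp (mononucleosome range) are counted per IES with
  a ≥ 9 bp aligned-overlap rule, normalized by DNA-seq as

  `r = (n/N) / (d/D)`,

  and compared between weakly (IRS < 0.2) and strongly (IRS ≥ 0.2) retained
  IESs within length strata using the two-sample Kolmogorov–Smirnov test.

* **Synthetic data.** A first-class simulator generates toy MAC+IES genomes
  (AT-rich, periodic IES length distribution with a suppressed ~35 bp peak,
  guaranteed alternative TA sites near boundaries), anlagen DNA-seq reads
  with per-IES retention/alternative-excision truth, cryptic excisions, and
  mononucleosome-sized fragments with per-IES density multipliers — emitted
  as standard FASTA/GFF3/SAM/FASTQ so every stage is testable without
  external data.

## Worked example

```r
library(iestools)

cfg <- sim_config(seed = 7, n_contigs = 1, contig_length = 12000,
                  n_ies = 30, coverage = 60)
sim <- run_simulation(cfg, truth_params = list(retention_prob = 0.5,
                                               alt_prob = 0.1))
an <- run_analysis(sim$dna$alignments, sim$annotations, sim$genome,
                   nucleosomal = sim$nuc$alignments)
an
#> <ies_analysis> 30 IESs, 88 events, 7144 mapped reads
#> <excision_summary>
#>   global alternative excision: 8.03%
#>   IESs with >=1 alternative read: 83.3%
#>   per-IES alt% median 5.41, mean 7.55 (n=30)
#>   cryptic excision: 0.098%
#>   forbidden-peak mass (alt lengths): 0.333
```

Every IES was simulated with retention probability 0.5 and a 10% chance
that an excision uses an alternative TA pair; at 60× depth the global
alternative excision percentage (8.0%) sits within sampling error of the
simulated 10%, and the per-IES retention scores average 0.53. `tidy(an)`
returns the per-IES table (boundary counts, IRS, event support, normalized
density), `glance(an)` the one-row summary, and `autoplot(an)`,
`plot_density_strata()`, `plot_fragment_lengths()` the standard figures.
`write_report(an, "report/")` writes the retention table (TSV), event calls
(GFF3), histograms and a JSON summary.

Real data enter through `load_genome()` (FASTA), `load_ies_annotations()`
(GFF3) and `read_alignments()` (SAM/BAM produced by any gapped/spliced
mapper against the MAC+IES reference).

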