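# HGTscan

Detection and verification of horizontally acquired genes in transcriptomes.

Some animals express genes acquired from bacteria, fungi, plants and protists
rather than by descent — most dramatically bdelloid rotifers, where roughly a
tenth of the identifiable transcriptome is of foreign origin. `HGTscan` is
for researchers who have an assembled transcriptome and taxon-partitioned
protein homology-search results and want to (i) score each transcript for
foreignness, (ii) justify the calling threshold against reference species,
(iii) verify calls phylogenetically, (iv) rule out contamination via the
genome assembly, and (v) quantify what the foreign genes contribute to
metabolism.

## The statistics at the core

For each transcript, with best bitscores per taxon partition collected from
the top five hits, the **HGT index** is

    h = S(best non-metazoan) − S(best metazoan)        [bits]

with a missing side contributing 0 bits. Transcripts are *foreign* (h ≥ θ,
default θ = 30), *indeterminate* (0 < h < θ) or *metazoan* (h ≤ 0). The
legacy **alien index** AI = ln(E_met + c) − ln(E_non-met + c), c = 1e-200, is
computed alongside for comparison. The threshold is justified by the
cross-species ratio of cumulative curves,

    R(h) = pct₁(index ≥ h) / pct₂(index ≥ h),

which plateaus where increasing θ stops improving specificity. Verification
assigns each foreign call with a metazoan match to one of five monophyly
groups from branch supports on its gene tree; the contamination screen chains
transcript-to-genome alignments under exon/intron constraints and reports
coverage and foreign/metazoan co-localisation; the metabolic footprint
colours EC numbers by origin and tests pathway enrichment with a
hypergeometric upper tail and Benjamini–Hochberg correction.

## Worked example

Everything is runnable offline against the built-in generator, which emulates
the statistical structure of a rotifer-style dataset (log-normal transcript
lengths, median 341 bp; 10% foreign transcripts, 59% of them eubacterial;
length-proportional bitscores with E-values consistent with them):

```r
library(HGTscan)

sim  <- simulateHitTable(simParams(nTranscripts = 1000, seed = 7))
prof <- buildProfiles(sim$hits)           # matched-set filter at E <= 1e-5
rec  <- hgtRecords(prof)                  # h, alien index, categories
rec
#> HGTRecords (h_U, theta = 30): 1000 transcripts
#>   metazoan 899 | indeterminate 0 | foreign 101 (10.1%)

s <- summarizeHGT(rec, prof)
round(100 * s$foreign_fraction, 1)        # 10.1 — % foreign among matched
round(100 * s$no_metazoan_among_foreign[["fraction"]], 1)
#> 75.2 — % of foreign calls with no significant metazoan hit at all

res <- runPipeline(list(seed = 7), params = simParams(nTranscripts = 1000, seed = 7))
round(res$report, 3)
#>              seed           matched  foreign_fraction      pct_at_theta
#>             7.000          1000.000             0.101            10.100
#> verification_rate coverage_above_50pct_foreign fraction_colocalized n_enriched_q05
#>             0.989                        0.960                0.835          2.000
```

Reading the report: 10.1% of matched transcripts are called foreign (the
generator's truth is 10%); 98.9% of foreign calls are *verified* — they fall
into monophyly groups 4/5 or have no metazoan match; 96% of foreign
transcripts align to the synthetic draft genome over more than half their
length (contaminants, 10% of foreign by construction, align nowhere); 83.5%
share a genomic contig with a metazoan transcript or a foreign transcript of
a different source taxon, ruling out contamination for that set; and both
pathways spiked with foreign enzymes are recovered at q < 0.05.

Real data enter through `readHits()` (12-column tabular search output, one
file or a taxon column per partition), `readTranscriptLengths()` (FASTA),
`readNewickSupports()` (support-annotated trees), `readSummaryTable()`
(per-transcript supplementary-style tables) and `readPathwayMap()` (TSV).

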