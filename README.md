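# cbfsurvey

Identification of CBF transcription factors and a survey of their putative
cold-responsive target genes, as a tested, reusable R pipeline.

C-repeat binding factors (CBFs, also called DREB1s) are AP2/ERF-family
transcription factors that are rapidly induced by cold and bind the
C-repeat/dehydration-responsive element (CRT/DRE, consensus G/ACCGAC, IUPAC
`RCCGAC`) in the promoters of downstream cold-responsive (COR) genes. A
genome-scale CBF study runs a fixed sequence of analyses:

1. **Family identification** — candidate CBFs are found by homology
   (local alignment against seed CBFs, BLOSUM62, affine gaps) and verified
   by the two CBF signature sequences, `PKK/RPAGRxKFxETRHP` (S1) and
   `DSAWR` (S2), which must occur in order with the ~60-residue AP2
   DNA-binding domain between them (S1→S2 separation 40–120 residues by
   default).
2. **Protein characterization** — the ProtParam-style property block per
   protein: length, molecular weight, isoelectric point (Bjellqvist pKa
   set), instability index (Guruprasad dipeptide weights; < 40 = stable),
   aliphatic index, and GRAVY (mean Kyte–Doolittle hydropathy).
3. **Phylogeny** — neighbor joining on pairwise-alignment p-distances with
   bootstrap support (resampled alignment columns, default 1000
   replicates), written as Newick.
4. **Promoter analysis** — the 1000 bp immediately upstream of each start
   codon is extracted (strand-aware, clipped at contig edges) and scanned
   for CRT/DRE and a catalogue of cis-elements with IUPAC-degenerate
   matching on both strands, overlaps included.
5. **Expression** — FPKM = c·10⁹/(N·L) from fragment counts, winter/summer
   fold changes with a 0.1-FPKM ratio floor, and qPCR relative expression
   by 2^−ΔΔCT with Welch significance on ΔCt.
6. **Target survey** — the headline step: genes changing **at least
   2-fold** between winter and summer mature leaves *and* carrying **at
   least one CRT/DRE** in their promoter are the putative CBF targets;
   survivors are classified into eleven functional categories by keyword
   and tested for term enrichment with the upper-tail hypergeometric
   probability (BH-adjusted alongside).

Every stage is exercised end-to-end on seeded synthetic data with planted
ground truth (`make_genome()`, `make_counts()`, `make_family()`,
`evolve_sequences()`), so the whole pipeline is testable without any
downloads.

## Worked example

The `analysis/` directory is a numbered workflow over the package. After
`Rscript analysis/01_simulate_fixtures.R` (which writes the synthetic
study inputs under `results/fixtures/`), the survey stage prints:

```
$ Rscript analysis/07_target_survey.R
A total of 110 potential target genes were identified, including 30
upregulated genes and 80 downregulated genes.
Agreement with planted truth: 110 of 110 planted targets recovered; 0 spurious
```

110 is exactly the planted structure (30 up + 80 down target genes whose
promoters carry a CRT/DRE copy); the 90 decoy genes — drifting less than
2-fold and without planted motifs — are all excluded. The family stage
recovers the 5 planted signature-bearing proteins from 55 with no false
positives, and the qPCR stage reports a cold-induction time course
(calibrator 0 h):

```
 sample n    rq    se  p_value significant
     0h 3  1.00 0.031       NA       FALSE
     1h 3 10.29 0.601 5.14e-05        TRUE
     3h 3  6.78 0.293 9.36e-06        TRUE
```

i.e. a ~10-fold significant induction peaking at 1 h, decaying by 48 h.

## Methods

See the methods vignette, `vignettes/cbf-target-survey.Rmd`, for the
models, parameter choices, numerical details, what the synthetic
generators do and do not emulate, and known limitations.
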