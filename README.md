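# oomat — maternal mRNA translation analysis in maturing oocytes

Fully grown mouse oocytes are transcriptionally silent, so meiotic
maturation runs on the regulated translation of stored maternal mRNAs.
3'UTR-binding proteins (DAZL, CPEB1) can both repress and activate the same
transcriptome, switching roles around germinal-vesicle breakdown (GVBD) and
acting through cytoplasmic polyadenylation. `oomat` implements the
computational analyses used to dissect such dual control, together with
synthetic-data generators that plant known structure so every stage is
testable without any external download:

* **Differential ribosome loading** from paired RiboTag IP / input count
  matrices. Counts are modelled as negative binomial
  (Var = μ + φμ²); per-gene dispersions are moment estimates shrunk toward a
  lowess mean–dispersion trend, and each gene is tested with a conditional
  exact test on the library-equalized group sums (at φ = 0 it reduces to the
  conditional binomial test). Transcripts are classified up / down /
  unchanged at the experiment's thresholds (2-fold, BH FDR < 0.05), and
  translational efficiency is TE = IP CPM / input CPM per replicate pair.
* **3'UTR cis-element scanning**: exhaustive IUPAC window matching for DAZL
  (`UUSUU`), CPE (`UUUUAU`, `UUUUAAU`) and PAS (`AAUAAA`, `AUUAAA`) with
  0-based half-open coordinates, element-coverage summaries over gene sets,
  and adenosine-replacement mutant design (`UUGUU → AAGAA`) with a re-scan
  guarantee that the element is destroyed.
* **Reporter translation kinetics**: YFP/mCherry normalization, windowed OLS
  translation rates (pre-/post-GVBD or early/late GV-arrest windows), Welch
  rate comparisons, linearity assessment, and adenylation inference from
  oligo- vs poly-adenylated reporter pairs — an accelerating oligo reporter
  with a flat poly control reads out endogenous polyadenylation.
* **RIP enrichment and integration**: antibody/IgG fold enrichment with
  Welch tests (1.5-fold, p < 0.05 cutoffs), 2^−ΔΔCt qPCR folds, and the
  joint classification of genes into target quadrants
  (bound-activated / bound-repressed / …) plus the null-subset analysis
  (affected transcripts carrying no binding element).

## Worked example

Simulate a morpholino-knockdown RiboTag experiment (2,000 genes, 5% planted
up and 5% down at 4-fold, two replicates per arm) and recover the planted
classes:

```r
library(oomat)

sim <- simulate_ribo_counts(count_sim_params(
  n_genes = 2000, frac_up = 0.05, frac_down = 0.05,
  effect_fold = 4, seed = 42))
de <- differential_loading(sim$dataset, fold = 2, alpha = 0.05)
table(called = de$class, planted = sim$truth$class)
#>            planted
#> called      down unchanged   up
#>   down        99         3    0
#>   unchanged    1      1794    0
#>   up           0         3  100
```

199 of the 200 planted effects are recovered at the 2-fold / FDR < 0.05
thresholds, every true positive with the correct direction, and 6 of 1,800
null genes are miscalled (empirical FDR ≈ 3%).

Scan a 3'UTR for regulatory elements and design a DAZL-site mutant:

```r
utr <- "AAUUGUUCCAUUUUAUGGAAUAAAGC"
hits <- scan_sequence(utr)
hits
#>   motif pattern start end matched
#> 1  DAZL   UUSUU     2   7   UUGUU
#> 2   CPE  UUUUAU    10  16  UUUUAU
#> 3   PAS  AAUAAA    18  24  AAUAAA

mutate_element(utr, hits[2, ])   # destroy the CPE, leave the rest
#> [1] "AAUUGUUCCAAAAAAAGGAAUAAAGC"
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the full
study design on synthetic data, each a thin narrative over the package
functions, writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # counts, UTRs, RIP table, trajectories (+ truth)
Rscript analysis/02_scan_utrs.R         # element hits, coverage, mutagenesis worksheet
Rscript analysis/03_ribosome_loading.R  # CPM, TE, differential loading vs truth
Rscript analysis/04_reporter_kinetics.R # window rates, Welch tests, adenylation calls
Rscript analysis/05_integrate.R         # fold enrichment, quadrants, null subset, summary
```

Stage 4, for example, prints the adenylation decision per reporter
construct (oligo log2(late/early) vs the poly control):

```
WT           oligo log2(late/early) = -0.03, poly = +0.04 -> stable
dCPE         oligo log2(late/early) = +1.11, poly = +0.08 -> adenylation
dDazl        oligo log2(late/early) = +0.00, poly = -0.01 -> stable
dCPE_dDazl   oligo log2(late/early) = +1.17, poly = -0.04 -> adenylation
```

i.e. the planted de-repression of the double mutant is read out as
endogenous adenylation of the oligo reporter while its pre-adenylated twin
stays flat. `run_pipeline()` performs the same five stages in one call and
is byte-deterministic for a fixed config.

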