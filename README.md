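# tph2edit

Clone-based inference of **TPH2 alternative splicing and mutually exclusive
RNA editing**, with the enzyme-kinetics and population-genetic analyses that
go with it.

Tryptophan hydroxylase 2 (TPH2) is the rate-limiting enzyme of brain
serotonin synthesis. Its mRNA occurs in two splice isoforms — *TPH2a* and
*TPH2b*, distinguished by a 6-nt coding insertion (c.439_440insGCAAGG, adding
Gly-Lys) produced by an alternative GT splice donor 6 nt downstream of the
non-canonical GC donor of intron 3. Each isoform carries its own set of four
RNA-editing positions (a-pattern: c.-42T>C, c.711A>G, c.1297A>G, c.1322G>A;
b-pattern: c.385C>T, c.804A>G, c.830C>T, c.1403A>G), and the two sets are
mutually exclusive. Since an edited base in cDNA looks exactly like a SNP,
edits are identified by cross-referencing each individual's genomic DNA:
an alternative base over a homozygous-reference genome is an edit, a base
present among the genomic alleles is a genuine SNP (as rs7305115 and
rs4290270 are). The package is aimed at transcriptomics researchers who want
to reproduce, stress-test or extend this inferential chain on simulated or
real clone libraries.

## What is implemented

| Stage | Functions |
|---|---|
| Surrogate reference model (both isoforms, HGVS-like c. coordinates, variant catalogue, translation, donor-site scan) | `build_reference()`, `apply_variants()`, `translate_cds()`, `scan_donor_sites()` |
| Synthetic data with truth tables (clone libraries, genomic haplotypes, kinetic assays, genotype cohorts) | `generate_clone_library()`, `generate_individual()`, `generate_kinetic_dataset()`, `generate_genotype_cohort()` |
| Clone calling (global affine-gap alignment, isoform classification, variant calls, QC) | `align_clone()`, `classify_clones()`, `call_variants()`, `annotate_clones()` |
| Edit/SNP discrimination, pattern labels, consequences | `classify_site()`, `assign_pattern()`, `annotate_consequence()`, `discriminate_clones()` |
| Cohort statistics (stratified frequency tables, Welch tests, Hardy-Weinberg, association, in-silico NdeI RFLP) | `editing_frequency_table()`, `compare_editing()`, `hwe_test()`, `genotype_association()`, `ndei_rflp()` |
| Enzyme kinetics (Michaelis-Menten, Haldane substrate inhibition, Lineweaver-Burk, recovery studies, variant comparison) | `fit_mm()`, `fit_substrate_inhibition()`, `fit_lineweaver_burk()`, `recover_parameters()`, `compare_variants()` |
| End-to-end pipeline | `run_pipeline()` |

The kinetic models are v = Vmax·S/(Km + S) and the Haldane
substrate-inhibition form v = Vmax·S/(Km + S + S²/Ki) (velocity maximal at
S = √(Km·Ki)), fitted by multi-start Levenberg–Marquardt least squares, with
the classical double-reciprocal regression alongside.

## Worked example

Simulate an amygdala-like library from an rs4290270 T/T donor, run the caller
and discriminator, and tabulate editing frequencies:

```r
library(tph2edit)

model <- build_reference()
prof  <- generate_individual(model, "donor1", geno_rs4290270 = "TT", seed = 7)
params <- generation_params(n_clones = 30, splice_fraction_b = 0.5,
                            edit_prob_b = c(0.78, 0.96, 0.96, 0.96),
                            error_rate = 0)
lib  <- generate_clone_library(model, prof, "amygdala", params, seed = 8)
ann  <- annotate_clones(lib$clones, model)
disc <- discriminate_clones(ann, model, list(donor1 = prof), lib$manifest)
table(disc$patterns$label)
#> TPH2a unedited      TPH2b 123     TPH2b 1234      TPH2b 134      TPH2b 234
#>             12              1             11              2              3
#>       TPH2b 34
#>              1

editing_frequency_table(disc$patterns, strata = "region")[
  , c("region", "isoform", "n_clones", paste0("pct_", 1:4))]
#>     region isoform n_clones pct_1 pct_2 pct_3 pct_4
#> 1 amygdala       a       12   0.0   0.0     0   0.0
#> 2 amygdala       b       18  77.8  83.3   100  94.4
```

The labels are the mutually exclusive editing patterns (e.g. `TPH2b 234` =
TPH2b edited at positions 2, 3 and 4 but not at the nonsense-creating
position 1); the percentages are per-position editing frequencies among
QC-passing clones of each isoform. Unedited TPH2a clones dominate the `a`
stratum because no a-pattern editing was simulated.

Fit a noisy saturation curve and test a genotype distribution for
Hardy-Weinberg equilibrium:

```r
d <- generate_kinetic_dataset("mm", km = 126, vmax = 1,
                              s_grid = c(10, 25, 50, 100, 200, 350, 500, 600),
                              noise_cv = 0.05, seed = 9)
fit_mm(d)
#> MM fit (nls): Km = 134, Vmax = 1.021; RSS = 0.0042; converged: TRUE

hwe_test(c(30, 40, 30))[c("chi_square", "df", "p")]
#> $chi_square
#> [1] 4
#> $df
#> [1] 1
#> $p
#> [1] 0.04550026
```

A single noisy 8-point curve recovers Km = 134 µM against a truth of 126 µM;
medians over replicate experiments (see `recover_parameters()`) land within a
few percent. The genotype counts (30, 40, 30) have a het deficit relative to
the (25, 50, 25) expectation at allele frequency 0.5, giving χ² = 4 on 1 df.

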