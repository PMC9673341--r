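# taxbench

Ground-truth benchmarking of metagenomic read classification, with first-class
support for the confound that dominates benchmarks built on
metagenome-assembled genomes (MAGs): **reference genomes with incomplete
taxonomic lineages**.

## The problem

When a metagenome is classified with a k-mer/LCA classifier (Kraken-style)
against some reference database, two questions matter: *how much* of the data
is classified at each taxonomic rank (the classification rate), and *how
accurately*. Both can only be measured on data of known composition, so the
standard design is to simulate reads from genomes of known taxonomy and
compare each read's assignment with the taxonomy of its source genome.

This comparison is subtler than it looks. Many genomes — in particular MAGs
and uncultured isolates — have *no label at all* at some ranks: a species may
be attached directly to an order, with no family or genus node on its lineage
(think "*Bacteroidales* bacterium KHT7": phylum, class, order and species
labels but no family or genus), or carry an informal species name
("uncultured ... sp."). Reads from such genomes are not "wrong" or
"unclassified" in the usual sense at those ranks, and naive per-rank accuracy
silently miscounts them. A visible symptom is the anomaly where the
genus-level classification rate drops *below* the species-level rate.

`taxbench` packages the whole benchmarking loop so these cases are handled
explicitly:

* **taxonomy** — NCBI-taxdump-dialect parsing, rank-aware lineage queries
  (`rank_ancestor()`, `lineage()`, `lca()`) where an absent rank is a value,
  not an error, plus lineage-completeness accounting
  (`completeness_report()`, `is_informal_name()`);
* **synthetic data** — taxonomies with a configurable fraction of
  family-less/genus-less species, random genomes, abundance-weighted
  paired-end reads with a per-read truth table (`simulate_reads()`), and
  classifier output with injected error structure
  (`simulate_classifier_output()`);
* **classifier** — a built-in exact-k-mer LCA classifier
  (`build_kmer_index()`, `classify_reads()`) emitting Kraken-dialect output,
  so end-to-end runs need no external binaries; real Kraken output files can
  be ingested instead;
* **evaluation** — the five-way per-read, per-rank status scheme:
  `correct`, `incorrect`, `unclassified_at_this_level`,
  `unclassified_at_any_level`, `truth_unknown`, plus classification rates
  and taxon-level false-positive/false-negative sets;
* **abundance** — per-rank abundance tables and truth-versus-classified
  concordance on log10 percentages, reporting both the regression R² and the
  deviation-from-identity R² side by side.

## The status scheme

For a read with truth taxid *t*, assignment *a*, evaluated at rank *r*:

1. lineage(*t*) has no label at *r* → **truth_unknown**;
2. *a* = 0 (no assignment at all) → **unclassified_at_any_level**;
3. lineage(*a*) has no label at *r* → **unclassified_at_this_level**;
4. ancestor of *a* at *r* = ancestor of *t* at *r* → **correct**;
5. otherwise → **incorrect**.

Percentages are always over all simulated reads, so the five categories sum
to 100 at every rank. Abundance concordance pairs taxa with nonzero
percentage in both tables and computes, on (log₁₀ x, log₁₀ y),
R²(OLS) = 1 − SS_res/SS_tot for the fitted line and
R²(identity) = 1 − Σ(y−x)²/SS_tot for the y = x line.

## Worked example

Fifty species, 30% of them without a genus label, 10,000 error-free read
pairs, classified against an index built from their own source genomes:

```r
library(taxbench)

cc  <- community_config(n_species = 50, n_read_pairs = 10000,
                        mean_genome_length = 10000,
                        missing_genus_frac = 0.3, seed = 11)
tax     <- generate_taxonomy(cc)
genomes <- generate_genomes(tax$db, tax$genome_taxids, cc, seed = 12)
sim     <- simulate_reads(genomes, tax$db, cc, seed = 13)

index   <- build_kmer_index(genomes, tax$db, k = 21)
#> <kmer_index> k = 21, 491,031 k-mers over 50 genomes
records <- classify_reads(index, sim$r1, sim$r2)

evaluate(sim$truth, records, tax$db)
#> <evaluation_summary> 10000 reads, overall classified 100.00%
#>       rank correct incorrect truth_unknown unclassified_at_any_level unclassified_at_this_level
#> 1:  family  100.00         0          0.00                         0                          0
#> 2:   genus   71.76         0         28.24                         0                          0
#> 3:  phylum  100.00         0          0.00                         0                          0
#> 4: species  100.00         0          0.00                         0                          0
```

Every read is classified and none is incorrect — the database contains
exactly the source genomes, so this is the positive control. But 28.24% of
reads are `truth_unknown` at genus: they come from the 17 genus-less
species, and the genus-level classification *rate* shows the same dent
(`ev$rank_rates`: genus 71.76% classified versus 100% at species) — the
genus-below-species anomaly reproduced from its known cause.

```r
truth_sp <- abundance_table(sim$truth, tax$db, "species", source = "truth")
cls_sp   <- abundance_table(records,  tax$db, "species", source = "classified")
concordance(truth_sp, cls_sp)
#> <concordance_result> rank species: 50 taxa, R2(ols) = 1.0000, R2(y=x) = 1.0000, slope = 1.000

head(top_n_comparison(truth_sp, cls_sp, n = 5), 3)
#>    taxid                          name truth_percent classified_percent
#> 1:    43             Meselter vitherum          9.99               9.99
#> 2:    58 Finegabreaceae bacterium TB18          5.92               5.92
#> 3:    56           Locopre coruterbais          5.38               5.38
```

`run_pipeline(pipeline_config(...))` wires all of the above into one call
and persists every intermediate (taxdump pair, FASTA/FASTQ, truth TSV,
Kraken-dialect output and report file, evaluation TSV, JSON report);
reruns with the same seed are byte-identical.

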