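# degeprimr

Degenerate PCR primer design for cross-species amplification of
single-copy nuclear protein-coding genes.

## What it does

Given (a) codon alignments of 1:1 orthologous genes across a panel of
reference taxa — or protein alignments plus coding sequences, which the
package back-translates — and (b) one annotated genome assembly (FASTA +
GFF3 exon models) per taxon, `degeprimr` infers degenerate
oligonucleotide primer pairs that amplify each gene in all reference
taxa and, by extension, in related species without sequenced genomes.

The method, in the field's standard terms:

* conserved windows are found by sliding 20–25-nt windows over each
  alignment and building the **minimal IUPAC consensus** (per column, the
  smallest code containing the union of observed bases); the **degree of
  degeneration** *d* of a window is the product of its per-position code
  cardinalities — the exact size of the synthesised primer pool;
* candidate primers pass a filter battery: *d* ≤ 256, GC 20–80%,
  mononucleotide runs ≤ 4 bp, nearest-neighbor melting temperature
  (unified parameters, entropic salt correction, CT/4 term) within
  45–66 °C, stricter rules on the 3′-terminal hexamer (*d* ≤ 4, runs
  ≤ 3), pairwise ΔTm ≤ 10 °C, and homo-/heterodimer stacking free energy
  ≥ −11 kcal/mol;
* pairs are validated **against every reference genome**: primers whose
  binding sequence is interrupted by an intron (exon/intron-boundary
  primers) or whose genomic product (introns included) exceeds 1000 bp
  are discarded; accepted amplicons get exact exonic/intronic nucleotide
  accounting from the gene models, plus a screen for unintended
  secondary products at approximate binding sites;
* per gene, an overlap-limited subset (pairwise amplicon overlap ≤ 50%)
  is selected, mean uncorrected p-distance of the amplified target across
  taxa is reported, and universal sequencing tails are attached to the
  5′ ends where the dimer screen allows.

A seeded synthetic-data generator (`generate_fixture`) builds ortholog
groups and annotated mini-genomes with planted conserved windows and a
truth table, so the whole pipeline is testable without any downloads.

## Worked example

Re-validate a published-style primer table (shipped with the package)
against the default filter battery:

```r
library(degeprimr)
tab <- system.file("extdata", "evaluated_primer_pairs.tsv",
                   package = "degeprimr")
chk <- check_primers(tab)
chk[1:3, c("id", "fwd_d", "rev_d", "total_d", "pass")]
#>          id fwd_d rev_d total_d pass
#> 1 3683_01_A    32    12     384 TRUE
#> 2 4652_02_A    24    16     384 TRUE
#> 3 4747_02_A     6    18     108 TRUE
```

`fwd_d` / `rev_d` are the primer degeneracies (pool sizes): the forward
primer of pair 3683_01_A, `GCYATYTTCGAYTTYGAYAG`, carries five 2-fold
`Y` codes, hence d = 2^5 = 32, and the pair pool totals 32 × 12 = 384
oligonucleotides. `pass` confirms each primer satisfies the length,
degeneracy, run and 3′-hexamer rules.

Run the full pipeline on a synthetic bundle:

```r
fx <- generate_fixture(fixture_spec(n_taxa = 4, n_genes = 2, seed = 90),
                       dir = tempfile())
res <- run_design(run_config_from_fixture(fx$dir))
res$markers[, c("pair_id", "total_degeneracy", "intronic_bp",
                "mean_p_distance", "annealing_C")]
#>     pair_id total_degeneracy intronic_bp mean_p_distance annealing_C
#> 1 g001_01_D                1         398        36.52095    53.47863
#> 2 g002_01_X                1         502        37.69608    51.61764
```

Each marker row is a selected primer pair: `intronic_bp` is the number
of intronic nucleotides inside the predicted amplicon (averaged over
taxa; here the fixture plants identical intron lengths, so it is exact),
`mean_p_distance` the average pairwise uncorrected p-distance (%) of the
amplified target region across the reference taxa, and `annealing_C`
the recommended annealing temperature (min Tm_min − 3 °C). The trailing
letter of each pair id names the first compatible sequencing tail (`X`
when none fits; such pairs are flagged).
`res$amplicons` holds the per-taxon predictions
(`exonic_bp + intronic_bp == target_len` always), `res$rejections` the
per-genome rejection log (e.g. `exon_intron_boundary`).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/degeprimr-cli.R fixtures --out bundle --taxa 9 --genes 20
Rscript inst/scripts/degeprimr-cli.R design --bundle bundle --out markers
Rscript inst/scripts/degeprimr-cli.R check-primers --table primers.tsv
```

See `vignettes/degenerate-primer-design.Rmd` for the model, parameter
and design rationale.

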