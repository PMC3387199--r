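---
title: "Designing degenerate PCR primers for cross-species amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing degenerate PCR primers for cross-species amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular phylogenetics of diverse clades still leans on targeted PCR of
single-copy nuclear protein-coding genes: a primer pair that amplifies the
same orthologous locus in many species yields cheap, directly comparable
sequence data, including fast-evolving introns useful for shallow
divergences. Designing such primers from a panel of annotated reference
genomes requires more than a per-sequence primer tool: the primers must sit
in regions conserved across *all* reference taxa, tolerate the residual
variation through IUPAC degeneracy, avoid exon/intron boundaries in every
genome, keep the genomic product (introns included) within a sequencable
size, and stay free of primer-dimer artefacts even after universal
sequencing tails are attached to their 5' ends.

`degeprimr` implements this pipeline end to end: codon alignments of 1:1
orthologs in, a ranked marker table of tailed degenerate primer pairs out.

## Pipeline overview

1. **Back-translation** (`backtranslate`): a protein multiple alignment is
   used as a blueprint to align the underlying coding sequences codon-wise;
   every amino-acid column becomes a codon column, protein gaps become
   `---`. Selenocysteine or otherwise ambiguous residues recoded as `X`
   are accepted verbatim, so a stray non-standard codon never aborts a
   gene.
2. **Conserved-window scan** (`scan_gene`): windows of every primer length
   slide one nucleotide at a time (primers are not frame-bound). Each
   window's minimal IUPAC consensus — per column, the smallest code
   containing the union of observed bases — is pushed through the filter
   battery below. Windows touching a column with a gap or an ambiguity
   code are rejected outright, because the consensus could no longer cover
   every row. Each surviving window is emitted in both orientations.
3. **Pairing** (`form_pairs`): forward x downstream-reverse combinations
   whose alignment-implied target lies within the amplicon bounds, whose
   Tm midpoints differ by at most the configured maximum, and which pass
   the homo- and heterodimer screen.
4. **Genome validation** (`validate_pair`): each pair is re-located in
   every reference genome. A primer whose binding sequence is interrupted
   by an intron has no contiguous genomic match; if it matches the spliced
   transcript but not the genome it is rejected as an
   exon/intron-boundary primer. Oversize genomic products (introns
   included) are rejected. Accepted pairs get exact intron/exon accounting
   of the target region from the gene model.
5. **Secondary-product screen** (`secondary_product_screen`): approximate
   binding sites (mismatches allowed) anywhere in the genome that form an
   unintended convergent pair within a plausible product size flag the
   pair as risky. The flag is reported, never used for ranking.
6. **Selection and tails** (`select_per_gene`, `tail_compatibility`,
   `attach_tail`): per gene, a greedy overlap-limited subset is kept; each
   pair is tested against the catalog of universal sequencing tails and
   reported with a recommended annealing temperature.

## Filters and their defaults

`design_params()` carries the full constraint set; defaults:

| constraint | default | unit |
|---|---|---|
| target-region length | 300–1000 | bp |
| primer length | 20–25 | nt |
| degeneracy *d* (product of per-position IUPAC cardinalities) | ≤ 256 | expansions |
| GC content | 20–80 | % |
| mononucleotide run (worst case over expansions) | ≤ 4 | bp |
| melting temperature | 45–66 | °C |
| Tm difference within a pair | ≤ 10 | °C |
| homo-/heterodimer ΔG | ≥ −11.0 | kcal/mol |
| 3'-terminal hexamer: degeneracy / GC / run | ≤ 4 / 20–80% / ≤ 3 | — |

Two semantic choices deserve note, both configurable:

* **GC and Tm filters are containment filters** for degenerate primers:
  the whole range over expansions must lie inside the window
  (`gc_mode = "contain"`, `tm_mode = "contain"`). Rationale: every
  expansion in the synthesised pool should be a usable primer. `"overlap"`
  semantics are available when a partial pool is acceptable.
* **Runs are worst-case over expansions**: a single expandable
  homopolymer (e.g. `AWAA` → `AAAA`) can still misprime, so the
  conservative bound is used.

The per-primer degeneracy cap is the filter; the pair total (the product
of the two primer degeneracies) is reported but uncapped.

## Thermodynamic model

`thermo_model()` loads the unified DNA/DNA nearest-neighbor parameter set
(dinucleotide ΔH/ΔS plus terminal A:T / G:C initiation terms) from a
versioned plain-text file. Melting temperature uses the two-state formula
with the entropic monovalent-salt correction
ΔS′ = ΔS + 0.368 (N−1) ln[Na⁺] and a CT/4 concentration term for
non-self-complementary duplexes:

Tm = 1000·ΔH / (ΔS′ + R ln(CT/4)) − 273.15.

Defaults are 50 mM Na⁺-equivalent and 0.8 µM of each oligonucleotide —
the concentration a degenerate-primer PCR recipe typically uses. The
implementation agrees with an independent nearest-neighbor implementation
to better than 0.01 °C on a frozen reference oligo set (see
`test-thermo.R`).

For a degenerate primer, `tm_range()` enumerates all expansions up to a
cap (default 256) and reports exact extremes; beyond the cap it evaluates
AT-biased and GC-biased representative expansions. The heuristic stays
within 1.5 °C of enumerated truth on randomized tests up to degeneracy
1024, because Tm extremes are dominated by base composition rather than
by stacking order.

**Dimer screening** (`duplex_dG`, `dimer_screen`) is a deliberate
simplification: all ungapped antiparallel offsets of the two oligos are
scanned and 37 °C stacking free energies are summed over Watson–Crick
paired steps only — no bulges, internal loops, dangling ends or
initiation terms. For a −11 kcal/mol pass/fail screen this
stacking-only bound is sufficient and fully deterministic; it is not a
secondary-structure predictor. Hairpin self-structure is not modelled; a
future hairpin screen can reuse the same machinery. Degenerate primers
are screened over all expansion combinations while their number stays
within `enum_cap`, and over GC-extreme representatives beyond it.

## Genome validation semantics

Gene models are exon interval sets (`GRanges`, grouped by `Parent` from
GFF3). Coordinates are 1-based inclusive throughout — the native
convention of the R/Bioconductor interval stack, which is what makes the
interval arithmetic here safe; GFF3 needs no conversion.

Within a gene's locus the forward primer must match the coding strand and
the reverse primer the template strand, mismatch-free, as contiguous
genomic sequence. When several site combinations are convergent, the
shortest product is taken as the intended one (the alignment-implied
target plus introns; any longer combination would involve a spurious
repeat). The target region is the stretch *between* the binding sites;
`exonic_bp + intronic_bp == target_len` holds by construction, and the
product length additionally counts both primers and both tails.
Intron/exon accounting uses the source gene's model only; overlapping
features of other genes are ignored.

The secondary screen defaults (mismatch tolerance 2, mismatch-free
3'-terminal 6 nt, product cap 3000 bp) are stated assumptions — the
thresholds a PCR practitioner would consider amplification-competent —
and are configurable.

## Selection, tails, annealing

Validated pairs of one gene are ranked by ascending total degeneracy
(cheaper, cleaner pools first), ties broken by descending mean intronic
content (intron-rich amplicons carry more fast-evolving signal), then by
position; greedy selection enforces that any two kept target regions
overlap at most 50% of the shorter one. The ranking criterion is a
package design choice and is deliberately pluggable — any ordering can be
applied upstream of `select_per_gene`.

A sequencing-tail pair is compatible when both tailed primers still pass
the dimer screen at the same threshold. Every marker reports its
compatible tails and is flagged if none fits. The recommended annealing
temperature is min(Tm_min of both primers) − 3 °C — a deliberately simple
rule: the weakest expansion of either primer must still anneal.

## The synthetic-data generator

`generate_fixture()` emulates the study design the pipeline is meant for:
a panel of reference taxa (default 9) with one annotated genome each, a
set of 1:1 ortholog groups (default 20), and — unlike real data — a known
truth table. Per gene it plants two filter-passing conserved windows
(default 22 nt) separated by a target region, derives each taxon's CDS
from a root sequence by uniform per-site substitution (default 0.2)
outside the windows, inserts GT..AG introns at codon boundaries between
the windows into the genomic copies only, embeds genes in random
intergenic spacers (a configurable fraction on the minus strand), and
writes standard FASTA/GFF3 plus the truth table. Seeded runs are
bit-reproducible.

What it does **not** emulate: indel evolution (protein alignments are
gap-free; gap handling is exercised by handcrafted unit fixtures),
transition/transversion bias, codon-usage structure, and realistic intron
length distributions — intron lengths are drawn uniformly from 45–653 bp
(truncated to ≤ 600, or ≤ 300 each for two-intron genes) so that the
genomic target always respects the 1000-bp amplicon cap. Passing the
planted-recovery tests therefore demonstrates the pipeline's bookkeeping
and filter logic, not its behaviour under alignment error or unusual base
composition.

A `straddle_genes` option deliberately places an intron inside a planted
forward window to exercise the exon/intron-boundary rejection. One
subtlety the truth table accounts for: a boundary-interrupted window can
still match the genome at a small shift when the intron's `GT` donor
happens to extend the conserved sequence — a biologically real binding
site, which the validator correctly accepts; the *planted* pair itself is
always rejected.

## Numerical and engineering choices

* All scanning is deterministic; candidate and pair orders are fixed
  (position, then length, then orientation), so reruns are byte-identical.
* Degeneracies are exact products kept as doubles (exact far beyond any
  cap used here); enumeration refuses above an explicit cap rather than
  silently truncating.
* Enumeration caps: 256 for Tm ranges, 64 expansion combinations per
  duplex class for dimer screens, GC-extreme representatives beyond.
* The end-to-end test experiment uses 20 genes x 9 taxa at 20%
  divergence with one straddle gene — large enough that every pipeline
  stage (including minus-strand genes and multi-intron amplicons) is
  exercised, small enough to run comfortably on one CPU.
* Per-genome site searches are cached per primer sequence and gene locus
  during a run; candidate pairs heavily share primer sequences, and the
  cache removes the redundant genome scans without changing any result.
* The secondary-product screen is computed for the selected (reported)
  pairs; it is a pure report and never feeds selection, so this ordering
  choice cannot change the marker table.

## Known limitations

* Dimer screening is stacking-only (above); borderline ΔG values near the
  threshold deserve a dedicated secondary-structure tool before synthesis.
* Tm for degenerate pools above the enumeration cap is a two-sided
  heuristic, not a guarantee.
* Genomes are scanned in memory; chunked streaming is available through
  per-contig iteration, but no index structures are built, so very large
  assemblies will be slow.
* Gene models are trusted as given; no spliced-alignment re-inference is
  attempted.
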