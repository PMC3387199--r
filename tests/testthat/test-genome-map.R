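model <- thermo_model()
params <- design_params()

test_that("planted primers are found as primary sites", {
  set.seed(501)
  bg <- random_concrete(2000)
  primer <- "GATTACAGATTACAGATTAC"
  g <- paste0(substr(bg, 1, 700), primer, substr(bg, 721, 2000))
  genome <- c(chr1 = g)
  s <- find_binding_sites(primer, genome)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 701L)
  expect_equal(s$strand, "+")
  expect_true(s$primary)

  # a degenerate primer whose two expansions are planted at two loci
  dp <- "GATYACAGATTACAGATTAC"
  g2 <- paste0(substr(bg, 1, 300), "GATCACAGATTACAGATTAC",
               substr(bg, 321, 900), "GATTACAGATTACAGATTAC",
               substr(bg, 921, 2000))
  s2 <- find_binding_sites(dp, c(chr1 = g2))
  expect_equal(sum(s2$primary), 2L)
  expect_equal(s2$start[s2$primary], c(301L, 901L))
})

test_that("site finding equals the naive sliding-window scan", {
  set.seed(502)
  for (i in 1:6) {
    genome <- Biostrings::DNAStringSet(c(c1 = random_concrete(3000),
                                         c2 = random_concrete(1500)))
    primer <- random_iupac(12, max_d = 16)  # short => hits arise by chance
    mm <- sample(0:2, 1)
    got <- find_binding_sites(primer, genome, max_mismatch = mm)
    want <- oracle_find_sites(primer, genome, max_mm = mm)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("site finding is strand-symmetric under genome reverse complement", {
  set.seed(503)
  genome <- c(chr1 = random_concrete(4000))
  primer <- random_iupac(11, max_d = 8)
  s1 <- find_binding_sites(primer, genome, max_mismatch = 1)
  rc <- revcomp_iupac(genome[["chr1"]])
  s2 <- find_binding_sites(primer, c(chr1 = rc), max_mismatch = 1)
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sort(table(s1$strand)), sort(table(s2$strand)))
  expect_equal(sort(4000 - s1$end + 1), sort(s2$start))
})

# hand-built locus: spacer | exon1 | intron (200) | exon2 | spacer
build_locus <- function(fwd, rev_primer, gap1 = 150, gap2 = 180,
                        intron_len = 200) {
  set.seed(504)
  e1 <- paste0(random_concrete(30), fwd, random_concrete(gap1))
  e2 <- paste0(random_concrete(gap2), revcomp_iupac(rev_primer),
               random_concrete(30))
  intron <- paste0("GT", random_concrete(intron_len - 4), "AG")
  pre <- random_concrete(100); post <- random_concrete(100)
  g <- paste0(pre, e1, intron, e2, post)
  ex1 <- c(101, 100 + nchar(e1))
  ex2 <- c(100 + nchar(e1) + intron_len + 1,
           100 + nchar(e1) + intron_len + nchar(e2))
  exons <- gene_model("chr1", starts = c(ex1[1], ex2[1]),
                      ends = c(ex1[2], ex2[2]), strand = "+", gene = "gX")
  list(genome = c(chr1 = g), models = stats::setNames(list(exons), "gX"),
       e1 = e1, e2 = e2)
}

test_that("validate_pair accounts introns and exons exactly", {
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  loc <- build_locus(fwd, rev_primer, gap1 = 150, gap2 = 180,
                     intron_len = 200)
  pair <- list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer)
  v <- validate_pair(pair, loc$genome, loc$models, params)
  expect_true(v$accepted)
  a <- v$amplicon
  # target: 150 exonic after fwd + 200 intron + 180 exonic before rev
  expect_equal(a$target_len, 150 + 200 + 180)
  expect_equal(a$intronic_bp, 200)
  expect_equal(a$exonic_bp, 330)
  expect_equal(a$exonic_bp + a$intronic_bp, a$target_len)
  expect_equal(a$product_len, a$target_len + 40)
  # with tails accounted
  v2 <- validate_pair(pair, loc$genome, loc$models, params, tail_len = 36)
  expect_equal(v2$amplicon$product_len, a$target_len + 40 + 36)
})

test_that("a primer straddling an exon/intron boundary is rejected as such", {
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  loc <- build_locus(fwd, rev_primer)
  # move the intron into the middle of the forward primer: split e1 there
  set.seed(505)
  g0 <- loc$genome[["chr1"]]
  # rebuild: place intron 10 nt into the fwd primer
  pre <- random_concrete(100)
  head1 <- paste0(random_concrete(30), substr(fwd, 1, 10))
  tail1 <- paste0(substr(fwd, 11, 20), random_concrete(150))
  e2 <- paste0(random_concrete(180), revcomp_iupac(rev_primer),
               random_concrete(30))
  intron <- paste0("GT", random_concrete(196), "AG")
  g <- paste0(pre, head1, intron, tail1, e2, random_concrete(100))
  exons <- gene_model("chr1",
                      starts = c(101, 101 + nchar(head1) + 200),
                      ends = c(100 + nchar(head1),
                               100 + nchar(head1) + 200 + nchar(tail1) + nchar(e2) - 1),
                      strand = "+", gene = "gX")
  pair <- list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer)
  v <- validate_pair(pair, c(chr1 = g), stats::setNames(list(exons), "gX"),
                     params)
  expect_false(v$accepted)
  expect_equal(v$reason, "exon_intron_boundary")
})

test_that("intronless genes report zero intronic bp", {
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  set.seed(506)
  e <- paste0(random_concrete(25), fwd, random_concrete(400),
              revcomp_iupac(rev_primer), random_concrete(25))
  g <- paste0(random_concrete(80), e, random_concrete(80))
  exons <- gene_model("chr1", starts = 81, ends = 80 + nchar(e),
                      strand = "+", gene = "gX")
  v <- validate_pair(list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer),
                     c(chr1 = g), stats::setNames(list(exons), "gX"), params)
  expect_true(v$accepted)
  expect_equal(v$amplicon$intronic_bp, 0L)
  expect_equal(v$amplicon$target_len, v$amplicon$exonic_bp)
})

test_that("oversize products and absent primers reject; missing model errors", {
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  loc <- build_locus(fwd, rev_primer, gap1 = 600, gap2 = 600,
                     intron_len = 300)
  pair <- list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer)
  v <- validate_pair(pair, loc$genome, loc$models, params)
  expect_false(v$accepted)
  expect_equal(v$reason, "oversize_product")

  v2 <- validate_pair(list(gene = "gX", fwd_seq = "TTTTTGGGGGCCCCCAAAAA",
                           rev_seq = rev_primer),
                      loc$genome, loc$models, params)
  expect_false(v2$accepted)
  expect_equal(v2$reason, "no_binding_site")

  expect_error(validate_pair(list(gene = "nope", fwd_seq = fwd,
                                  rev_seq = rev_primer),
                             loc$genome, loc$models, params),
               "no gene model")
})

test_that("minus-strand gene models validate with swapped primer strands", {
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  loc <- build_locus(fwd, rev_primer)
  # reverse-complement the whole contig; exon coordinates mirror
  g <- loc$genome[["chr1"]]
  n <- nchar(g)
  rc <- revcomp_iupac(g)
  ex <- loc$models$gX
  starts <- n - GenomicRanges::end(ex) + 1
  ends <- n - GenomicRanges::start(ex) + 1
  exons <- gene_model("chr1", starts = sort(starts), ends = sort(ends),
                      strand = "-", gene = "gX")
  v <- validate_pair(list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer),
                     c(chr1 = rc), stats::setNames(list(exons), "gX"), params)
  expect_true(v$accepted)
  expect_equal(v$amplicon$intronic_bp, 200)
  expect_equal(v$amplicon$target_len, 530)
})

test_that("secondary products are reported and match a brute-force scan", {
  set.seed(507)
  fwd <- "GCCATCTTCGACTTCGACAG"
  rev_primer <- "TGGTGAGTACGCACCTAGTT"
  loc <- build_locus(fwd, rev_primer)
  # clean single-locus genome: no secondary entry beyond the intended one
  pair <- list(gene = "gX", fwd_seq = fwd, rev_seq = rev_primer)
  v <- validate_pair(pair, loc$genome, loc$models, params)
  rep0 <- secondary_product_screen(pair, loc$genome, params,
                                   intended = v$amplicon)
  expect_equal(nrow(rep0), 0L)
  expect_false(attr(rep0, "risky"))

  # plant a second convergent fwd/rev site pair 800 bp apart
  extra <- paste0(random_concrete(200), fwd, random_concrete(760),
                  revcomp_iupac(rev_primer), random_concrete(200))
  g2 <- c(chr1 = loc$genome[["chr1"]], chr2 = extra)
  rep1 <- secondary_product_screen(pair, g2, params, intended = v$amplicon)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$contig, "chr2")
  expect_equal(rep1$product_len, 800L)
  expect_true(attr(rep1, "risky"))
})

test_that("fixture GFF3 files round-trip through read_gene_models", {
  fx <- generate_fixture(fixture_spec(n_taxa = 2, n_genes = 2, seed = 33),
                         dir = tempfile())
  mods <- read_gene_models(file.path(fx$dir, "annotation", "taxon01.gff3"))
  expect_setequal(names(mods), c("g001", "g002"))
  ex <- mods[["g001"]]
  expect_true(all(GenomicRanges::width(ex) > 0))
  expect_true(!is.unsorted(GenomicRanges::start(ex)))
  # exon count = intron count + 1
  expect_equal(length(ex), fx$truth$n_introns[1] + 1L)
})
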