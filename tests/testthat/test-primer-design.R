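model <- thermo_model()

test_that("column consensus is the minimal covering IUPAC code", {
  expect_equal(column_consensus(c("AC", "AT", "AC")), "AY")
  expect_true(is.na(column_consensus(c("A-", "AT"))))
  expect_true(is.na(column_consensus(c("AN", "AT"))))
  expect_equal(column_consensus(c("A", "C", "G", "T")), "N")
  expect_equal(column_consensus("ACGT"), "ACGT")
})

test_that("default design parameters carry the standard constraint set", {
  p <- design_params()
  expect_equal(p$amplicon_len, c(300, 1000))
  expect_equal(p$primer_len, c(20L, 25L))
  expect_equal(p$max_degeneracy, 256)
  expect_equal(p$gc, c(20, 80))
  expect_equal(p$run_max, 4L)
  expect_equal(p$tm, c(45, 66))
  expect_equal(p$max_dTm, 10)
  expect_equal(p$dimer_threshold, -11.0)
  expect_equal(p$three_prime,
               list(window = 6L, max_degeneracy = 4, gc = c(20, 80),
                    run_max = 3L))
  expect_error(design_params(gc = c(90, 10)), "min <= max")
})

test_that("YAML config overrides individual keys only", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("max_degeneracy: 64", "tm: [50, 60]",
               "three_prime:", "  run_max: 2"), f)
  p <- design_params_from_yaml(f)
  expect_equal(p$max_degeneracy, 64)
  expect_equal(p$tm, c(50, 60))
  expect_equal(p$three_prime$run_max, 2)
  expect_equal(p$three_prime$window, 6L)  # untouched default
  writeLines("not_a_key: 1", f)
  expect_error(design_params_from_yaml(f), "unknown")
})

make_aln <- function(rows) codon_alignment(rows)

test_that("an identical alignment yields a candidate for every window", {
  seqlen <- 60
  set.seed(401)
  s <- random_concrete(seqlen)
  aln <- make_aln(c(a = s, b = s, c = s))
  relaxed <- design_params(gc = c(0, 100), tm = c(0, 200), run_max = 60L,
                           three_prime = list(window = 6L,
                                              max_degeneracy = 1e6,
                                              gc = c(0, 100), run_max = 60L))
  sites <- scan_gene(aln, relaxed, model)
  n_expected <- sum(seqlen - (20:25) + 1L) * 2L
  expect_equal(nrow(sites), n_expected)
  expect_true(all(sites$degeneracy == 1))
})

test_that("an N column kills every window crossing it", {
  s <- random_concrete(60)
  s2 <- paste0(substr(s, 1, 29), "N", substr(s, 31, 60))
  aln <- make_aln(c(a = s, b = s2))
  relaxed <- design_params(gc = c(0, 100), tm = c(0, 200), run_max = 60L,
                           three_prime = list(window = 6L,
                                              max_degeneracy = 1e6,
                                              gc = c(0, 100), run_max = 60L))
  sites <- scan_gene(aln, relaxed, model)
  expect_true(all(sites$end < 30 | sites$start > 30))
})

test_that("every row window is an expansion of the emitted consensus", {
  set.seed(402)
  fx <- generate_fixture(fixture_spec(n_taxa = 4, n_genes = 1,
                                      divergence = 0.25, seed = 31),
                         dir = tempfile())
  prot <- Biostrings::readAAStringSet(
    file.path(fx$dir, "alignments", "g001.prot.fasta"))
  cds <- Biostrings::readDNAStringSet(file.path(fx$dir, "cds", "g001.cds.fasta"))
  aln <- backtranslate(prot, cds)
  sites <- scan_gene(aln, design_params(), model, gene = "g001")
  expect_gt(nrow(sites), 0)
  for (i in sample(nrow(sites), min(10, nrow(sites)))) {
    st <- sites[i, ]
    cons <- if (st$orientation == "fwd") st$seq else revcomp_iupac(st$seq)
    sets <- lapply(strsplit(cons, "")[[1]],
                   function(cd) IUPAC_SETS[[cd]])
    for (row in aln$rows) {
      win <- strsplit(substr(row, st$start, st$end), "")[[1]]
      expect_true(all(mapply(function(s, b) b %in% s, sets, win)))
    }
  }
})

test_that("scanning recovers the planted conserved windows", {
  set.seed(403)
  fx <- generate_fixture(fixture_spec(n_taxa = 6, n_genes = 1,
                                      divergence = 0.45, seed = 32),
                         dir = tempfile())
  g <- fx$genes$g001
  prot <- Biostrings::readAAStringSet(
    file.path(fx$dir, "alignments", "g001.prot.fasta"))
  cds <- Biostrings::readDNAStringSet(file.path(fx$dir, "cds", "g001.cds.fasta"))
  aln <- backtranslate(prot, cds)
  sites <- scan_gene(aln, design_params(), model, gene = "g001")
  fwd <- sites[sites$orientation == "fwd", ]
  rev_ <- sites[sites$orientation == "rev", ]
  # at 45% background divergence every candidate window must anchor in a
  # planted conserved window (low-degeneracy flanks reach a few columns out)
  ov <- function(s, e, ws, we) pmin(e, we) - pmax(s, ws) + 1
  expect_true(all(ov(sites$start, sites$end, g$fwd_start, g$fwd_end) >= 10 |
                    ov(sites$start, sites$end, g$rev_start, g$rev_end) >= 10))
  expect_true(any(fwd$start >= g$fwd_start & fwd$end <= g$fwd_end))
  expect_true(any(rev_$start >= g$rev_start & rev_$end <= g$rev_end))
})

test_that("deterministic output order and rerun stability", {
  set.seed(404)
  s <- random_concrete(90)
  aln <- make_aln(c(a = s, b = s))
  sites1 <- scan_gene(aln, design_params(), model)
  sites2 <- scan_gene(aln, design_params(), model)
  expect_identical(sites1, sites2)
  expect_true(!is.unsorted(sites1$start))
})

test_that("filters are pure predicates: verdicts compose order-independently", {
  set.seed(406)
  fx <- generate_fixture(fixture_spec(n_taxa = 4, n_genes = 1,
                                      divergence = 0.3, seed = 34),
                         dir = tempfile())
  prot <- Biostrings::readAAStringSet(
    file.path(fx$dir, "alignments", "g001.prot.fasta"))
  cds <- Biostrings::readDNAStringSet(file.path(fx$dir, "cds", "g001.cds.fasta"))
  aln <- backtranslate(prot, cds)
  diag <- scan_gene(aln, design_params(), model, gene = "g001",
                    keep_rejected = TRUE)
  expect_gt(nrow(diag), 0)
  # the survivor set is the conjunction of the individual verdicts, so any
  # application order yields the same set
  conj <- diag$d_ok & diag$gc_ok & diag$run_ok & diag$three_prime_ok &
    diag$tm_ok
  expect_equal(diag$pass, conj)
  plain <- scan_gene(aln, design_params(), model, gene = "g001")
  expect_equal(nrow(plain), sum(diag$pass))
  expect_equal(plain$seq, diag$seq[diag$pass])
})

test_that("form_pairs equals a brute-force double loop on a site fixture", {
  set.seed(405)
  p <- design_params()
  # synthetic site table: concrete primers at controlled spacings
  mk_site <- function(start, ori) {
    s <- random_concrete(20)
    tmr <- tm_range(s, model)
    data.frame(gene = "g", start = start, end = start + 19L, width = 20L,
               orientation = ori, seq = s, degeneracy = 1,
               gc_min = unname(gc_range(s)[1]), gc_max = unname(gc_range(s)[2]),
               run = max_run(s), tm_min = tmr[["min"]], tm_max = tmr[["max"]],
               stringsAsFactors = FALSE)
  }
  sites <- rbind(
    do.call(rbind, lapply(c(1, 40, 80, 200, 700), mk_site, ori = "fwd")),
    do.call(rbind, lapply(c(30, 420, 460, 520, 1500), mk_site, ori = "rev")))
  got <- form_pairs(sites, p, model)
  # independent re-derivation with the same predicates
  expected <- 0L
  fwd <- sites[sites$orientation == "fwd", ]
  rvs <- sites[sites$orientation == "rev", ]
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rvs))) {
    tgt <- rvs$start[j] - fwd$end[i] - 1L
    if (rvs$start[j] <= fwd$end[i]) next
    if (tgt < 300 || tgt > 1000) next
    if (abs((fwd$tm_min[i] + fwd$tm_max[i]) / 2 -
              (rvs$tm_min[j] + rvs$tm_max[j]) / 2) > 10) next
    if (!dimer_screen(fwd$seq[i], rvs$seq[j], model = model)$pass) next
    expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
  if (nrow(got)) {
    expect_true(all(got$target_cols >= 300 & got$target_cols <= 1000))
    expect_equal(got$total_degeneracy,
                 got$fwd_degeneracy * got$rev_degeneracy)
  }
})
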