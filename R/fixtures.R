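# Seeded synthetic-data generator: ortholog groups, codon alignments and
# annotated mini-genomes with planted conserved primer windows, so the whole
# pipeline can be exercised and truth-checked without external data.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

# sample() guards: never fall into the scalar-expansion trap
.pick1 <- function(x) x[sample.int(length(x), 1L)]
.pick_int <- function(lo, hi, k = 1L) {
  lo + sample.int(hi - lo + 1L, k, replace = TRUE) - 1L
}

#' Specification of a synthetic fixture bundle
#'
#' Describes the simulated study conditions: number of taxa and genes,
#' background per-site divergence outside the planted primer windows,
#' planted window length, intron counts, and the random seed. Seeded runs
#' are bit-reproducible.
#'
#' @param n_taxa Number of reference taxa (default 9).
#' @param n_genes Number of 1:1 ortholog groups (default 20).
#' @param divergence Per-site substitution probability per taxon outside
#'   the planted windows (default 0.2).
#' @param window_divergence Substitution probability inside the planted
#'   windows (default 0: windows are mutation-free and hence recoverable).
#' @param window_len Planted primer-window length in nt (default 22).
#' @param introns_per_gene Length-2 integer range of intron counts per gene
#'   (default `c(1, 2)`), all placed between the two planted windows.
#' @param intron_len Length-2 range intron lengths are drawn from (default
#'   `c(45, 653)`); two-intron genes draw from `c(min, 300)` so the genomic
#'   target stays within the 1000-bp amplicon bound.
#' @param target_cols Length-2 range of the exonic target-region length
#'   (alignment columns between the windows; default `c(310, 380)`).
#' @param spacer_len Length-2 range of intergenic spacer lengths.
#' @param minus_strand_frac Fraction of genes placed on the minus strand of
#'   their contig (default 0.3).
#' @param straddle_genes Integer indices of genes whose forward window is
#'   deliberately interrupted by an intron (an exon/intron-boundary primer,
#'   which the genome validation must reject).
#' @param seed Integer random seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_taxa = 9L, n_genes = 20L, divergence = 0.2,
                         window_divergence = 0, window_len = 22L,
                         introns_per_gene = c(1L, 2L),
                         intron_len = c(45L, 653L),
                         target_cols = c(310L, 380L),
                         spacer_len = c(100L, 300L),
                         minus_strand_frac = 0.3,
                         straddle_genes = integer(0),
                         seed = 1L) {
  stopifnot(n_taxa >= 2, n_genes >= 1, divergence >= 0, divergence <= 1,
            window_len >= 20, intron_len[1] >= 10,
            all(straddle_genes %in% seq_len(n_genes)))
  structure(as.list(environment()), class = "fixture_spec")
}

.random_codons <- function(n) {
  repeat {
    s <- paste0(sample(.BASES, 3 * n, replace = TRUE), collapse = "")
    codons <- substring(s, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
    if (!any(codons %in% .STOP_CODONS)) return(s)
  }
}

# draw a window sequence that passes the full filter battery in the given
# orientation and introduces no in-frame stop at its frame offset
.draw_window <- function(len, orientation, frame_off, params, model) {
  repeat {
    w <- paste0(sample(.BASES, len, replace = TRUE), collapse = "")
    pad <- paste0(c(rep("A", frame_off), strsplit(w, "")[[1]]), collapse = "")
    ncod <- floor(nchar(pad) / 3)
    codons <- substring(pad, seq(1, ncod * 3, 3), seq(3, ncod * 3, 3))
    if (any(codons %in% .STOP_CODONS)) next
    if (.site_filters(w, orientation, params, model)$pass) return(w)
  }
}

# mutate a CDS per-site (uniform replacement to a different base), skipping
# frozen positions; repairs any codon that became an in-frame stop by
# redrawing its mutable positions
.mutate_cds <- function(cds, rate, frozen, window_rate = 0, windows = NULL) {
  ch <- strsplit(cds, "")[[1]]
  n <- length(ch)
  rate_vec <- rep(rate, n)
  if (!is.null(windows)) rate_vec[windows] <- window_rate
  rate_vec[frozen] <- 0
  hit <- stats::runif(n) < rate_vec
  for (i in which(hit)) ch[i] <- .pick1(setdiff(.BASES, ch[i]))
  # repair in-frame stops using positions that are free to vary
  for (ci in seq_len(n / 3)) {
    idx <- (3 * ci - 2):(3 * ci)
    for (tries in 1:50) {
      if (!paste0(ch[idx], collapse = "") %in% .STOP_CODONS) break
      mutable <- idx[!idx %in% frozen & !(idx %in% windows & window_rate == 0)]
      if (!length(mutable)) stop("cannot repair stop codon adjacent to frozen window")
      p <- .pick1(mutable)
      ch[p] <- .pick1(.BASES)
    }
  }
  paste0(ch, collapse = "")
}

.rand_intron <- function(len) {
  paste0("GT", paste0(sample(.BASES, len - 4, replace = TRUE), collapse = ""), "AG")
}

#' Generate a synthetic fixture bundle
#'
#' Builds `n_genes` ortholog groups: a root CDS per gene (codon-wise, no
#' in-frame stops) with two planted filter-passing primer windows, taxa
#' derived by per-site substitution outside the windows, introns
#' (GT..AG-bounded, at codon boundaries between the windows) inserted into
#' the genomic copies only, one genome contig per taxon with genes embedded
#' in random intergenic spacers (a configurable fraction on the minus
#' strand), and a truth table of planted windows and expected per-taxon
#' amplicon spans.
#'
#' Written outputs per bundle: `genomes/<taxon>.fasta`,
#' `annotation/<taxon>.gff3`, `alignments/<gene>.prot.fasta` (aligned
#' protein rows), `cds/<gene>.cds.fasta`, and `truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param params,model Filter settings the planted windows are guaranteed
#'   to satisfy; defaults [design_params()] / [thermo_model()].
#' @return Invisibly, a list: `dir`, `truth` (`data.frame`), `genes`
#'   (per-gene plant metadata), `taxa`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture"),
                             params = design_params(), model = thermo_model()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  taxa <- sprintf("taxon%02d", seq_len(spec$n_taxa))
  genes <- sprintf("g%03d", seq_len(spec$n_genes))
  for (d in c("genomes", "annotation", "alignments", "cds")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  lead <- 30L; trail <- 30L
  wl <- spec$window_len
  truth <- list(); gene_meta <- list()
  # per-taxon accumulators for genome assembly
  contigs <- stats::setNames(vector("list", spec$n_taxa), taxa)

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    straddle <- gi %in% spec$straddle_genes
    n_intron <- .pick_int(spec$introns_per_gene[1], spec$introns_per_gene[2])
    ilen_max <- if (n_intron >= 2) min(spec$intron_len[2], 300L) else
      min(spec$intron_len[2], 600L)
    intron_lens <- .pick_int(spec$intron_len[1], ilen_max, n_intron)
    tcols <- .pick_int(spec$target_cols[1], spec$target_cols[2])

    f_start <- lead + 1L
    f_end <- f_start + wl - 1L
    r_start <- f_end + tcols + 1L
    r_end <- r_start + wl - 1L
    len_nt <- r_end + trail
    len_nt <- len_nt + (3L - len_nt %% 3L) %% 3L
    n_cod <- len_nt / 3L

    # planted windows must pass the filter battery and pair cleanly
    repeat {
      fwd_w <- .draw_window(wl, "fwd", (f_start - 1L) %% 3L, params, model)
      rev_w <- .draw_window(wl, "rev", (r_start - 1L) %% 3L, params, model)
      fwd_primer <- fwd_w
      rev_primer <- revcomp_iupac(rev_w)
      tm_f <- tm_range(fwd_primer, model); tm_r <- tm_range(rev_primer, model)
      if (abs(mean(tm_f) - mean(tm_r)) > params$max_dTm - 1) next
      if (!dimer_screen(fwd_primer, rev_primer,
                        threshold = params$dimer_threshold, model = model,
                        enum_cap = params$enum_cap)$pass) next
      break
    }

    # root CDS with the windows substituted in, stop-free
    repeat {
      root <- .random_codons(n_cod)
      substr(root, f_start, f_end) <- fwd_w
      substr(root, r_start, r_end) <- rev_w
      codons <- substring(root, seq(1, len_nt, 3), seq(3, len_nt, 3))
      if (!any(codons %in% .STOP_CODONS)) break
    }
    win_idx <- c(f_start:f_end, r_start:r_end)

    # intron positions: codon boundaries; between the windows, or (straddle)
    # the first one inside the forward window
    target_span <- (f_end + 1L):(r_start - 1L)
    cand <- target_span[target_span %% 3L == 1L]
    cand <- cand[cand > f_end + 15L & cand < r_start - 15L]
    ipos <- sort(cand[sample.int(length(cand), n_intron)])
    while (n_intron > 1 && any(diff(ipos) < 30L)) ipos <- sort(cand[sample.int(length(cand), n_intron)])
    if (straddle) {
      inwin <- (f_start:f_end)[(f_start:f_end) %% 3L == 1L]
      inwin <- inwin[inwin > f_start + 2L & inwin < f_end - 2L]
      ipos[1] <- inwin[1]
      ipos <- sort(ipos)
    }

    cds_rows <- character(spec$n_taxa); names(cds_rows) <- taxa
    for (ti in seq_along(taxa)) {
      cds_rows[ti] <- .mutate_cds(root, spec$divergence, frozen = integer(0),
                                  window_rate = spec$window_divergence,
                                  windows = win_idx)
    }
    prot_rows <- vapply(cds_rows, .translate_cds,
                        character(1), genetic_code = Biostrings::GENETIC_CODE)

    # genomic copies: insert taxon-specific intron sequences at shared
    # positions/lengths; record exon segment boundaries within the gene
    seg_starts <- c(1L, ipos)
    seg_ends <- c(ipos - 1L, len_nt)
    for (ti in seq_along(taxa)) {
      tx <- taxa[ti]
      exon_seqs <- substring(cds_rows[ti], seg_starts, seg_ends)
      intr_seqs <- vapply(intron_lens, .rand_intron, character(1))
      parts <- character(0)
      ex_off <- integer(0); off <- 0L
      for (k in seq_along(exon_seqs)) {
        parts <- c(parts, exon_seqs[k])
        ex_off <- rbind(ex_off, c(off + 1L, off + nchar(exon_seqs[k])))
        off <- off + nchar(exon_seqs[k])
        if (k <= length(intr_seqs)) {
          parts <- c(parts, intr_seqs[k])
          off <- off + nchar(intr_seqs[k])
        }
      }
      gseq <- paste0(parts, collapse = "")
      contigs[[tx]] <- c(contigs[[tx]], list(list(gene = g, seq = gseq,
                                                  exons = ex_off)))
    }

    gene_meta[[g]] <- list(
      gene = g, fwd_primer = fwd_primer, rev_primer = rev_primer,
      fwd_start = f_start, fwd_end = f_end, rev_start = r_start,
      rev_end = r_end, target_cols = tcols, n_introns = n_intron,
      intron_lens = intron_lens, straddle = straddle)
    truth[[g]] <- data.frame(
      gene = g, fwd_primer = fwd_primer, rev_primer = rev_primer,
      fwd_start = f_start, fwd_end = f_end,
      rev_start = r_start, rev_end = r_end,
      target_cols = tcols, n_introns = n_intron,
      intronic_bp = if (straddle) NA_integer_ else sum(intron_lens),
      target_len_genomic = if (straddle) NA_integer_ else tcols + sum(intron_lens),
      straddle = straddle, stringsAsFactors = FALSE)

    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(prot_rows),
      file.path(dir, "alignments", paste0(g, ".prot.fasta")))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(cds_rows),
      file.path(dir, "cds", paste0(g, ".cds.fasta")))
  }

  # assemble one contig per taxon: spacer, gene, spacer, gene, ...
  minus <- stats::runif(spec$n_genes) < spec$minus_strand_frac
  for (ti in seq_along(taxa)) {
    tx <- taxa[ti]
    seqparts <- character(0)
    rows <- list(); pos <- 0L
    for (k in seq_along(contigs[[tx]])) {
      sp <- .pick_int(spec$spacer_len[1], spec$spacer_len[2])
      seqparts <- c(seqparts, paste0(sample(.BASES, sp, replace = TRUE),
                                     collapse = ""))
      pos <- pos + sp
      entry <- contigs[[tx]][[k]]
      gseq <- entry$seq
      M <- nchar(gseq)
      strand <- if (minus[k]) "-" else "+"
      exons <- entry$exons
      if (strand == "-") {
        gseq <- revcomp_iupac(gseq)
        exons <- cbind(M - exons[, 2] + 1L, M - exons[, 1] + 1L)
        exons <- exons[order(exons[, 1]), , drop = FALSE]
      }
      g_start <- pos + 1L
      seqparts <- c(seqparts, gseq)
      pos <- pos + M
      rows[[length(rows) + 1L]] <- data.frame(
        gene = entry$gene, start = g_start, end = pos, strand = strand,
        ex_start = g_start + exons[, 1] - 1L,
        ex_end = g_start + exons[, 2] - 1L, stringsAsFactors = FALSE)
    }
    sp <- .pick_int(spec$spacer_len[1], spec$spacer_len[2])
    seqparts <- c(seqparts, paste0(sample(.BASES, sp, replace = TRUE),
                                   collapse = ""))
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste0(seqparts, collapse = ""), "chr1"))
    Biostrings::writeXStringSet(genome,
                                file.path(dir, "genomes", paste0(tx, ".fasta")))
    ann <- do.call(rbind, rows)
    .write_gff3(ann, file.path(dir, "annotation", paste0(tx, ".gff3")))
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(dir = dir, truth = truth, genes = gene_meta, taxa = taxa))
}

# GFF3 writer for the fixture's gene/exon rows (one gene feature plus its
# exon features, Parent-linked)
.write_gff3 <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(ann$gene)) {
    a <- ann[ann$gene == g, ]
    writeLines(sprintf("chr1\tdegeprimr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       a$start[1], a$end[1], a$strand[1], g), con)
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf(
        "chr1\tdegeprimr\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        a$ex_start[i], a$ex_end[i], a$strand[i], g, i, g), con)
    }
  }
}
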