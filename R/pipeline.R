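# Pipeline composition and I/O: run configuration, the end-to-end design
# run over a bundle of alignments + genomes, and re-validation of external
# primer tables.

#' Run configuration for an end-to-end design run
#'
#' @param alignment_dir Directory of aligned protein FASTA files
#'   (`<gene>.prot.fasta`).
#' @param cds_dir Directory of unaligned CDS FASTA files
#'   (`<gene>.cds.fasta`).
#' @param genome_dir Directory of genome FASTA files (`<taxon>.fasta`).
#' @param annotation_dir Directory of GFF3 files (`<taxon>.gff3`).
#' @param out_dir Output directory for reports (created if needed); `NULL`
#'   suppresses file output.
#' @param params A [design_params()].
#' @param model A [thermo_model()].
#' @param tails Sequencing-tail catalog ([sequencing_tails()]).
#' @param require_all_genomes Keep only pairs validating in every genome
#'   (default `TRUE`).
#' @param max_overlap Per-gene amplicon overlap limit (default 0.5).
#' @param seed Integer seed recorded with the run (the design stage itself
#'   is deterministic).
#' @param verbose Emit per-stage counts via [message()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(alignment_dir, cds_dir, genome_dir, annotation_dir,
                       out_dir = NULL, params = design_params(),
                       model = thermo_model(), tails = sequencing_tails(),
                       require_all_genomes = TRUE, max_overlap = 0.5,
                       seed = 1L, verbose = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run configuration pointing at a fixture bundle
#'
#' @param dir A directory written by [generate_fixture()].
#' @param ... Passed on to [run_config()].
#' @return A [run_config()].
#' @export
run_config_from_fixture <- function(dir, ...) {
  run_config(alignment_dir = file.path(dir, "alignments"),
             cds_dir = file.path(dir, "cds"),
             genome_dir = file.path(dir, "genomes"),
             annotation_dir = file.path(dir, "annotation"), ...)
}

.read_named <- function(path, reader) {
  x <- reader(path)
  stats::setNames(as.character(x), sub(" .*", "", names(x)))
}

# tail name "...-X" -> code letter "X"
.tail_code <- function(name) sub(".*-", "", name)

#' Execute the full primer design pipeline
#'
#' For every gene: back-translate the protein alignment onto its CDSs, scan
#' for candidate sites, form pairs, validate each pair against every
#' reference genome (exon/intron boundaries, product size, intron/exon
#' accounting), screen for secondary products, select an overlap-limited
#' pair set per gene, test sequencing-tail compatibility, and emit the
#' final marker table. Per-gene failures are quarantined and reported, not
#' fatal.
#'
#' @param config A [run_config()].
#' @return List: `markers` (final table, one row per selected pair),
#'   `amplicons` (long-form per-genome predictions), `counts` (per-stage
#'   totals), `rejections` (pair-level rejection log), `risks`
#'   (secondary-product report for the selected pairs), `failed_genes`.
#' @export
run_design <- function(config) {
  stopifnot(inherits(config, "run_config"))
  params <- config$params; model <- config$model
  aln_files <- sort(list.files(config$alignment_dir, "\\.prot\\.fasta$",
                               full.names = TRUE))
  if (!length(aln_files)) {
    genes <- character(0)
  } else {
    genes <- sub("\\.prot\\.fasta$", "", basename(aln_files))
  }
  genome_files <- sort(list.files(config$genome_dir, "\\.fasta$",
                                  full.names = TRUE))
  taxa <- sub("\\.fasta$", "", basename(genome_files))
  genomes <- lapply(genome_files, Biostrings::readDNAStringSet)
  names(genomes) <- taxa
  for (tx in taxa) names(genomes[[tx]]) <- sub(" .*", "", names(genomes[[tx]]))
  models <- lapply(file.path(config$annotation_dir, paste0(taxa, ".gff3")),
                   read_gene_models)
  names(models) <- taxa
  caches <- lapply(taxa, function(tx) new.env(parent = emptyenv()))
  names(caches) <- taxa

  counts <- c(genes = length(genes), candidate_sites = 0, pairs = 0,
              validated = 0, selected = 0)
  markers <- list(); amplicons <- list(); rejections <- list()
  risks <- list()
  failed <- character(0)

  process_gene <- function(g) {
    prot <- .read_named(file.path(config$alignment_dir,
                                  paste0(g, ".prot.fasta")),
                        Biostrings::readAAStringSet)
    cds <- .read_named(file.path(config$cds_dir, paste0(g, ".cds.fasta")),
                       Biostrings::readDNAStringSet)
    aln <- backtranslate(prot, cds)
    sites <- scan_gene(aln, params, model, gene = g)
    counts["candidate_sites"] <<- counts["candidate_sites"] + nrow(sites)
    pairs <- form_pairs(sites, params, model)
    counts["pairs"] <<- counts["pairs"] + nrow(pairs)
    keep <- list()
    for (i in seq_len(nrow(pairs))) {
      amps <- list(); ok <- TRUE
      for (tx in taxa) {
        v <- .validate_core(pairs$fwd_seq[i], pairs$rev_seq[i], g,
                            genomes[[tx]], models[[tx]], params,
                            cache = caches[[tx]])
        if (!v$accepted) {
          rejections[[length(rejections) + 1L]] <<- data.frame(
            gene = g, pair_row = i, taxon = tx, reason = v$reason,
            stringsAsFactors = FALSE)
          ok <- FALSE
          if (config$require_all_genomes) break
        } else {
          v$amplicon$taxon <- tx
          amps[[tx]] <- v$amplicon
        }
      }
      if (config$require_all_genomes && !ok) next
      if (!length(amps)) next
      pr <- pairs[i, ]
      pr$mean_target_len <- mean(vapply(amps, `[[`, numeric(1), "target_len"))
      pr$intronic_bp <- mean(vapply(amps, `[[`, numeric(1), "intronic_bp"))
      pr$exonic_bp <- mean(vapply(amps, `[[`, numeric(1), "exonic_bp"))
      keep[[length(keep) + 1L]] <- list(pair = pr, amps = amps)
    }
    counts["validated"] <<- counts["validated"] + length(keep)
    if (!length(keep)) return(NULL)
    kp <- do.call(rbind, lapply(keep, `[[`, "pair"))
    sel <- select_per_gene(kp, max_overlap = config$max_overlap)
    counts["selected"] <<- counts["selected"] + nrow(sel)
    # divergence over the amplified target region (between the primers)
    rows <- vapply(aln$rows, function(r) r, character(1))
    sel$mean_p_distance <- vapply(seq_len(nrow(sel)), function(i) {
      reg <- substr(rows, sel$target_start[i], sel$target_end[i])
      100 * p_distance_matrix(reg)$mean
    }, numeric(1))
    out <- list()
    for (i in seq_len(nrow(sel))) {
      pr <- sel[i, ]
      amp0 <- keep[[which(vapply(keep, function(k)
        identical(k$pair$fwd_start, pr$fwd_start) &&
          identical(k$pair$rev_start, pr$rev_start), logical(1)))[1]]]$amps
      amp0 <- do.call(rbind, lapply(amp0, function(a) {
        a$taxon <- as.character(a$taxon)
        as.data.frame(a, stringsAsFactors = FALSE)
      }))
      compat <- tail_compatibility(pr, config$tails, model,
                                   threshold = params$dimer_threshold,
                                   enum_cap = params$enum_cap)
      code <- if (length(compat)) .tail_code(compat[1]) else "X"
      pr$pair_id <- sprintf("%s_%02d_%s", g, i, code)
      # secondary-product risk is assessed for the reported pairs only; it
      # does not feed the selection ranking
      pr$risky_secondary <- FALSE
      for (ai in seq_len(nrow(amp0))) {
        tx <- amp0$taxon[ai]
        scr <- secondary_product_screen(pr, genomes[[tx]], params,
                                        intended = amp0[ai, ])
        if (nrow(scr)) {
          scr$taxon <- tx
          scr$pair_id <- pr$pair_id
          risks[[length(risks) + 1L]] <<- scr
        }
        pr$risky_secondary <- pr$risky_secondary || isTRUE(attr(scr, "risky"))
      }
      pr$compatible_tails <- paste(compat, collapse = ",")
      pr$tail_flagged <- length(compat) == 0
      if (length(compat)) {
        trow <- config$tails[config$tails$name == compat[1], ]
        pr$fwd_tailed <- attach_tail(pr$fwd_seq, trow$forward)
        pr$rev_tailed <- attach_tail(pr$rev_seq, trow$reverse)
        tl <- nchar(trow$forward) + nchar(trow$reverse)
      } else {
        pr$fwd_tailed <- pr$fwd_seq; pr$rev_tailed <- pr$rev_seq
        tl <- 0L
      }
      pr$annealing_C <- recommend_annealing(pr, offset = params$annealing_offset)
      amp <- amp0
      amp$pair_id <- pr$pair_id
      amp$gene <- g
      amp$product_len <- amp$target_len + nchar(pr$fwd_seq) +
        nchar(pr$rev_seq) + tl
      amplicons[[length(amplicons) + 1L]] <<- amp
      out[[length(out) + 1L]] <- pr
    }
    do.call(rbind, out)
  }

  for (g in genes) {
    res <- tryCatch(process_gene(g), error = function(e) {
      failed <<- c(failed, g)
      warning(sprintf("gene %s failed: %s", g, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) markers[[length(markers) + 1L]] <- res
  }

  markers <- if (length(markers)) do.call(rbind, markers) else
    data.frame(pair_id = character(), gene = character(),
               stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  amplicons <- if (length(amplicons)) do.call(rbind, amplicons) else
    data.frame(pair_id = character(), taxon = character(),
               stringsAsFactors = FALSE)
  rownames(amplicons) <- NULL
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(gene = character(), taxon = character(), reason = character(),
               stringsAsFactors = FALSE)
  risks <- if (length(risks)) do.call(rbind, risks) else
    data.frame(pair_id = character(), taxon = character(),
               contig = character(), product_len = integer(),
               stringsAsFactors = FALSE)
  rownames(risks) <- NULL
  if (config$verbose) {
    message(paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(markers, file.path(config$out_dir, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(amplicons, file.path(config$out_dir, "amplicons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rejections, file.path(config$out_dir, "rejections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(risks, file.path(config$out_dir, "secondary_risks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(markers)) {
      export_primers_fasta(markers,
                           file.path(config$out_dir, "tailed_primers.fasta"))
    }
  }
  list(markers = markers, amplicons = amplicons, counts = counts,
       rejections = rejections, risks = risks, failed_genes = failed)
}

#' Re-validate an external primer table
#'
#' Reads a primer-pair table (TSV with columns `id`, `forward`, `reverse`;
#' further columns are preserved) and recomputes, per primer, the
#' degeneracy, length, GC range, worst-case run, 3'-window verdicts and Tm
#' range, plus the pair's total degeneracy and filter conformance under the
#' given parameters.
#'
#' @param x Path to a TSV file, or a `data.frame` with the same columns.
#' @param params A [design_params()].
#' @param model A [thermo_model()].
#' @return `data.frame`, one row per pair, with `fwd_d`/`rev_d`/`total_d`
#'   and per-primer verdict columns (`*_len_ok`, `*_d_ok`, `*_run_ok`,
#'   `*_three_prime_ok`, and combined `pass`).
#' @export
check_primers <- function(x, params = design_params(), model = thermo_model()) {
  tab <- if (is.character(x)) {
    utils::read.table(x, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
  } else x
  stopifnot(all(c("id", "forward", "reverse") %in% names(tab)))
  one <- function(seq, prefix) {
    seq <- iupac(seq)
    n <- nchar(seq)
    d <- degeneracy(seq)
    gr <- unname(gc_range(seq))
    tp <- params$three_prime
    t3 <- three_prime_checks(seq, window = tp$window,
                             max_degeneracy = tp$max_degeneracy, gc = tp$gc,
                             run_max = tp$run_max, gc_mode = params$gc_mode)
    tmr <- unname(tm_range(seq, model, enum_cap = max(params$enum_cap, 256)))
    out <- list(n, d, gr[1], gr[2], max_run(seq), tmr[1], tmr[2],
                n >= params$primer_len[1] && n <= params$primer_len[2],
                d <= params$max_degeneracy, max_run(seq) <= params$run_max,
                t3$pass)
    names(out) <- paste0(prefix, c("_len", "_d", "_gc_min", "_gc_max", "_run",
                                   "_tm_min", "_tm_max", "_len_ok", "_d_ok",
                                   "_run_ok", "_three_prime_ok"))
    out
  }
  res <- lapply(seq_len(nrow(tab)), function(i) {
    f <- one(tab$forward[i], "fwd")
    r <- one(tab$reverse[i], "rev")
    c(list(id = tab$id[i]), f, r,
      list(total_d = f$fwd_d * r$rev_d,
           pass = f$fwd_len_ok && f$fwd_d_ok && f$fwd_run_ok &&
             f$fwd_three_prime_ok && r$rev_len_ok && r$rev_d_ok &&
             r$rev_run_ok && r$rev_three_prime_ok))
  })
  out <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
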