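# Validation of candidate primer pairs against annotated reference genomes:
# binding-site search (exact and approximate), exon/intron-boundary and
# product-size rejection, amplicon intron/exon accounting, and screening
# for secondary amplification products.

#' Read gene models (exon structures) from a GFF3 file
#'
#' Imports `exon` features and groups them by their `Parent` attribute
#' (falling back to `ID`/`gene_id` when `Parent` is absent). GFF3 1-based
#' inclusive coordinates are kept, matching the `GRanges` convention used
#' throughout the package.
#'
#' @param path Path to a GFF3 file.
#' @return A named `GRangesList`, one element of sorted, non-overlapping
#'   exons per gene.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  if (!length(parent) || all(is.na(parent)) || all(parent == "character(0)")) {
    stop("exon features lack Parent attributes in ", path)
  }
  grl <- GenomicRanges::split(ex, parent)
  grl <- S4Vectors::endoapply(grl, function(g) GenomicRanges::sort(g, ignore.strand = TRUE))
  for (nm in names(grl)) {
    g <- grl[[nm]]
    if (length(GenomicRanges::reduce(g, ignore.strand = TRUE)) != length(g)) {
      stop("overlapping exons in gene model ", nm)
    }
  }
  grl
}

#' Build a gene model from exon coordinates
#'
#' Convenience constructor for a single gene's exon structure without going
#' through GFF3.
#'
#' @param contig Sequence name.
#' @param starts,ends Integer vectors of exon starts/ends (1-based,
#'   inclusive).
#' @param strand `"+"` or `"-"`.
#' @param gene Gene identifier.
#' @return A `GRanges` of exons, sorted along the genome.
#' @export
gene_model <- function(contig, starts, ends, strand = "+", gene = "gene") {
  stopifnot(length(starts) == length(ends), all(starts <= ends))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(start = starts, end = ends),
                               strand = strand)
  S4Vectors::mcols(gr)$Parent <- gene
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# mismatch count of an IUPAC pattern laid over a concrete window (pattern
# position matches when the window base is in the code's set)
.iupac_mismatches <- function(pat_sets, window_chars) {
  sum(!mapply(function(s, b) b %in% s, pat_sets, window_chars))
}

#' Find genomic binding sites of a degenerate primer
#'
#' Searches both strands of every contig for positions where some concrete
#' expansion of the primer matches with at most `max_mismatch` mismatches.
#' Matching treats the primer's IUPAC codes as base sets against the fixed
#' genome letters. Sites with zero mismatches are flagged `primary`. For a
#' minus-strand site the reported `start`/`end` are plus-strand coordinates
#' of the matched region (the primer reads 5'->3' along the minus strand).
#'
#' @param primer IUPAC sequence (5'->3').
#' @param genome A `DNAStringSet` (or named character vector) of contigs.
#' @param max_mismatch Maximum mismatches (default 0).
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `mismatches`, `primary`, ordered by contig, start, strand.
#' @export
find_binding_sites <- function(primer, genome, max_mismatch = 0L) {
  stopifnot(max_mismatch >= 0)
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  pat_f <- Biostrings::DNAString(iupac(primer))
  pat_r <- Biostrings::reverseComplement(pat_f)
  hits <- list()
  for (ci in seq_along(genome)) {
    subj <- genome[[ci]]
    for (str in c("+", "-")) {
      pat <- if (str == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = "subject")
      if (!length(m)) next
      st <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        with.indels = FALSE, fixed = "subject")
      hits[[length(hits) + 1L]] <- data.frame(
        contig = names(genome)[ci], start = st, end = Biostrings::end(m),
        strand = str, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), primary = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res$primary <- res$mismatches == 0L
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# splice a gene's exons into its (plus-sense) transcript sequence
.spliced_transcript <- function(genome, exons) {
  contig <- as.character(GenomicRanges::seqnames(exons)[1])
  segs <- lapply(seq_along(exons), function(i) {
    Biostrings::subseq(genome[[contig]], GenomicRanges::start(exons)[i],
                       GenomicRanges::end(exons)[i])
  })
  tx <- Biostrings::DNAString(paste(vapply(segs, as.character, character(1)),
                                    collapse = ""))
  if (as.character(GenomicRanges::strand(exons)[1]) == "-") {
    tx <- Biostrings::reverseComplement(tx)
  }
  tx
}

.matches_in_seq <- function(primer, seqs) {
  nrow(find_binding_sites(primer, seqs, max_mismatch = 0L)) > 0
}

#' Validate a candidate pair against one genome
#'
#' Locates mismatch-free binding sites of both primers within the source
#' gene's locus and rejects the pair when (a) either primer has no such
#' site — distinguishing the case where the primer's binding sequence is
#' interrupted by an intron (it matches the spliced transcript but not the
#' genome: an exon/intron-boundary primer) — (b) the amplified target
#' region exceeds the configured maximum, or (c) the sites do not face
#' each other convergently. Accepted pairs are returned with full
#' intron/exon accounting of the target region against the gene model.
#'
#' @param pair One row of a [form_pairs()] result (or any list with
#'   `fwd_seq`, `rev_seq`, `gene`, and optionally `target_cols`).
#' @param genome `DNAStringSet` (or named character vector) of contigs.
#' @param models Named `GRangesList` of exons per gene
#'   (see [read_gene_models()]).
#' @param params A [design_params()].
#' @param tail_len Total length (nt) of 5' tails that will be attached to
#'   the two primers; enters the product length only.
#' @param cache Optional environment reused across calls for one genome:
#'   caches per-gene locus subsequences and per-primer site searches, which
#'   repeat heavily when many candidate pairs share primer sequences.
#' @return List with `accepted` (logical), `reason` (for rejections:
#'   `"exon_intron_boundary"`, `"no_binding_site"`, `"oversize_product"`,
#'   `"divergent_orientation"`), and for accepted pairs an `amplicon`
#'   `data.frame`: contig, product/target coordinates, `target_len`,
#'   `exonic_bp`, `intronic_bp`, `product_len`.
#' @export
validate_pair <- function(pair, genome, models, params = design_params(),
                          tail_len = 0L, cache = NULL) {
  res <- .validate_core(pair$fwd_seq, pair$rev_seq, pair$gene, genome,
                        models, params, tail_len, cache)
  if (res$accepted) {
    res$amplicon <- as.data.frame(res$amplicon, stringsAsFactors = FALSE)
  }
  res
}

.validate_core <- function(fwd_seq, rev_seq, gene, genome, models,
                           params, tail_len = 0L, cache = NULL) {
  if (!inherits(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  if (!gene %in% names(models)) {
    stop("no gene model for gene ", gene)  # error, not a rejection
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lk <- paste0("locus_", gene)
  if (is.null(cache[[lk]])) {
    exons <- models[[gene]]
    locus <- c(min(GenomicRanges::start(exons)), max(GenomicRanges::end(exons)))
    contig <- as.character(GenomicRanges::seqnames(exons)[1])
    cache[[lk]] <- list(
      exons_start = GenomicRanges::start(exons),
      exons_end = GenomicRanges::end(exons),
      contig = contig,
      strand = as.character(GenomicRanges::strand(exons)[1]),
      locus = locus,
      sub = Biostrings::DNAStringSet(stats::setNames(
        as.character(Biostrings::subseq(genome[[contig]], locus[1], locus[2])),
        contig)),
      exons = models[[gene]])
  }
  L <- cache[[lk]]

  site_in_locus <- function(primer, want_strand) {
    key <- paste0("sites_", gene, "_", primer, "_", want_strand)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- find_binding_sites(primer, L$sub, max_mismatch = 0L)
    s <- s[s$strand == want_strand, , drop = FALSE]
    s$start <- s$start + L$locus[1] - 1L
    s$end <- s$end + L$locus[1] - 1L
    cache[[key]] <- s
    s
  }
  # coding-sense forward primer binds the coding strand; the reverse primer
  # (written as reverse complement of coding sense) binds the template strand
  fwd_strand <- L$strand
  rev_strand <- if (L$strand == "+") "-" else "+"
  f_sites <- site_in_locus(fwd_seq, fwd_strand)
  r_sites <- site_in_locus(rev_seq, rev_strand)

  if (!nrow(f_sites) || !nrow(r_sites)) {
    tk <- paste0("tx_", gene)
    if (is.null(cache[[tk]])) {
      cache[[tk]] <- Biostrings::DNAStringSet(stats::setNames(
        as.character(.spliced_transcript(genome, L$exons)), "tx"))
    }
    missing <- c(if (!nrow(f_sites)) fwd_seq, if (!nrow(r_sites)) rev_seq)
    boundary <- any(vapply(missing, .matches_in_seq, logical(1),
                           seqs = cache[[tk]]))
    return(list(accepted = FALSE,
                reason = if (boundary) "exon_intron_boundary" else "no_binding_site"))
  }

  # orientation along the genome: the left site must be the one whose 3' end
  # points rightwards (plus-strand site), the right one minus-strand
  left <- if (L$strand == "+") f_sites else r_sites
  right <- if (L$strand == "+") r_sites else f_sites
  nl <- nrow(left); nr <- nrow(right)
  ii <- rep(seq_len(nl), times = nr)
  jj <- rep(seq_len(nr), each = nl)
  conv <- left$end[ii] < right$start[jj]
  if (!any(conv)) return(list(accepted = FALSE, reason = "divergent_orientation"))
  ii <- ii[conv]; jj <- jj[conv]
  tlen <- right$start[jj] - left$end[ii] - 1L
  # intended product: the candidate's alignment-implied target length, plus
  # any introns, is the shortest convergent product at the locus
  pick <- which.min(tlen)
  li <- ii[pick]; rj <- jj[pick]
  target_len <- tlen[pick]
  if (target_len > params$amplicon_len[2]) {
    return(list(accepted = FALSE, reason = "oversize_product"))
  }
  t_start <- left$end[li] + 1L
  t_end <- right$start[rj] - 1L
  exonic <- sum(pmax(0L, pmin(L$exons_end, t_end) - pmax(L$exons_start, t_start) + 1L))
  amp <- list(
    contig = L$contig, strand = L$strand,
    product_start = left$start[li], product_end = right$end[rj],
    target_start = t_start, target_end = t_end,
    target_len = target_len, exonic_bp = exonic,
    intronic_bp = target_len - exonic,
    product_len = target_len + nchar(fwd_seq) + nchar(rev_seq) +
      as.integer(tail_len))
  list(accepted = TRUE, reason = NA_character_, amplicon = amp)
}

#' Screen a pair for potential secondary amplification products
#'
#' Finds approximate binding sites of both primers (up to
#' `params$max_mismatch` mismatches) across the whole genome and reports
#' every convergent site combination on one contig whose implied product is
#' at most `params$secondary_max_len` and is not the intended product. A
#' combination counts as risky only when both sites have a mismatch-free
#' 3'-terminal stretch of `params$secondary_clean3` nucleotides.
#'
#' @param pair As in [validate_pair()].
#' @param genome `DNAStringSet` or named character vector.
#' @param params A [design_params()].
#' @param intended Optional `data.frame` with `contig`, `product_start`,
#'   `product_end` of the intended product (from [validate_pair()]); any
#'   site pair reproducing those coordinates is not reported.
#' @return `data.frame` of risk entries (contig, coordinates, primers
#'   involved, mismatch counts, product length) with attribute `risky`
#'   (logical); zero rows when the genome offers no secondary product.
#' @export
secondary_product_screen <- function(pair, genome, params = design_params(),
                                     intended = NULL) {
  if (!inherits(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  m3 <- params$secondary_clean3
  clean3 <- function(primer, sites) {
    if (!nrow(sites)) return(logical(0))
    sets <- .iupac_sets[.iupac_chars(primer)]
    n <- length(sets)
    vapply(seq_len(nrow(sites)), function(i) {
      win <- as.character(Biostrings::subseq(genome[[sites$contig[i]]],
                                             sites$start[i], sites$end[i]))
      ch <- strsplit(win, "")[[1]]
      if (sites$strand[i] == "-") {
        ch <- rev(c(A = "T", C = "G", G = "C", T = "A",
                    N = "N")[ch])  # primer-sense letters
      }
      tail_idx <- (n - m3 + 1L):n
      all(mapply(function(s, b) b %in% s, sets[tail_idx], ch[tail_idx]))
    }, logical(1))
  }
  all_sites <- function(primer, which) {
    s <- find_binding_sites(primer, genome, max_mismatch = params$max_mismatch)
    if (nrow(s)) {
      s$primer <- which
      s$clean3 <- clean3(primer, s)
    } else {
      s$primer <- character(0); s$clean3 <- logical(0)
    }
    s
  }
  sites <- rbind(all_sites(pair$fwd_seq, "fwd"), all_sites(pair$rev_seq, "rev"))
  out <- list()
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      if (plus$contig[i] != minus$contig[j]) next
      if (minus$end[j] <= plus$end[i]) next  # must face each other
      prod_len <- minus$end[j] - plus$start[i] + 1L
      if (prod_len > params$secondary_max_len) next
      if (!is.null(intended) &&
          plus$contig[i] == intended$contig &&
          plus$start[i] == intended$product_start &&
          minus$end[j] == intended$product_end) next
      out[[length(out) + 1L]] <- data.frame(
        contig = plus$contig[i],
        start = plus$start[i], end = minus$end[j],
        product_len = prod_len,
        left_primer = plus$primer[i], right_primer = minus$primer[j],
        left_mismatches = plus$mismatches[i],
        right_mismatches = minus$mismatches[j],
        both_clean3 = plus$clean3[i] && minus$clean3[j],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), start = integer(), end = integer(),
               product_len = integer(), left_primer = character(),
               right_primer = character(), left_mismatches = integer(),
               right_mismatches = integer(), both_clean3 = logical(),
               stringsAsFactors = FALSE)
  attr(res, "risky") <- any(res$both_clean3)
  res
}
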