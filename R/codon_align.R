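# Codon-aware back-translation of protein alignments onto coding sequences,
# and the uncorrected p-distance divergence statistic.

#' Codon alignment container
#'
#' A gap-synchronized nucleotide alignment of one ortholog group: every row
#' has equal length divisible by three, every gap run is codon-aligned, and
#' removing the gaps from a row reproduces its source CDS.
#'
#' @param rows Named character vector of aligned nucleotide rows (names are
#'   taxon ids); gaps as `-`.
#' @param cds_ids Optional character vector of source CDS identifiers
#'   (defaults to the taxon ids).
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(rows, cds_ids = names(rows)) {
  stopifnot(is.character(rows), length(rows) >= 1, !is.null(names(rows)))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (w %% 3L != 0L) stop("alignment length not divisible by 3")
  for (i in seq_along(rows)) {
    codons <- substring(rows[i], seq(1, w, 3), seq(3, w, 3))
    partial <- grepl("-", codons) & codons != "---"
    if (any(partial)) {
      stop(sprintf("row %s: gap not codon-aligned at codon %d",
                   names(rows)[i], which(partial)[1]))
    }
  }
  structure(list(taxa = names(rows), rows = rows, cds_ids = cds_ids),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa, %d columns (%d codons)\n",
              length(x$rows), nchar(x$rows[1]), nchar(x$rows[1]) / 3))
  invisible(x)
}

.degap <- function(s) gsub("-", "", s, fixed = TRUE)

.translate_cds <- function(cds, genetic_code) {
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- genetic_code[codons]
  # codons with ambiguity codes (or unknown triplets) translate to X
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Uses the aligned amino acids as a blueprint: every amino-acid column
#' becomes one codon column of the corresponding CDS, and protein gaps
#' become `---`. Each CDS must translate to its ungapped protein row;
#' positions where either side is the wildcard `X` (e.g. selenocysteine
#' sites recoded as `X`, or ambiguous codons) are exempt from the
#' translation check and the codon is retained verbatim. A terminal stop
#' codon on the CDS is trimmed.
#'
#' @param protein_alignment Named character vector of aligned protein rows
#'   (gaps as `-`), or an `AAStringSet`.
#' @param cds_sequences Named character vector of unaligned coding
#'   sequences, or a `DNAStringSet`; names must cover the protein row names.
#' @param genetic_code Named character vector mapping codons to amino
#'   acids; default `Biostrings::GENETIC_CODE` (the standard code).
#' @return A [codon_alignment()].
#' @export
backtranslate <- function(protein_alignment, cds_sequences,
                          genetic_code = Biostrings::GENETIC_CODE) {
  if (methods::is(protein_alignment, "XStringSet")) {
    protein_alignment <- stats::setNames(as.character(protein_alignment),
                                         names(protein_alignment))
  }
  if (methods::is(cds_sequences, "XStringSet")) {
    cds_sequences <- stats::setNames(as.character(cds_sequences),
                                     names(cds_sequences))
  }
  prot <- toupper(protein_alignment)
  cds <- chartr("Uu", "Tt", toupper(cds_sequences))
  missing <- setdiff(names(prot), names(cds))
  if (length(missing)) stop("no CDS for taxa: ", paste(missing, collapse = ", "))
  stops <- names(genetic_code)[genetic_code == "*"]
  out <- character(length(prot))
  for (i in seq_along(prot)) {
    taxon <- names(prot)[i]
    p <- strsplit(prot[i], "")[[1]]
    s <- cds[[taxon]]
    n <- nchar(s)
    if (n %% 3L == 0L && n >= 3L && substr(s, n - 2, n) %in% stops) {
      s <- substr(s, 1, n - 3)  # trim terminal stop
      n <- n - 3L
    }
    aa_len <- sum(p != "-")
    if (n != 3L * aa_len) {
      stop(sprintf("taxon %s: CDS length %d incompatible with %d aligned residues",
                   taxon, n, aa_len))
    }
    codons <- substring(s, seq_len(aa_len) * 3 - 2, seq_len(aa_len) * 3)
    trans <- genetic_code[codons]
    trans[is.na(trans)] <- "X"
    res <- p[p != "-"]
    bad <- which(trans != res & trans != "X" & res != "X")
    if (length(bad)) {
      stop(sprintf(
        "taxon %s: codon %s at residue %d translates to %s, protein row has %s",
        taxon, codons[bad[1]], bad[1], trans[bad[1]], res[bad[1]]))
    }
    row <- character(length(p))
    row[p == "-"] <- "---"
    row[p != "-"] <- codons
    out[i] <- paste0(row, collapse = "")
  }
  names(out) <- names(prot)
  codon_alignment(out)
}

#' Pairwise uncorrected p-distances over aligned rows
#'
#' For every row pair, the fraction of mismatching sites among comparable
#' sites; a site is comparable only when both rows carry a concrete
#' A/C/G/T base (gaps and ambiguity codes are excluded from numerator and
#' denominator). Pairs with zero comparable sites are flagged `NA`, warned
#' about, and excluded from the mean.
#'
#' @param rows Character vector (>= 2) of equal-length aligned rows.
#' @return List: `d` symmetric distance matrix (zero diagonal), `n_sites`
#'   matrix of comparable-site counts, `mean` arithmetic mean over defined
#'   pairs.
#' @export
p_distance_matrix <- function(rows) {
  stopifnot(length(rows) >= 2)
  if (length(unique(nchar(rows))) != 1L) stop("rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  conc <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  k <- length(rows)
  d <- matrix(0, k, k, dimnames = list(names(rows), names(rows)))
  ns <- matrix(0L, k, k, dimnames = dimnames(d))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- conc[i, ] & conc[j, ]
      ns[i, j] <- ns[j, i] <- sum(ok)
      if (!any(ok)) {
        warning(sprintf("no comparable sites between rows %d and %d", i, j))
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
      }
    }
  }
  up <- d[upper.tri(d)]
  list(d = d, n_sites = ns, mean = mean(up[!is.na(up)]))
}
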