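# Post-processing of validated primer pairs: overlap-limited per-gene
# selection, sequencing-tail compatibility and attachment, and annealing
# temperature recommendation.

#' Universal sequencing-tail catalog
#'
#' Loads a catalog of concrete sequencing-primer pairs whose sequences are
#' attached to the 5' ends of PCR primers to provide universal sequencing
#' binding sites. The packaged default catalog holds the four HOG-Seq
#' forward/reverse tail pairs with their approximate melting temperatures.
#'
#' @param path Optional path to a tab-separated catalog (`name`, `forward`,
#'   `tm_forward`, `reverse`, `tm_reverse`); defaults to the packaged file.
#' @return `data.frame`, one row per tail pair.
#' @export
sequencing_tails <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sequencing_tails.tsv", package = "degeprimr")
  }
  tails <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("forward", "reverse")) {
    tails[[col]] <- vapply(tails[[col]], iupac, character(1))
    if (any(vapply(tails[[col]], degeneracy, numeric(1)) != 1)) {
      stop("sequencing tails must be concrete (degeneracy 1)")
    }
  }
  tails
}

#' Attach a 5' sequencing tail to a primer
#'
#' Concatenates a concrete tail onto the primer's 5' end. Degeneracy is
#' unchanged; length grows by the tail length.
#'
#' @param primer IUPAC sequence.
#' @param tail Concrete tail sequence (may be empty).
#' @return Tailed IUPAC sequence.
#' @export
attach_tail <- function(primer, tail) {
  if (nchar(tail) == 0) return(iupac(primer))
  tail <- iupac(tail)
  if (degeneracy(tail) != 1) stop("tail must be concrete (degeneracy 1)")
  paste0(tail, iupac(primer))
}

#' Sequencing-tail compatibility of a primer pair
#'
#' A tail pair is compatible when the two tailed primers (tail + primer,
#' 5'->3') still pass the dimer screen — both homodimers and the
#' heterodimer — at the configured free-energy floor.
#'
#' @param pair List/row with `fwd_seq` and `rev_seq`.
#' @param tails Catalog from [sequencing_tails()].
#' @param model A [thermo_model()].
#' @param threshold Free-energy floor (kcal/mol), default -11.0.
#' @param enum_cap Expansion cap forwarded to [dimer_screen()].
#' @return Character vector of compatible tail names (possibly empty).
#' @export
tail_compatibility <- function(pair, tails = sequencing_tails(),
                               model = thermo_model(), threshold = -11.0,
                               enum_cap = 64) {
  ok <- vapply(seq_len(nrow(tails)), function(i) {
    tf <- attach_tail(pair$fwd_seq, tails$forward[i])
    tr <- attach_tail(pair$rev_seq, tails$reverse[i])
    dimer_screen(tf, tr, threshold = threshold, model = model,
                 enum_cap = enum_cap)$pass
  }, logical(1))
  tails$name[ok]
}

#' Recommended annealing temperature for a pair
#'
#' The lower of the two primers' minimum melting temperatures minus a fixed
#' offset, so that the weakest expansion of either primer still anneals.
#'
#' @param pair List/row with `fwd_tm_min` and `rev_tm_min`.
#' @param offset Offset in C (default 3).
#' @return Temperature in C.
#' @export
recommend_annealing <- function(pair, offset = 3) {
  min(pair$fwd_tm_min, pair$rev_tm_min) - offset
}

#' Export tailed primer pairs as FASTA
#'
#' Writes two records per marker (`<pair_id>_F`, `<pair_id>_R`) with the
#' tailed IUPAC sequences.
#'
#' @param markers Marker table from [run_design()] (needs `pair_id`,
#'   `fwd_tailed`, `rev_tailed`).
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
export_primers_fasta <- function(markers, path) {
  seqs <- c(rbind(markers$fwd_tailed, markers$rev_tailed))
  names(seqs) <- c(rbind(paste0(markers$pair_id, "_F"),
                         paste0(markers$pair_id, "_R")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# fraction of the shorter region covered by the overlap of two intervals
.overlap_frac <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  ov / min(e1 - s1 + 1, e2 - s2 + 1)
}

#' Overlap-limited per-gene pair selection
#'
#' Greedy selection of validated pairs of one gene in rank order (ascending
#' total degeneracy, ties broken by descending intronic bp, then by target
#' position), accepting a pair only while its target region overlaps every
#' already-selected target by at most `max_overlap` of the shorter region.
#'
#' @param pairs `data.frame` of validated pairs of one gene with
#'   `total_degeneracy`, `target_start`, `target_end` and (optionally)
#'   `intronic_bp` columns.
#' @param max_overlap Maximum pairwise overlap fraction (default 0.5).
#' @return The selected subset, in rank order.
#' @export
select_per_gene <- function(pairs, max_overlap = 0.5) {
  if (!nrow(pairs)) return(pairs)
  intronic <- if ("intronic_bp" %in% names(pairs)) pairs$intronic_bp else
    rep(0, nrow(pairs))
  ord <- order(pairs$total_degeneracy, -intronic, pairs$target_start)
  sel <- integer(0)
  for (i in ord) {
    ok <- all(vapply(sel, function(j) {
      .overlap_frac(pairs$target_start[i], pairs$target_end[i],
                    pairs$target_start[j], pairs$target_end[j]) <= max_overlap
    }, logical(1)))
    if (ok) sel <- c(sel, i)
  }
  pairs[sel, , drop = FALSE]
}
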