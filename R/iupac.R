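# IUPAC degenerate-nucleotide algebra: code sets, expansion, degeneracy,
# consensus-related bounds (GC, mononucleotide runs) and 3'-end rules.

# Base sets per IUPAC code, taken from Biostrings; gaps and extended symbols
# are not part of the primer alphabet.
.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

.iupac_card <- vapply(.iupac_sets, length, integer(1))

#' Normalise and validate an IUPAC nucleotide sequence
#'
#' Input is upper-cased and RNA-style `U` is normalised to `T`. Any symbol
#' outside the 15-letter IUPAC nucleotide alphabet (including gaps) is an
#' error that names the first offending position.
#'
#' @param seq Character scalar, primer sequence written 5' to 3'.
#' @return Upper-cased character scalar over `A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`.
#' @examples
#' iupac("gcyatyttcgayttygayag")
#' @export
iupac <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  if (nchar(s) < 1L) stop("IUPAC sequence must have length >= 1")
  ch <- strsplit(s, "")[[1]]
  bad <- which(!ch %in% names(.iupac_sets))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC symbol '%s' at position %d", ch[bad[1]], bad[1]))
  }
  s
}

.iupac_chars <- function(seq) strsplit(iupac(seq), "")[[1]]

#' Degeneracy of a degenerate oligonucleotide
#'
#' The degree of degeneration *d*: the number of distinct concrete A/C/G/T
#' sequences the oligo represents, i.e. the product over positions of the
#' cardinality of each IUPAC code (A/C/G/T count 1; R/Y/S/W/K/M count 2;
#' B/D/H/V count 3; N counts 4).
#'
#' @param seq IUPAC sequence (character scalar).
#' @return Numeric scalar (exact integer value; may exceed `.Machine$integer.max`).
#' @examples
#' degeneracy("GCYATYTTCGAYTTYGAYAG")  # 32
#' @export
degeneracy <- function(seq) {
  prod(.iupac_card[.iupac_chars(seq)])
}

#' Total degeneracy of a primer pair
#'
#' Product of the forward and reverse primer degeneracies (the "Total d" of
#' a pair of degenerate primers).
#'
#' @param fwd,rev IUPAC sequences.
#' @return Numeric scalar.
#' @export
pair_degeneracy <- function(fwd, rev) degeneracy(fwd) * degeneracy(rev)

#' Enumerate all concrete expansions of a degenerate oligo
#'
#' @param seq IUPAC sequence.
#' @param cap Refuse enumeration when the degeneracy exceeds this cap; callers
#'   that only need bounds should use the non-enumerating functions.
#' @return Character vector of all concrete A/C/G/T sequences consistent with
#'   the codes; its length equals `degeneracy(seq)`.
#' @export
expand_iupac <- function(seq, cap = 4096) {
  d <- degeneracy(seq)
  if (d > cap) {
    stop(sprintf("degeneracy %s exceeds enumeration cap %s", format(d), format(cap)))
  }
  sets <- .iupac_sets[.iupac_chars(seq)]
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}

#' GC-content range over all expansions
#'
#' Per-position bounds: a position adds 1 to the minimum GC count iff its
#' code is a subset of \{G,C\} (G, C or S) and adds 1 to the maximum iff the
#' code contains G or C at all. Equivalent to the min/max GC fraction over
#' the full expansion set, expressed as percent of primer length.
#'
#' @param seq IUPAC sequence.
#' @return Numeric vector `c(min, max)` in percent.
#' @export
gc_range <- function(seq) {
  ch <- .iupac_chars(seq)
  sets <- .iupac_sets[ch]
  lo <- vapply(sets, function(s) all(s %in% c("G", "C")), logical(1))
  hi <- vapply(sets, function(s) any(s %in% c("G", "C")), logical(1))
  c(min = 100 * sum(lo) / length(ch), max = 100 * sum(hi) / length(ch))
}

#' Worst-case mononucleotide run length
#'
#' The maximum, over all concrete expansions, of the longest single-nucleotide
#' repeat. Computed without enumeration: for each base b, the longest stretch
#' of consecutive codes whose sets all contain b.
#'
#' @param seq IUPAC sequence.
#' @return Integer scalar >= 1.
#' @export
max_run <- function(seq) {
  ch <- .iupac_chars(seq)
  sets <- .iupac_sets[ch]
  best <- 1L
  for (b in c("A", "C", "G", "T")) {
    has <- vapply(sets, function(s) b %in% s, logical(1))
    r <- rle(has)
    if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
  }
  as.integer(best)
}

#' Reverse complement of a degenerate oligo
#'
#' Maps each code to its complement (R-Y, K-M, B-V, D-H; S, W and N are
#' self-complementary) and reverses; degeneracy is preserved.
#'
#' @param seq IUPAC sequence.
#' @return IUPAC sequence, character scalar.
#' @export
revcomp_iupac <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(iupac(seq))))
}

#' 3'-terminal window rules for a degenerate primer
#'
#' Evaluates the stricter constraints applied to the 3'-terminal window of a
#' primer (default: last six nucleotides): window degeneracy, GC-content
#' range, and worst-case mononucleotide run. The GC rule requires the whole
#' range over expansions to lie inside the configured window (`gc_mode =
#' "contain"`), so that every synthesised expansion satisfies it; `"overlap"`
#' semantics are available.
#'
#' @param seq IUPAC sequence written 5' to 3'; the window is taken from its
#'   3' (right) end.
#' @param window Window length (default 6).
#' @param max_degeneracy Maximum window degeneracy (default 4).
#' @param gc Length-2 numeric, allowed GC percent window (default `c(20, 80)`).
#' @param run_max Maximum mononucleotide run in the window (default 3).
#' @param gc_mode `"contain"` (default) or `"overlap"`.
#' @return List with logical `pass`, per-rule logical verdicts, and the
#'   window sequence.
#' @export
three_prime_checks <- function(seq, window = 6L, max_degeneracy = 4,
                               gc = c(20, 80), run_max = 3L,
                               gc_mode = c("contain", "overlap")) {
  gc_mode <- match.arg(gc_mode)
  s <- iupac(seq)
  n <- nchar(s)
  if (window > n) stop("3' window longer than primer")
  w <- substr(s, n - window + 1L, n)
  d_ok <- degeneracy(w) <= max_degeneracy
  gr <- gc_range(w)
  gc_ok <- if (gc_mode == "contain") {
    gr[1] >= gc[1] && gr[2] <= gc[2]
  } else {
    gr[2] >= gc[1] && gr[1] <= gc[2]
  }
  run_ok <- max_run(w) <= run_max
  list(pass = d_ok && gc_ok && run_ok,
       degeneracy_ok = d_ok, gc_ok = unname(gc_ok), run_ok = run_ok,
       window_seq = w)
}
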