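# Nearest-neighbor duplex thermodynamics: melting-temperature ranges for
# degenerate primers and hybridization free-energy screening of dimers.

.R_GAS <- 1.987  # cal/(mol*K)

#' Nearest-neighbor thermodynamic model
#'
#' Loads the unified DNA/DNA nearest-neighbor parameter set (dinucleotide
#' dH/dS plus terminal initiation terms) and binds it to the solution
#' conditions used throughout primer evaluation.
#'
#' @param salt_mM Monovalent-cation concentration in mM (Na+ equivalent);
#'   default 50.
#' @param oligo_uM Concentration of each oligonucleotide in uM; default 0.8,
#'   matching a standard degenerate-primer PCR recipe.
#' @param nn_file Path to a tab-separated parameter table (`step`, `dH`,
#'   `dS`); defaults to the unified parameter file shipped with the package.
#' @return An object of class `thermo_model`: named `dH`/`dS`/`dG37` vectors
#'   over the 16 dinucleotide steps, initiation terms, and concentrations.
#' @export
thermo_model <- function(salt_mM = 50, oligo_uM = 0.8, nn_file = NULL) {
  stopifnot(salt_mM > 0, oligo_uM > 0)
  if (is.null(nn_file)) {
    nn_file <- system.file("extdata", "nn_unified_v1.tsv", package = "degeprimr")
  }
  tab <- utils::read.table(nn_file, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  steps <- tab[!grepl("^init", tab$step), ]
  init <- tab[grepl("^init", tab$step), ]
  dH <- stats::setNames(steps$dH, steps$step)
  dS <- stats::setNames(steps$dS, steps$step)
  need <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  if (!all(need %in% names(dH))) stop("nearest-neighbor table is missing steps")
  # complementary-step symmetry: 5'XY3' and its reverse complement describe
  # the same stack and must carry identical parameters
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (s in need) {
    if (abs(dH[s] - dH[rc(s)]) > 1e-9 || abs(dS[s] - dS[rc(s)]) > 1e-9) {
      stop(sprintf("complementary-step symmetry violated at %s/%s", s, rc(s)))
    }
  }
  dG37 <- dH - 310.15 * dS / 1000
  structure(list(
    dH = dH, dS = dS, dG37 = dG37,
    dH16 = unname(dH[.step_order]), dS16 = unname(dS[.step_order]),
    dG37n = unname(dG37[.step_order]),
    init = list(AT = c(dH = init$dH[init$step == "init_AT"],
                       dS = init$dS[init$step == "init_AT"]),
                GC = c(dH = init$dH[init$step == "init_GC"],
                       dS = init$dS[init$step == "init_GC"])),
    salt_M = salt_mM / 1000, oligo_M = oligo_uM * 1e-6
  ), class = "thermo_model")
}

.concrete_chars <- function(seq) {
  ch <- .iupac_chars(seq)
  if (any(!ch %in% c("A", "C", "G", "T"))) {
    stop("sequence contains degenerate symbols; use tm_range()/expansions")
  }
  ch
}

# integer encoding A=1 C=2 G=3 T=4; complement is 5 - code
.base_int <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.int_seq <- function(seq) {
  v <- .base_int[strsplit(toupper(seq), "")[[1]]]
  if (anyNA(v)) stop("sequence contains degenerate symbols; use tm_range()/expansions")
  v
}
# step names in the order indexed by 4 * (x - 1) + y for codes (x, y)
.step_order <- as.vector(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0)))

#' Nearest-neighbor melting temperature of a concrete oligo
#'
#' Two-state nearest-neighbor Tm with entropic monovalent-salt correction
#' (`dS + 0.368 (N-1) ln[Na+]`) at the model's primer concentration
#' (`CT/4` term for non-self-complementary duplexes):
#' `Tm = 1000 dH / (dS' + R ln(CT/4)) - 273.15`.
#'
#' @param seq Concrete A/C/G/T sequence, length >= 8.
#' @param model A [thermo_model()].
#' @return Temperature in degrees Celsius.
#' @export
tm_concrete <- function(seq, model = thermo_model()) {
  v <- .int_seq(seq)
  n <- length(v)
  if (n < 8) stop("Tm estimation requires length >= 8")
  idx <- 4L * (v[-n] - 1L) + v[-1L]
  dH <- sum(model$dH16[idx])
  dS <- sum(model$dS16[idx])
  for (term in v[c(1, n)]) {
    key <- if (term %in% c(2L, 3L)) "GC" else "AT"
    dH <- dH + model$init[[key]]["dH"]
    dS <- dS + model$init[[key]]["dS"]
  }
  dS <- dS + 0.368 * (n - 1) * log(model$salt_M)
  ct <- 2 * model$oligo_M
  unname(1000 * dH / (dS + .R_GAS * log(ct / 4)) - 273.15)
}

# representative expansion following a base-preference order per position
.pref_expansion <- function(seq, pref) {
  sets <- .iupac_sets[.iupac_chars(seq)]
  paste0(vapply(sets, function(s) pref[pref %in% s][1], character(1)),
         collapse = "")
}

#' Melting-temperature range of a degenerate primer
#'
#' Minimum and maximum [tm_concrete()] over the expansion set. Exact by
#' enumeration when the degeneracy is at most `enum_cap`; above the cap the
#' range is estimated from AT-biased and GC-biased representative expansions
#' (a documented heuristic that brackets the true extremes closely, since
#' stacking extremes are dominated by base composition).
#'
#' @param seq IUPAC sequence.
#' @param model A [thermo_model()].
#' @param enum_cap Maximum degeneracy for exact enumeration (default 256).
#' @return Numeric `c(min, max)` in degrees Celsius; `min <= max`.
#' @export
tm_range <- function(seq, model = thermo_model(), enum_cap = 256) {
  d <- degeneracy(seq)
  if (d <= enum_cap) {
    tms <- vapply(expand_iupac(seq, cap = enum_cap), tm_concrete,
                  numeric(1), model = model)
    return(c(min = min(tms), max = max(tms)))
  }
  lo <- min(vapply(list(c("A", "T", "G", "C"), c("T", "A", "C", "G")),
                   function(p) tm_concrete(.pref_expansion(seq, p), model),
                   numeric(1)))
  hi <- max(vapply(list(c("G", "C", "A", "T"), c("C", "G", "T", "A")),
                   function(p) tm_concrete(.pref_expansion(seq, p), model),
                   numeric(1)))
  c(min = lo, max = hi)
}

#' Minimum duplex free energy of two concrete oligos
#'
#' Scans all ungapped antiparallel offsets of `a` against `b` (both written
#' 5' to 3') and sums nearest-neighbor stacking free energies (dG at 37 C)
#' over steps whose both positions are Watson-Crick paired. No bulges,
#' internal-loop or dangling-end terms are modelled; initiation is omitted,
#' so the value is a stacking-only screen. Returns the most negative offset
#' total, or 0 when no favorable duplex exists.
#'
#' @param a,b Concrete A/C/G/T sequences.
#' @param model A [thermo_model()].
#' @return Free energy in kcal/mol (<= 0).
#' @export
duplex_dG <- function(a, b, model = thermo_model()) {
  av <- .int_seq(a)
  bv <- rev(.int_seq(b))  # 3'->5' under a (antiparallel)
  na <- length(av); nb <- length(bv)
  # P[i, j]: a[i] Watson-Crick paired with (reversed) b[j]
  P <- outer(av, bv, function(x, y) x + y == 5L)
  if (na < 2L || nb < 2L || !any(P)) return(0)
  # a step at a-position i is stacked on the diagonal when both (i, j) and
  # (i + 1, j + 1) pair; each diagonal j - i is one ungapped offset
  Q <- P[-na, -nb, drop = FALSE] & P[-1L, -1L, drop = FALSE]
  if (!any(Q)) return(0)
  g_step <- model$dG37n[4L * (av[-na] - 1L) + av[-1L]]
  hit <- which(Q, arr.ind = TRUE)
  totals <- rowsum(g_step[hit[, 1L]], hit[, 2L] - hit[, 1L])
  min(0, min(totals))
}

# min-GC / max-GC representative expansions used when enumeration is too big
.gc_extreme_reps <- function(seq) {
  unique(c(.pref_expansion(seq, c("A", "T", "G", "C")),
           .pref_expansion(seq, c("G", "C", "A", "T"))))
}

.screen_reps <- function(seq, n_cap) {
  d <- degeneracy(seq)
  if (d <= n_cap) expand_iupac(seq, cap = n_cap) else .gc_extreme_reps(seq)
}

# worst (most negative) duplex dG over two expansion-representative sets
.worst_duplex <- function(xs, ys, model) {
  worst <- 0
  for (x in xs) for (y in ys) {
    g <- duplex_dG(x, y, model)
    if (g < worst) worst <- g
  }
  worst
}

#' Primer-dimer screen for a degenerate primer pair
#'
#' Fails when any evaluated expansion combination yields a homodimer (within
#' the forward pool, within the reverse pool) or heterodimer free energy
#' below `threshold`. Expansions are enumerated exhaustively while the
#' number of combinations per duplex class stays at or below `enum_cap`;
#' beyond that, GC-extreme representative expansions stand in.
#'
#' @param fwd,rev IUPAC sequences (pass the same sequence twice to screen a
#'   single primer's homodimer only).
#' @param threshold Free-energy floor in kcal/mol (default -11.0).
#' @param model A [thermo_model()].
#' @param enum_cap Maximum expansion combinations evaluated per duplex class.
#' @return List: logical `pass`, worst `dG` observed, and the duplex class
#'   (`homo_fwd`, `homo_rev`, `hetero`) attaining it.
#' @export
dimer_screen <- function(fwd, rev, threshold = -11.0, model = thermo_model(),
                         enum_cap = 64) {
  per_side <- max(1L, floor(sqrt(enum_cap)))
  ef <- .screen_reps(iupac(fwd), per_side)
  er <- .screen_reps(iupac(rev), per_side)
  g <- c(homo_fwd = .worst_duplex(ef, ef, model),
         homo_rev = .worst_duplex(er, er, model),
         hetero = .worst_duplex(ef, er, model))
  worst <- which.min(g)
  list(pass = g[[worst]] >= threshold, dG = g[[worst]],
       class = names(g)[worst])
}
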