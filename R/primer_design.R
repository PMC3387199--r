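# Conserved-window scanning of codon alignments, minimal IUPAC consensus
# construction, the full primer filter battery, and candidate pairing.

#' Primer design parameters
#'
#' Bundles every tunable constraint of the design pipeline. The defaults are
#' the standard parameter set for cross-species degenerate primer design:
#' amplified target 300-1000 bp, primer length 20-25 nt, per-primer
#' degeneracy at most 256, GC content 20-80%, mononucleotide runs at most
#' 4 bp, melting temperature 45-66 C with at most 10 C difference within a
#' pair, dimer free-energy floor -11.0 kcal/mol, and a stricter 3'-terminal
#' hexamer rule set (degeneracy <= 4, GC 20-80%, runs <= 3).
#'
#' @param amplicon_len Length-2 numeric, allowed target-region length (bp).
#' @param primer_len Length-2 integer, allowed primer length (nt).
#' @param max_degeneracy Per-primer degeneracy cap.
#' @param gc Length-2 numeric, GC percent window.
#' @param run_max Maximum mononucleotide run (bp).
#' @param tm Length-2 numeric, melting-temperature window (C).
#' @param max_dTm Maximum Tm difference within a pair (C).
#' @param dimer_threshold Dimer free-energy floor (kcal/mol).
#' @param three_prime List of 3'-window rules: `window`, `max_degeneracy`,
#'   `gc`, `run_max`.
#' @param gc_mode GC filter semantics for degenerate primers: `"contain"`
#'   requires the whole GC range over expansions inside the window.
#' @param tm_mode Tm filter semantics: `"contain"` requires
#'   `[Tm_min, Tm_max]` inside the window.
#' @param max_mismatch Mismatch tolerance for approximate genome matches
#'   (secondary-product screening).
#' @param secondary_max_len Maximum length (bp) of a genomic site pair
#'   considered a plausible secondary product.
#' @param secondary_clean3 Length (nt) of the mismatch-free 3'-terminal
#'   stretch required for a site to count as secondary-product-competent.
#' @param annealing_offset Offset (C) subtracted from the pair's lowest
#'   Tm_min when recommending an annealing temperature.
#' @param enum_cap Expansion-enumeration cap used by Tm and dimer screens.
#' @return Object of class `design_params`.
#' @export
design_params <- function(amplicon_len = c(300, 1000),
                          primer_len = c(20L, 25L),
                          max_degeneracy = 256,
                          gc = c(20, 80),
                          run_max = 4L,
                          tm = c(45, 66),
                          max_dTm = 10,
                          dimer_threshold = -11.0,
                          three_prime = list(window = 6L, max_degeneracy = 4,
                                             gc = c(20, 80), run_max = 3L),
                          gc_mode = "contain",
                          tm_mode = "contain",
                          max_mismatch = 2L,
                          secondary_max_len = 3000L,
                          secondary_clean3 = 6L,
                          annealing_offset = 3,
                          enum_cap = 64) {
  p <- list(amplicon_len = as.numeric(amplicon_len),
            primer_len = as.integer(primer_len),
            max_degeneracy = max_degeneracy, gc = as.numeric(gc),
            run_max = as.integer(run_max), tm = as.numeric(tm),
            max_dTm = max_dTm, dimer_threshold = dimer_threshold,
            three_prime = three_prime, gc_mode = gc_mode, tm_mode = tm_mode,
            max_mismatch = as.integer(max_mismatch),
            secondary_max_len = as.integer(secondary_max_len),
            secondary_clean3 = as.integer(secondary_clean3),
            annealing_offset = annealing_offset, enum_cap = enum_cap)
  for (nm in c("amplicon_len", "primer_len", "gc", "tm")) {
    if (length(p[[nm]]) != 2L || p[[nm]][1] > p[[nm]][2]) {
      stop(nm, " must be c(min, max) with min <= max")
    }
  }
  structure(p, class = "design_params")
}

#' Read design parameters from a YAML config file
#'
#' Keys mirror the arguments of [design_params()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A [design_params()] object.
#' @export
design_params_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(design_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown design parameter keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$three_prime)) {
    tp <- formals(design_params)$three_prime
    tp <- eval(tp)
    tp[names(cfg$three_prime)] <- cfg$three_prime
    cfg$three_prime <- tp
  }
  do.call(design_params, cfg)
}

# bit encoding of base sets: A=1, C=2, G=4, T=8
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.mask_code <- local({
  codes <- names(.iupac_sets)
  m <- integer(15)
  v <- character(15)
  for (cd in codes) {
    bits <- sum(.base_bits[.iupac_sets[[cd]]])
    v[bits] <- cd
  }
  v
})

#' Minimal IUPAC consensus of aligned window rows
#'
#' Per column, the smallest IUPAC code containing the union of the observed
#' bases. A gap or any ambiguity code (including N) in any row disqualifies
#' the column, and with it the whole window: the consensus would no longer
#' guarantee that every row is one of its expansions.
#'
#' @param rows Character vector of equal-length aligned window rows.
#' @return The consensus as a character scalar, or `NA_character_` when a
#'   column is rejected.
#' @export
column_consensus <- function(rows) {
  stopifnot(length(rows) >= 1)
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  codes <- apply(mat, 2, function(col) {
    if (any(!col %in% names(.base_bits))) return(NA_character_)
    .mask_code[Reduce(bitwOr, .base_bits[col])]
  })
  if (anyNA(codes)) NA_character_ else paste0(codes, collapse = "")
}

# per-column union codes for a whole alignment; NA where a column holds a
# gap or ambiguity in any row
.column_codes <- function(rows) {
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  bits <- matrix(.base_bits[mat], nrow = nrow(mat))
  masks <- apply(bits, 2, function(b) if (anyNA(b)) NA_integer_ else Reduce(bitwOr, b))
  ifelse(is.na(masks), NA_character_, .mask_code[pmax(masks, 1L)])
}

# pure per-window predicate battery; returns list of verdicts
.site_filters <- function(cons, orientation, params, model,
                          force_tm = FALSE) {
  d <- degeneracy(cons)
  gr <- gc_range(cons)
  run <- max_run(cons)
  seq5to3 <- if (orientation == "fwd") cons else revcomp_iupac(cons)
  tp <- params$three_prime
  d_ok <- d <= params$max_degeneracy
  gc_ok <- if (params$gc_mode == "contain") {
    gr[1] >= params$gc[1] && gr[2] <= params$gc[2]
  } else gr[2] >= params$gc[1] && gr[1] <= params$gc[2]
  run_ok <- run <= params$run_max
  t3 <- three_prime_checks(seq5to3, window = tp$window,
                           max_degeneracy = tp$max_degeneracy, gc = tp$gc,
                           run_max = tp$run_max, gc_mode = params$gc_mode)
  tm_ok <- NA
  tmr <- c(NA_real_, NA_real_)
  if (force_tm || (d_ok && gc_ok && run_ok && t3$pass)) {
    tmr <- tm_range(seq5to3, model, enum_cap = max(params$enum_cap, 256))
    tm_ok <- if (params$tm_mode == "contain") {
      tmr[1] >= params$tm[1] && tmr[2] <= params$tm[2]
    } else tmr[2] >= params$tm[1] && tmr[1] <= params$tm[2]
  }
  list(seq = seq5to3, degeneracy = d, gc_min = unname(gr[1]),
       gc_max = unname(gr[2]), run = run, d_ok = d_ok,
       gc_ok = unname(gc_ok), run_ok = run_ok, three_prime_ok = t3$pass,
       tm_min = unname(tmr[1]), tm_max = unname(tmr[2]), tm_ok = unname(tm_ok),
       pass = isTRUE(d_ok && gc_ok && run_ok && t3$pass && tm_ok))
}

#' Scan one gene alignment for candidate primer sites
#'
#' Slides windows of every length within `params$primer_len` (step 1 nt,
#' not codon-constrained) over the alignment, builds the minimal IUPAC
#' consensus of each window, and applies the filter battery: degeneracy
#' cap, GC window, mononucleotide-run cap, 3'-terminal rules (on the end
#' appropriate to each orientation) and the melting-temperature window.
#' Each surviving window is emitted in both orientations: as a forward
#' primer (consensus as written, plus strand of the coding sequence) and as
#' a reverse primer (reverse complement).
#'
#' @param aln A [codon_alignment()] (>= 2 rows).
#' @param params A [design_params()].
#' @param model A [thermo_model()].
#' @param gene Gene identifier attached to the output (default taken from
#'   `aln$gene` when present).
#' @param keep_rejected When `TRUE`, every window with a coverable consensus
#'   is emitted together with per-filter verdict columns (`d_ok`, `gc_ok`,
#'   `run_ok`, `three_prime_ok`, `tm_ok`, `pass`) — a diagnostics dump;
#'   default emits passing sites only.
#' @return `data.frame` of candidate sites ordered by start, then window
#'   length, then orientation (`fwd` before `rev`): columns `gene`,
#'   `start`, `end` (1-based inclusive alignment columns), `width`,
#'   `orientation`, `seq` (5'->3'), `degeneracy`, `gc_min`, `gc_max`,
#'   `run`, `tm_min`, `tm_max`.
#' @export
scan_gene <- function(aln, params = design_params(), model = thermo_model(),
                      gene = NULL, keep_rejected = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$rows) < 2) stop("scan_gene needs >= 2 aligned rows")
  if (is.null(gene)) gene <- if (!is.null(aln$gene)) aln$gene else "gene"
  L <- nchar(aln$rows[1])
  empty <- data.frame(gene = character(), start = integer(), end = integer(),
                      width = integer(), orientation = character(),
                      seq = character(), degeneracy = numeric(),
                      gc_min = numeric(), gc_max = numeric(), run = integer(),
                      tm_min = numeric(), tm_max = numeric(),
                      stringsAsFactors = FALSE)
  if (L < params$primer_len[1]) {
    warning("alignment shorter than minimum primer length")
    return(empty)
  }
  codes <- .column_codes(aln$rows)
  log2d <- log2(.iupac_card[codes])
  log2d[is.na(codes)] <- 1e6  # finite penalty so windowed sums stay comparable
  cum <- cumsum(c(0, log2d))
  cap_log <- log2(params$max_degeneracy)
  out <- vector("list", 64)
  n_out <- 0
  huge <- 5e5  # marks a window crossing a rejected (gap/ambiguity) column
  for (p in seq_len(L - params$primer_len[1] + 1L)) {
    for (w in params$primer_len[1]:params$primer_len[2]) {
      q <- p + w - 1L
      if (q > L) break
      span_log <- cum[q + 1L] - cum[p]
      if (span_log > huge) next  # no coverable consensus exists
      if (!keep_rejected && span_log > cap_log) next
      cons <- paste0(codes[p:q], collapse = "")
      for (ori in c("fwd", "rev")) {
        f <- .site_filters(cons, ori, params, model,
                           force_tm = keep_rejected)
        if (!keep_rejected && !f$pass) next
        n_out <- n_out + 1
        if (n_out > length(out)) out <- c(out, vector("list", length(out)))
        row <- data.frame(
          gene = gene, start = p, end = q, width = w, orientation = ori,
          seq = f$seq, degeneracy = f$degeneracy, gc_min = f$gc_min,
          gc_max = f$gc_max, run = f$run, tm_min = f$tm_min,
          tm_max = f$tm_max, stringsAsFactors = FALSE)
        if (keep_rejected) {
          row$d_ok <- f$d_ok; row$gc_ok <- f$gc_ok; row$run_ok <- f$run_ok
          row$three_prime_ok <- f$three_prime_ok
          row$tm_ok <- f$tm_ok; row$pass <- f$pass
        }
        out[[n_out]] <- row
      }
    }
  }
  if (n_out == 0) return(empty)
  res <- do.call(rbind, out[seq_len(n_out)])
  res[order(res$start, res$width, res$orientation), , drop = FALSE]
}

#' Form candidate primer pairs from scanned sites
#'
#' Combines forward sites with downstream reverse sites of one gene. A pair
#' is emitted when the alignment-implied target region (the columns strictly
#' between the two binding windows) lies within the amplicon-length bounds,
#' the primers' Tm midpoints differ by at most `max_dTm`, and the pair
#' passes the dimer screen (both homodimers and the heterodimer). The
#' alignment-level length check is provisional; the authoritative per-genome
#' product length is established by [validate_pair()].
#'
#' @param sites `data.frame` from [scan_gene()] for a single gene.
#' @param params A [design_params()].
#' @param model A [thermo_model()].
#' @return `data.frame`, one row per pair: primer sequences, coordinates,
#'   per-primer degeneracies, `total_degeneracy`, Tm summaries, target
#'   coordinates/length at alignment scale, and `dimer_dG`.
#' @export
form_pairs <- function(sites, params = design_params(), model = thermo_model()) {
  fwd <- sites[sites$orientation == "fwd", , drop = FALSE]
  rvs <- sites[sites$orientation == "rev", , drop = FALSE]
  out <- list()
  per_side <- max(1L, floor(sqrt(params$enum_cap)))
  reps_cache <- new.env(parent = emptyenv())
  reps_of <- function(s) {
    if (is.null(reps_cache[[s]])) reps_cache[[s]] <- .screen_reps(s, per_side)
    reps_cache[[s]]
  }
  homo_cache <- new.env(parent = emptyenv())
  homo_of <- function(s) {
    if (is.null(homo_cache[[s]])) {
      homo_cache[[s]] <- .worst_duplex(reps_of(s), reps_of(s), model)
    }
    homo_cache[[s]]
  }
  for (i in seq_len(nrow(fwd))) {
    f <- fwd[i, ]
    for (j in seq_len(nrow(rvs))) {
      r <- rvs[j, ]
      if (r$start <= f$end) next  # reverse window must lie downstream
      target <- r$start - f$end - 1L
      if (target < params$amplicon_len[1] || target > params$amplicon_len[2]) next
      mid_f <- (f$tm_min + f$tm_max) / 2
      mid_r <- (r$tm_min + r$tm_max) / 2
      if (abs(mid_f - mid_r) > params$max_dTm) next
      worst <- min(homo_of(f$seq), homo_of(r$seq),
                   .worst_duplex(reps_of(f$seq), reps_of(r$seq), model))
      if (worst < params$dimer_threshold) next
      out[[length(out) + 1L]] <- data.frame(
        gene = f$gene, fwd_seq = f$seq, rev_seq = r$seq,
        fwd_start = f$start, fwd_end = f$end,
        rev_start = r$start, rev_end = r$end,
        fwd_degeneracy = f$degeneracy, rev_degeneracy = r$degeneracy,
        total_degeneracy = f$degeneracy * r$degeneracy,
        fwd_tm_min = f$tm_min, fwd_tm_max = f$tm_max,
        rev_tm_min = r$tm_min, rev_tm_max = r$tm_max,
        target_start = f$end + 1L, target_end = r$start - 1L,
        target_cols = target, dimer_dG = worst,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), fwd_seq = character(),
                      rev_seq = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$fwd_start, res$rev_start), , drop = FALSE]
}
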