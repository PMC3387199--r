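# Independent brute-force oracles, deliberately implemented differently from
# the package code paths they cross-check.

IUPAC_SETS <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])

# recursive enumeration of all concrete expansions
oracle_expand <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- ""
  for (c0 in ch) {
    out <- as.vector(vapply(IUPAC_SETS[[c0]],
                            function(b) paste0(out, b), character(length(out))))
  }
  out
}

oracle_gc_minmax <- function(seq) {
  gc <- vapply(oracle_expand(seq), function(s) {
    ch <- strsplit(s, "")[[1]]
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1))
  c(min(gc), max(gc))
}

oracle_max_run <- function(seq) {
  max(vapply(oracle_expand(seq), function(s) {
    r <- rle(strsplit(s, "")[[1]])
    max(r$lengths)
  }, numeric(1)))
}

# naive offset-scan duplex energy: antiparallel ungapped alignment of a
# against reversed b, summing 37C stacking terms over WC-paired steps
oracle_duplex <- function(a, b, model) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  na <- length(av); nb <- length(bv)
  best <- 0
  for (k in (-(nb - 1)):(na - 1)) {
    i1 <- max(1, k + 1); i2 <- min(na, k + nb)
    if (i2 - i1 < 1) next
    tot <- 0
    for (i in i1:(i2 - 1)) {
      p1 <- bv[i - k] == comp[[av[i]]]
      p2 <- bv[i + 1 - k] == comp[[av[i + 1]]]
      if (p1 && p2) tot <- tot + model$dG37[[paste0(av[i], av[i + 1])]]
    }
    best <- min(best, tot)
  }
  best
}

# naive sliding-window degenerate site search over both strands
oracle_find_sites <- function(primer, genome, max_mm = 0) {
  sets <- IUPAC_SETS[strsplit(primer, "")[[1]]]
  n <- length(sets)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_sets <- rev(lapply(sets, function(s) unname(comp[s])))
  hits <- list()
  for (contig in names(genome)) {
    ch <- strsplit(as.character(genome[[contig]]), "")[[1]]
    for (p in seq_len(length(ch) - n + 1)) {
      win <- ch[p:(p + n - 1)]
      mm_f <- sum(!mapply(function(s, b) b %in% s, sets, win))
      if (mm_f <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          contig = contig, start = p, end = p + n - 1, strand = "+",
          mismatches = mm_f, stringsAsFactors = FALSE)
      }
      mm_r <- sum(!mapply(function(s, b) b %in% s, rc_sets, win))
      if (mm_r <= max_mm) {
        hits[[length(hits) + 1]] <- data.frame(
          contig = contig, start = p, end = p + n - 1, strand = "-",
          mismatches = mm_r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# random degenerate oligo with bounded degeneracy
random_iupac <- function(len, max_d = 256) {
  repeat {
    codes <- sample(names(IUPAC_SETS), len, replace = TRUE,
                    prob = c(rep(8, 4), rep(2, 6), rep(1, 4), 0.5))
    d <- prod(vapply(IUPAC_SETS[codes], length, integer(1)))
    if (d <= max_d) return(paste0(codes, collapse = ""))
  }
}

random_concrete <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# published evaluated primer-pair table shipped with the package
evaluated_pairs <- function() {
  utils::read.table(system.file("extdata", "evaluated_primer_pairs.tsv",
                                package = "degeprimr"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
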