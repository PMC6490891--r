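# Independent oracles used to cross-check the package implementations.
# These are written from scratch (recursive enumeration, naive scanning,
# dense-grid search) rather than calling the code paths they verify.

.GC <- Biostrings::GENETIC_CODE
.STOPS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

oracle_aa <- function(cod) .GC[[cod]]

# fractional synonymous sites of one codon: per position, mean over the
# non-stop single-base changes of the indicator "same amino acid"
oracle_syn_sites <- function(cod) {
  s <- 0
  for (p in 1:3) {
    syn <- integer(0)
    for (b in setdiff(.BASES, substr(cod, p, p))) {
      alt <- cod
      substr(alt, p, p) <- b
      if (alt %in% .STOPS) next
      syn <- c(syn, as.integer(oracle_aa(alt) == oracle_aa(cod)))
    }
    if (length(syn)) s <- s + mean(syn)
  }
  s
}

# (synonymous, non-synonymous) differences between two codons, averaged
# over all minimal mutational pathways, enumerated recursively; pathways
# through stops excluded, with an all-pathway fallback
oracle_codon_diffs <- function(a, b, allow_stops = FALSE) {
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  rec <- function(cur, remaining) {
    if (length(remaining) == 0) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (!allow_stops && nxt %in% .STOPS) next
      step <- if (oracle_aa(nxt) == oracle_aa(cur)) c(1, 0) else c(0, 1)
      for (tl in rec(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- step + tl
      }
    }
    out
  }
  res <- rec(a, diffpos)
  if (length(res) == 0) return(oracle_codon_diffs(a, b, allow_stops = TRUE))
  colMeans(do.call(rbind, res))
}

# full NG86 on a pair of gap-free codon strings (or codon-aligned strings
# with "-" gaps), by explicit enumeration
oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a)
  cod_a <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cod_b <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  ok <- !grepl("-", cod_a) & !grepl("-", cod_b) &
    !cod_a %in% .STOPS & !cod_b %in% .STOPS
  cod_a <- cod_a[ok]; cod_b <- cod_b[ok]
  S <- mean(c(sum(vapply(cod_a, oracle_syn_sites, numeric(1))),
              sum(vapply(cod_b, oracle_syn_sites, numeric(1)))))
  N <- 3 * length(cod_a) - S
  d <- rowSums(vapply(seq_along(cod_a), function(i) {
    oracle_codon_diffs(cod_a[i], cod_b[i])
  }, numeric(2)))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(s_sites = S, n_sites = N, sd = d[1], nd = d[2],
       ks = jc(d[1] / S), ka = jc(d[2] / N))
}

# naive position-by-position IUPAC scanner (set membership per column,
# vectorized over offsets; sequence N only matched by pattern N)
.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T", "N"))

oracle_scan_strand <- function(seq, signal) {
  ch <- strsplit(seq, "")[[1]]
  pat <- strsplit(signal, "")[[1]]
  w <- length(pat)
  L <- length(ch)
  if (L < w) return(integer(0))
  ok <- rep(TRUE, L - w + 1)
  for (k in seq_len(w)) {
    ok <- ok & ch[seq_len(L - w + 1) + k - 1] %in% .IUPAC[[pat[k]]]
  }
  which(ok)
}

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# hits of a catalog on one sequence, both strands, as a data frame
# comparable to scan_promoters() output for a single promoter
oracle_scan <- function(id, seq, catalog) {
  rows <- list()
  for (k in seq_len(nrow(catalog))) {
    for (st in oracle_scan_strand(seq, catalog$signal[k])) {
      rows[[length(rows) + 1]] <- data.frame(
        promoter = id, motif = catalog$name[k], start = st, strand = "+",
        stringsAsFactors = FALSE)
    }
    rc <- oracle_revcomp(catalog$signal[k])
    for (st in oracle_scan_strand(seq, rc)) {
      rows[[length(rows) + 1]] <- data.frame(
        promoter = id, motif = catalog$name[k], start = st, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(promoter = character(), motif = character(),
                      start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$motif, out$strand), , drop = FALSE]
}

# score an emitted alignment under the affine model: substitution scores
# plus -(open + L * ext) per maximal gap run
score_alignment <- function(ga, gb, mat, open = 10, ext = 0.1) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  s <- 0
  run_a <- 0; run_b <- 0   # separate gap runs per row
  for (i in seq_along(ca)) {
    if (ca[i] == "-") {
      run_a <- run_a + 1
      if (run_b > 0) { s <- s - (open + run_b * ext); run_b <- 0 }
    } else if (cb[i] == "-") {
      run_b <- run_b + 1
      if (run_a > 0) { s <- s - (open + run_a * ext); run_a <- 0 }
    } else {
      if (run_a > 0) { s <- s - (open + run_a * ext); run_a <- 0 }
      if (run_b > 0) { s <- s - (open + run_b * ext); run_b <- 0 }
      s <- s + mat[ca[i], cb[i]]
    }
  }
  if (run_a > 0) s <- s - (open + run_a * ext)
  if (run_b > 0) s <- s - (open + run_b * ext)
  s
}

# exhaustive optimal global alignment score by enumerating every monotone
# alignment path (diagonal / up / left); feasible for lengths <= 6
enum_align_score <- function(a, b, mat, open = 10, ext = 0.1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ga, gb) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_alignment(paste(ga, collapse = ""),
                                         paste(gb, collapse = ""),
                                         mat, open, ext))
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, c(ga, ca[i]), c(gb, cb[j]))
    }
    if (i <= length(ca)) rec(i + 1, j, c(ga, ca[i]), c(gb, "-"))
    if (j <= length(cb)) rec(i, j + 1, c(ga, "-"), c(gb, cb[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

dna_score_matrix <- function() {
  m <- matrix(-3, 4, 4, dimnames = list(.BASES, .BASES))
  diag(m) <- 2
  m
}

blosum62 <- function() {
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

random_sense_cds <- function(n_codons) {
  paste(sample(setdiff(names(.GC), .STOPS), n_codons, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

seq_table <- function(ids, seqs, desc = "") {
  data.frame(id = ids, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}
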