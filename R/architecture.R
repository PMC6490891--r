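TOPOLOGY_CLASSES <- c("FULL_FORWARD", "FULL_REVERSE", "HALF_FORWARD",
                      "HALF_REVERSE", "QUARTER_NBD", "QUARTER_TMD",
                      "ABC2_NBD_NBD", "TMD_TMD", "UNIQUE")

#' Classify an ordered NBD/TMD domain string into a topology class
#'
#' ABC transporters fall into canonical domain arrangements: full-sized
#' (two TMDs + two NBDs), half-sized (one of each), quarter-sized (a single
#' domain), ABC2-type (NBD-NBD), TMD-TMD, and everything else (UNIQUE).
#' "Forward" means the TMD precedes the NBD; "reverse" the opposite.
#'
#' @param domain_string Character vector over `{"NBD","TMD"}`, ordered
#'   N-terminal to C-terminal.
#' @return One of `r paste(TOPOLOGY_CLASSES, collapse = ", ")`.
#' @export
classify_topology <- function(domain_string) {
  if (length(domain_string) == 0) stop("empty domain string")
  if (!all(domain_string %in% c("NBD", "TMD"))) {
    stop("domain string tokens must be NBD or TMD")
  }
  key <- paste(domain_string, collapse = "-")
  switch(key,
         "TMD-NBD-TMD-NBD" = "FULL_FORWARD",
         "NBD-TMD-NBD-TMD" = "FULL_REVERSE",
         "TMD-NBD" = "HALF_FORWARD",
         "NBD-TMD" = "HALF_REVERSE",
         "NBD" = "QUARTER_NBD",
         "TMD" = "QUARTER_TMD",
         "NBD-NBD" = "ABC2_NBD_NBD",
         "TMD-TMD" = "TMD_TMD",
         "UNIQUE")
}

#' Build per-protein domain architectures from domain hits
#'
#' Orders each protein's hits by alignment start; same-type hits
#' overlapping by more than 50% of the shorter hit are merged before the
#' domain string is read off. `soluble` flags proteins with no TMD.
#'
#' @param hits Domain-hit data frame from [parse_domtblout()].
#' @return `data.frame(protein_id, domain_string, topology_class, soluble)`
#'   with `domain_string` dash-separated.
#' @export
build_architectures <- function(hits) {
  stopifnot(all(c("protein_id", "domain_name", "ali_start", "ali_end")
                %in% names(hits)))
  ids <- sort(unique(hits$protein_id))
  rows <- lapply(ids, function(id) {
    h <- hits[hits$protein_id == id, , drop = FALSE]
    h <- h[order(h$ali_start, h$ali_end), , drop = FALSE]
    merged <- h[0, ]
    for (i in seq_len(nrow(h))) {
      if (nrow(merged) > 0) {
        j <- nrow(merged)
        ov <- min(merged$ali_end[j], h$ali_end[i]) -
          max(merged$ali_start[j], h$ali_start[i]) + 1L
        shorter <- min(merged$ali_end[j] - merged$ali_start[j],
                       h$ali_end[i] - h$ali_start[i]) + 1L
        if (merged$domain_name[j] == h$domain_name[i] && ov > 0.5 * shorter) {
          merged$ali_end[j] <- max(merged$ali_end[j], h$ali_end[i])
          merged$evalue[j] <- min(merged$evalue[j], h$evalue[i])
          next
        }
      }
      merged <- rbind(merged, h[i, , drop = FALSE])
    }
    ds <- merged$domain_name
    data.frame(protein_id = id,
               domain_string = paste(ds, collapse = "-"),
               topology_class = classify_topology(ds),
               soluble = !any(ds == "TMD"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count topology classes with full/half/quarter rollups
#'
#' @param architectures Data frame from [build_architectures()], or a
#'   character vector of topology classes.
#' @return List with `counts` (named integer vector over all nine classes,
#'   absent classes 0) and `rollups` (`full`, `half`, `quarter`).
#' @export
summarize_topology <- function(architectures) {
  cls <- if (is.data.frame(architectures)) architectures$topology_class
         else architectures
  if (length(cls) == 0) stop("no architectures to summarize")
  counts <- table(factor(cls, levels = TOPOLOGY_CLASSES))
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       rollups = c(full = counts[["FULL_FORWARD"]] + counts[["FULL_REVERSE"]],
                   half = counts[["HALF_FORWARD"]] + counts[["HALF_REVERSE"]],
                   quarter = counts[["QUARTER_NBD"]] + counts[["QUARTER_TMD"]]))
}

# Average residue masses (Da); peptide MW = sum(residues) + one water.
AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760)
WATER_MASS <- 18.0153

#' Average molecular weight of a peptide in Daltons
#' @param sequence Amino-acid string (standard 20-letter alphabet).
#' @export
compute_mw <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, names(AA_MASS))
  if (length(bad)) stop("unknown amino acid '", bad[1], "'")
  sum(AA_MASS[res]) + WATER_MASS
}

#' Load the packaged pKa set (EMBOSS values)
#' @return `data.frame(group, pka, sign)` covering the termini and the
#'   ionizable side chains C, D, E, H, K, R, Y.
#' @export
default_pka_set <- function() {
  read.delim(system.file("extdata", "emboss_pka.tsv", package = "famscan"),
             stringsAsFactors = FALSE)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and ionizable side chains:
#' basic groups contribute `+1/(1+10^(pH-pKa))`, acidic groups
#' `-1/(1+10^(pKa-pH))`. Strictly decreasing in pH.
#'
#' @param sequence Amino-acid string.
#' @param ph pH value (vectorized).
#' @param pka_set pKa table as from [default_pka_set()].
#' @export
net_charge <- function(sequence, ph, pka_set = default_pka_set()) {
  res <- strsplit(toupper(sequence), "")[[1]]
  counts <- c(Nterm = 1, Cterm = 1,
              table(factor(res, levels = setdiff(pka_set$group,
                                                 c("Nterm", "Cterm")))))
  vapply(ph, function(p) {
    q <- 0
    for (i in seq_len(nrow(pka_set))) {
      n <- counts[[pka_set$group[i]]]
      if (is.na(n) || n == 0) next
      q <- q + if (pka_set$sign[i] > 0) {
        n / (1 + 10^(p - pka_set$pka[i]))
      } else {
        -n / (1 + 10^(pka_set$pka[i] - p))
      }
    }
    q
  }, numeric(1))
}

#' Theoretical isoelectric point by bisection
#'
#' Finds the pH in [0, 14] where [net_charge()] crosses zero, to a
#' tolerance of 1e-3. The charge function is strictly decreasing in pH so
#' the root is unique; a sequence with no ionizable side chains still has
#' the terminus-driven root.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @export
compute_pi <- function(sequence, pka_set = default_pka_set(), tol = 1e-3) {
  if (!nzchar(sequence)) stop("empty sequence")
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Protein length, molecular weight and isoelectric point
#' @param seqs Sequence table from [parse_fasta()] (amino acids).
#' @return `data.frame(protein_id, length, mw, pi)`.
#' @export
protein_properties <- function(seqs) {
  data.frame(protein_id = seqs$id,
             length = nchar(seqs$seq),
             mw = vapply(seqs$seq, compute_mw, numeric(1), USE.NAMES = FALSE),
             pi = vapply(seqs$seq, compute_pi, numeric(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
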