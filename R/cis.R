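IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N"))

#' Compile an IUPAC degenerate signal into a matcher
#'
#' Position-wise set matcher: a sequence letter matches a pattern letter
#' iff it lies in that letter's IUPAC expansion. A sequence `N` is matched
#' only by a pattern `N` (ambiguity in the catalog, never in the genome,
#' counts as a match).
#'
#' @param signal IUPAC pattern over `ACGTRYSWKMBDHVN`.
#' @return List with `signal`, `length`, `regex` (PCRE with overlapping
#'   lookahead) and `sets` (per-position allowed letters).
#' @export
compile_iupac <- function(signal) {
  letters_ <- strsplit(toupper(signal), "")[[1]]
  if (length(letters_) == 0) stop("empty signal")
  bad <- setdiff(letters_, names(IUPAC_EXPANSION))
  if (length(bad)) stop("illegal IUPAC character '", bad[1], "'")
  sets <- IUPAC_EXPANSION[letters_]
  classes <- vapply(sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  list(signal = toupper(signal), length = length(letters_),
       regex = paste0("(?=(", paste(classes, collapse = ""), "))"),
       sets = sets)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.scan_one_strand <- function(seq, matcher) {
  m <- gregexpr(matcher$regex, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m)
}

#' Scan promoters for catalog motifs
#'
#' Reports every (overlapping) occurrence of every catalog signal at every
#' offset. Minus-strand hits are occurrences of the signal's reverse
#' complement on the forward sequence and are reported with
#' forward-orientation coordinates (`start` = leftmost base, 1-based).
#'
#' @param promoters Sequence table from [parse_fasta()] (nucleotide).
#' @param catalog Motif catalog `data.frame(name, signal, ...)`; defaults
#'   to the packaged [cis_element_catalog()].
#' @param strands `"both"` (default, the PLACE convention), `"+"` or `"-"`.
#' @return `data.frame(promoter, motif, start, strand, match)` ordered by
#'   (promoter, start, motif, strand).
#' @export
scan_promoters <- function(promoters, catalog = cis_element_catalog(),
                           strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  matchers <- lapply(catalog$signal, compile_iupac)
  rc_matchers <- lapply(catalog$signal, function(s) compile_iupac(.revcomp(s)))
  rows <- list()
  for (p in seq_len(nrow(promoters))) {
    seq <- toupper(promoters$seq[p])
    for (k in seq_len(nrow(catalog))) {
      if (strands %in% c("both", "+")) {
        for (st in .scan_one_strand(seq, matchers[[k]])) {
          rows[[length(rows) + 1]] <- data.frame(
            promoter = promoters$id[p], motif = catalog$name[k],
            start = st, strand = "+",
            match = substr(seq, st, st + matchers[[k]]$length - 1L),
            stringsAsFactors = FALSE)
        }
      }
      if (strands %in% c("both", "-")) {
        for (st in .scan_one_strand(seq, rc_matchers[[k]])) {
          rows[[length(rows) + 1]] <- data.frame(
            promoter = promoters$id[p], motif = catalog$name[k],
            start = st, strand = "-",
            match = substr(seq, st, st + rc_matchers[[k]]$length - 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(promoter = character(), motif = character(),
                      start = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$promoter, promoters$id), out$start, out$motif,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motifs present in every promoter
#'
#' Presence/absence intersection: a motif qualifies when it has at least
#' one hit (either strand) in every listed promoter.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param promoter_ids Promoters that must all contain a motif; promoters
#'   with no hits still count against every motif.
#' @return Sorted character vector of motif names.
#' @export
common_elements <- function(hits, promoter_ids) {
  if (length(promoter_ids) == 0) stop("empty promoter set")
  present <- unique(hits[hits$promoter %in% promoter_ids,
                         c("promoter", "motif")])
  tab <- table(present$motif)
  sort(names(tab)[tab == length(unique(promoter_ids))])
}

#' Extract promoter sequences upstream of gene models
#'
#' For a `+` strand gene the promoter is the `upstream_length` bases ending
#' immediately before the gene start; for a `-` strand gene it is the
#' reverse complement of the bases immediately after the gene end. The
#' result is 5'->3' relative to the gene. Promoters truncated by a contig
#' edge are flagged; a gene with zero upstream bases is an error.
#'
#' @param genes Gene-model data frame from [parse_gff3()].
#' @param genome Sequence table (from [parse_fasta()]) of contigs.
#' @param upstream_length Promoter length in bp (default 1500).
#' @return Sequence table `data.frame(id, desc, seq)` plus a `truncated`
#'   logical column; `id` equals the gene id.
#' @export
extract_promoters <- function(genes, genome, upstream_length = 1500) {
  stopifnot(upstream_length > 0)
  contig <- setNames(toupper(genome$seq), genome$id)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$seq_id %in% names(contig)) {
      stop("contig '", g$seq_id, "' not found for gene '", g$gene_id, "'")
    }
    clen <- nchar(contig[[g$seq_id]])
    if (g$strand == "+") {
      from <- max(1L, g$start - upstream_length)
      to <- g$start - 1L
      if (to < from) stop("gene '", g$gene_id, "' has no upstream sequence")
      seq <- substr(contig[[g$seq_id]], from, to)
    } else {
      from <- g$end + 1L
      to <- min(clen, g$end + upstream_length)
      if (to < from) stop("gene '", g$gene_id, "' has no upstream sequence")
      seq <- .revcomp(substr(contig[[g$seq_id]], from, to))
    }
    data.frame(id = g$gene_id, desc = "promoter", seq = seq,
               truncated = nchar(seq) < upstream_length,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
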