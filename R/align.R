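#' Alignment parameter set
#'
#' Gap penalties default to the gap-open/gap-extension pair 10 / 0.1 used
#' throughout the pipeline; a gap of length L costs
#' `gap_open + L * gap_extend`. The protein matrix is BLOSUM62; nucleotide
#' scoring is +2 match / -3 mismatch.
#'
#' @param matrix `"BLOSUM62"` (protein) or `"DNA"` (+2/-3).
#' @param gap_open,gap_extend Non-negative penalties,
#'   `gap_open >= gap_extend`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.1) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

.subst_matrix <- function(name) {
  if (name == "DNA") {
    Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                             baseOnly = TRUE)
  } else {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
  }
}

.record <- function(x, what = "sequence") {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    list(id = x$id, seq = x$seq)
  } else if (is.character(x) && length(x) == 1) {
    list(id = what, seq = toupper(x))
  } else stop("expected a single-row sequence table or a string")
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings) under the package's
#' affine gap model. Protein sequences are scored with BLOSUM62 and
#' nucleotide sequences with +2/-3 according to `params$matrix`.
#'
#' @param a,b Single-row sequence tables (from [parse_fasta()]) or plain
#'   strings.
#' @param params An [align_params()] object.
#' @return List of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b`, `score`, `identity_pct`, `coverage_pct`.
#' @export
global_align <- function(a, b, params = align_params()) {
  ra <- .record(a, "a"); rb <- .record(b, "b")
  if (!nzchar(ra$seq) || !nzchar(rb$seq)) stop("empty sequence")
  is_dna_a <- grepl("^[ACGTN]+$", ra$seq)
  is_dna_b <- grepl("^[ACGTN]+$", rb$seq)
  if (params$matrix == "DNA" && !(is_dna_a && is_dna_b)) {
    stop("alphabet mismatch: DNA scoring requested for non-nucleotide input")
  }
  aln <- Biostrings::pairwiseAlignment(
    ra$seq, rb$seq, type = "global",
    substitutionMatrix = .subst_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  stats <- homology_stats(list(aligned_a = ga, aligned_b = gb,
                               len_a = nchar(ra$seq), len_b = nchar(rb$seq)))
  structure(list(id_a = ra$id, id_b = rb$id, aligned_a = ga, aligned_b = gb,
                 score = Biostrings::score(aln),
                 identity_pct = stats[["identity_pct"]],
                 coverage_pct = stats[["coverage_pct"]]),
            class = "pairwise_alignment")
}

#' Percent identity and coverage of a pairwise alignment
#'
#' Identity is matches over aligned (both-non-gap) columns x 100; coverage
#' is aligned columns over the shorter input length x 100. These feed the
#' paralog (> 70 / > 70, strict) and ortholog (>= 98 / >= 70, inclusive)
#' homology criteria.
#'
#' @param aln A `pairwise_alignment`, or any list with equal-length gapped
#'   `aligned_a` / `aligned_b` strings.
#' @return Named numeric vector `c(identity_pct, coverage_pct)`.
#' @export
homology_stats <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  both <- ca != "-" & cb != "-"
  n_aln <- sum(both)
  if (n_aln == 0) stop("alignment has zero aligned columns; identity undefined")
  len_a <- if (!is.null(aln$len_a)) aln$len_a else sum(ca != "-")
  len_b <- if (!is.null(aln$len_b)) aln$len_b else sum(cb != "-")
  c(identity_pct = 100 * sum(ca[both] == cb[both]) / n_aln,
    coverage_pct = 100 * n_aln / min(len_a, len_b))
}

.check_cds <- function(seq, id) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) {
    stop("CDS '", id, "' length not divisible by 3")
  }
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  if (stops[length(stops)]) {  # trailing stop trimmed
    codons <- codons[-length(codons)]
    stops <- stops[-length(stops)]
  }
  if (any(stops)) {
    stop("internal stop codon at codon ", which(stops)[1], " of '", id, "'")
  }
  codons
}

#' Protein-guided codon alignment of two CDS
#'
#' Translates both coding sequences, globally aligns the proteins, and
#' back-threads each aligned residue or gap to its codon triplet, so all
#' gaps are whole-codon units and the reading frame is preserved. A single
#' trailing stop codon is trimmed; internal stops are an error.
#'
#' @param cds_a,cds_b Single-row nucleotide sequence tables or strings.
#' @param params Protein [align_params()] used for the guide alignment.
#' @return List of class `codon_alignment` with gapped `aligned_a`,
#'   `aligned_b` (nucleotide strings, lengths multiples of 3).
#' @export
codon_align <- function(cds_a, cds_b, params = align_params()) {
  ra <- .record(cds_a, "a"); rb <- .record(cds_b, "b")
  cod_a <- .check_cds(ra$seq, ra$id)
  cod_b <- .check_cds(rb$seq, rb$id)
  prot_a <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cod_a, collapse = ""))))
  prot_b <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(cod_b, collapse = ""))))
  aln <- global_align(prot_a, prot_b, params)
  expand <- function(gapped, codons) {
    out <- character(nchar(gapped))
    j <- 0
    for (i in seq_len(nchar(gapped))) {
      if (substr(gapped, i, i) == "-") out[i] <- "---"
      else { j <- j + 1; out[i] <- codons[j] }
    }
    paste(out, collapse = "")
  }
  structure(list(id_a = ra$id, id_b = rb$id,
                 aligned_a = expand(aln$aligned_a, cod_a),
                 aligned_b = expand(aln$aligned_b, cod_b)),
            class = "codon_alignment")
}
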