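# Locus id: protein/transcript id with a trailing ".<digits>" isoform
# suffix stripped, so two isoforms of one locus collapse together.
.locus_id <- function(id) sub("\\.\\d+$", "", id)

#' Filter domain hits into family-member candidates
#'
#' Keeps proteins carrying at least one nucleotide-binding-domain (NBD)
#' hit at `evalue <= evalue_max` (the boundary is kept: the exclusion rule
#' drops E-values strictly greater than the cutoff). Redundant entries --
#' identical sequences, or isoforms sharing a locus id -- are collapsed to
#' the longest sequence (equal lengths: lexicographically smallest id).
#' Output order is deterministic (`protein_id` ascending) and invariant to
#' input order.
#'
#' @param hits Domain-hit table from [parse_domtblout()].
#' @param proteins Sequence table from [parse_fasta()]; every hit must
#'   reference one of these ids.
#' @param evalue_max Inclusive E-value cutoff (default 1e-5).
#' @return `data.frame(protein_id, n_nbd, n_tmd, best_evalue, seq)`.
#' @export
filter_candidates <- function(hits, proteins, evalue_max = 1e-5) {
  missing <- setdiff(hits$protein_id, proteins$id)
  if (length(missing)) {
    stop("domain hit references protein '", missing[1],
         "' absent from the FASTA")
  }
  nbd <- hits[hits$domain_name == "NBD" & hits$evalue <= evalue_max, ]
  keep_ids <- sort(unique(nbd$protein_id))
  if (length(keep_ids) == 0) {
    return(data.frame(protein_id = character(), n_nbd = integer(),
                      n_tmd = integer(), best_evalue = numeric(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  cand <- proteins[match(keep_ids, proteins$id), c("id", "seq")]
  # redundancy collapse: identical sequence, then shared locus id; the
  # longest sequence survives, equal lengths keep the smallest id
  cand <- cand[order(-nchar(cand$seq), cand$id), , drop = FALSE]
  cand <- cand[!duplicated(cand$seq), , drop = FALSE]
  cand <- cand[!duplicated(.locus_id(cand$id)), , drop = FALSE]
  cand <- cand[order(cand$id), , drop = FALSE]
  stats <- lapply(cand$id, function(id) {
    h <- hits[hits$protein_id == id, ]
    data.frame(protein_id = id,
               n_nbd = sum(h$domain_name == "NBD"),
               n_tmd = sum(h$domain_name == "TMD"),
               best_evalue = min(h$evalue[h$domain_name == "NBD"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  out$seq <- cand$seq
  rownames(out) <- NULL
  out
}

#' Assign a subfamily by nearest labeled reference
#'
#' Globally aligns the query against every reference protein and returns
#' the subfamily label of the highest-scoring alignment; score ties are
#' broken by the lexicographically smallest reference id.
#'
#' @param query Single-row sequence table or a protein string.
#' @param refs Labeled reference set: sequence table with a `subfamily`
#'   column (letters A-G, I).
#' @param params Protein [align_params()].
#' @return List: `subfamily`, `score`, `ref_id`.
#' @export
assign_subfamily <- function(query, refs, params = align_params()) {
  if (nrow(refs) == 0) stop("empty reference set")
  q <- .record(query, "query")
  if (!nzchar(q$seq)) stop("empty query sequence")
  ord <- order(refs$id)
  best <- NULL
  for (i in ord) {
    sc <- global_align(q$seq, refs$seq[i], params)$score
    if (is.null(best) || sc > best$score) {
      best <- list(subfamily = refs$subfamily[i], score = sc,
                   ref_id = refs$id[i])
    }
  }
  best
}

#' Assign systematic gene symbols within (species, subfamily)
#'
#' Symbols are `<prefix>ABC<subfamily><index>` with indices 1..n assigned
#' by chromosome name then start position, ascending. Members on
#' unanchored scaffolds (seq ids not matching `anchored_regex`) are
#' numbered after anchored ones; members with no gene model are placed
#' last (with a warning). Coordinate ties break by `protein_id`.
#'
#' @param members `data.frame(protein_id, subfamily, ...)`.
#' @param gene_models Gene-model table from [parse_gff3()]; matched to
#'   members by `gene_id == protein_id`.
#' @param species_prefix Two-letter species code (e.g. `"Ca"`).
#' @param anchored_regex Pattern distinguishing chromosomes from
#'   scaffolds.
#' @return `members` with `symbol`, `chromosome`, `start`, `end`, `strand`
#'   columns added, ordered by symbol.
#' @export
assign_names <- function(members, gene_models, species_prefix,
                         anchored_regex = "^(chr|Chr)?[0-9]+$") {
  m <- match(members$protein_id, gene_models$gene_id)
  members$chromosome <- gene_models$seq_id[m]
  members$start <- gene_models$start[m]
  members$end <- gene_models$end[m]
  members$strand <- gene_models$strand[m]
  if (anyNA(m)) {
    warning(sum(is.na(m)), " member(s) without a gene model placed last")
  }
  anchored <- !is.na(m) & grepl(anchored_regex, members$chromosome)
  tier <- ifelse(is.na(m), 3L, ifelse(anchored, 1L, 2L))
  out <- lapply(split(members, members$subfamily), function(d) {
    ord <- order(tier[match(d$protein_id, members$protein_id)],
                 d$chromosome, d$start, d$protein_id, na.last = TRUE)
    d <- d[ord, , drop = FALSE]
    d$symbol <- paste0(species_prefix, "ABC", d$subfamily, seq_len(nrow(d)))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  cols <- c("symbol", "protein_id", "subfamily", "chromosome", "start",
            "end", "strand")
  out[, c(cols, setdiff(names(out), cols))]
}

#' Identify, classify and name family members end to end
#'
#' Convenience wrapper chaining [filter_candidates()],
#' [assign_subfamily()] (against a labeled reference set, when supplied)
#' and [assign_names()].
#'
#' @param proteins,hits,gene_models Parsed inputs.
#' @param refs Optional labeled reference set; without it the subfamily
#'   column is `NA` and symbols are not assigned.
#' @param species_prefix Two-letter species code.
#' @param evalue_max E-value cutoff for [filter_candidates()].
#' @return Member table with symbols (when refs are given).
#' @export
identify_family <- function(proteins, hits, gene_models = NULL, refs = NULL,
                            species_prefix = "Ca", evalue_max = 1e-5) {
  members <- filter_candidates(hits, proteins, evalue_max)
  if (!is.null(refs)) {
    asg <- lapply(members$seq, assign_subfamily, refs = refs)
    members$subfamily <- vapply(asg, `[[`, character(1), "subfamily")
    members$subfamily_score <- vapply(asg, `[[`, numeric(1), "score")
    if (!is.null(gene_models)) {
      members <- assign_names(members, gene_models, species_prefix)
    }
  }
  members
}
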