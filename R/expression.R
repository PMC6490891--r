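#' RPKM normalization of a read-count matrix
#'
#' `RPKM[g, s] = 1e9 * C[g, s] / (N[s] * L[g])` with gene lengths in bp
#' and `N` the total mapped reads per sample. Exactly linear in counts at
#' fixed `N` and `L`, and invariant to scaling counts and library sizes
#' together.
#'
#' @param counts Integer matrix, genes x samples (dimnames recommended).
#' @param gene_length Numeric vector of gene lengths in bp (> 0), one per
#'   row.
#' @param library_size Total mapped reads per sample; defaults to the
#'   column sums. Must be >= the column sums and > 0.
#' @return Numeric matrix of RPKM values, same shape as `counts`.
#' @export
rpkm <- function(counts, gene_length, library_size = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_length) != nrow(counts)) {
    stop("gene_length must have one entry per gene")
  }
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("negative counts")
  zero <- which(library_size == 0)
  if (length(zero)) {
    stop("library size is zero for sample ",
         if (!is.null(colnames(counts))) colnames(counts)[zero[1]] else zero[1])
  }
  if (any(library_size < colSums(counts) - 1e-9)) {
    stop("library_size smaller than column sum")
  }
  out <- 1e9 * t(t(counts / gene_length) / library_size)
  dimnames(out) <- dimnames(counts)
  out
}

#' Log2 heatmap matrix with hierarchical orderings
#'
#' Transforms RPKM to `log2(RPKM + pseudo)` and orders rows (and columns,
#' when there are >= 3 samples) by agglomerative clustering, average
#' linkage on Euclidean distances by default. Fully deterministic for a
#' fixed input.
#'
#' @param expr RPKM matrix.
#' @param pseudo Pseudo-count added before the log (default 1, so RPKM 0
#'   maps to 0).
#' @param linkage,metric Passed to [stats::hclust()] / [stats::dist()].
#' @return List: `matrix` (transformed, reordered), `row_order`,
#'   `col_order` (indices into the input).
#' @export
heatmap_matrix <- function(expr, pseudo = 1, linkage = "average",
                           metric = "euclidean") {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0) stop("empty expression matrix")
  lg <- log2(expr + pseudo)
  row_order <- seq_len(nrow(lg))
  if (nrow(lg) > 1) {
    row_order <- stats::hclust(stats::dist(lg, method = metric),
                               method = linkage)$order
  }
  col_order <- seq_len(ncol(lg))
  if (ncol(lg) > 2) {
    col_order <- stats::hclust(stats::dist(t(lg), method = metric),
                               method = linkage)$order
  }
  list(matrix = lg[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order)
}

#' Shared and specific expression sets across sample groups
#'
#' A gene counts as expressed in a group when its RPKM reaches `threshold`
#' in at least one sample of that group. Genes are assigned to the Venn
#' region named by the sorted group names joined with `"&"`; regions
#' partition the genes expressed in at least one group.
#'
#' @param expr RPKM matrix with column names.
#' @param groups Named character vector mapping sample (column) name to
#'   group label; every name must be a column of `expr`.
#' @param threshold Expression threshold in RPKM units (default 1).
#' @return Named list of gene-id vectors, one per non-empty region.
#' @export
expression_sets <- function(expr, groups, threshold = 1) {
  expr <- as.matrix(expr)
  if (length(unique(groups)) < 2) stop("need at least two groups")
  unknown <- setdiff(names(groups), colnames(expr))
  if (length(unknown)) stop("unknown sample in group map: '", unknown[1], "'")
  glabs <- sort(unique(groups))
  expressed <- vapply(glabs, function(g) {
    cols <- names(groups)[groups == g]
    apply(expr[, cols, drop = FALSE] >= threshold, 1, any)
  }, logical(nrow(expr)))
  if (is.null(dim(expressed))) expressed <- matrix(expressed, nrow = 1)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expr)))
  region <- apply(expressed, 1, function(e) paste(glabs[e], collapse = "&"))
  keep <- region != ""
  split(genes[keep], region[keep])
}

#' Reciprocal-best-hit ortholog matching between two CDS sets
#'
#' All-vs-all global nucleotide alignment (+2/-3, affine gaps 10/0.1);
#' candidate pairs must pass identity >= `min_identity` and coverage >=
#' `min_coverage` (inclusive), and a pair is reported only when each
#' member is the other's highest-scoring candidate (reciprocal best hit;
#' score ties broken by lexicographically smallest partner id).
#'
#' @param cds_a,cds_b Sequence tables of coding sequences.
#' @param min_identity,min_coverage Inclusive thresholds in percent
#'   (defaults 98 / 70).
#' @return `data.frame(id_a, id_b, identity_pct, coverage_pct, score)`.
#' @export
match_orthologs <- function(cds_a, cds_b, min_identity = 98,
                            min_coverage = 70) {
  if (nrow(cds_a) == 0 || nrow(cds_b) == 0) stop("empty sequence set")
  params <- align_params(matrix = "DNA")
  cand <- list()
  for (i in seq_len(nrow(cds_a))) {
    for (j in seq_len(nrow(cds_b))) {
      aln <- global_align(cds_a[i, ], cds_b[j, ], params)
      if (aln$identity_pct >= min_identity &&
          aln$coverage_pct >= min_coverage) {
        cand[[length(cand) + 1]] <- data.frame(
          id_a = cds_a$id[i], id_b = cds_b$id[j],
          identity_pct = aln$identity_pct,
          coverage_pct = aln$coverage_pct, score = aln$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, cand)
  best_of <- function(df, key, partner) {
    do.call(rbind, lapply(split(df, df[[key]]), function(d) {
      d <- d[order(-d$score, d[[partner]]), , drop = FALSE]
      d[1, , drop = FALSE]
    }))
  }
  ba <- best_of(tab, "id_a", "id_b")
  bb <- best_of(tab, "id_b", "id_a")
  rbh <- merge(ba, bb)
  rbh <- rbh[order(rbh$id_a, rbh$id_b), , drop = FALSE]
  rownames(rbh) <- NULL
  rbh[, c("id_a", "id_b", "identity_pct", "coverage_pct", "score")]
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt = mean(target Ct) - mean(reference Ct)` per sample;
#' `ddCt = dCt(sample) - dCt(calibrator)`; fold change `2^-ddCt`.
#' The per-sample SD of dCt is propagated from the replicate SDs in
#' quadrature: `sqrt(sd_target^2 + sd_reference^2)`.
#'
#' @param target_ct,reference_ct Replicate Ct values for the sample
#'   (typically 3 each; values must lie in (0, 45)).
#' @param cal_target_ct,cal_reference_ct Replicate Ct values for the
#'   calibrator sample.
#' @return List: `fold`, `ddct`, `dct`, `sd_dct`, and the fold range
#'   `fold_lo` / `fold_hi` at one SD.
#' @export
ddct <- function(target_ct, reference_ct, cal_target_ct, cal_reference_ct) {
  for (v in list(target_ct, reference_ct, cal_target_ct, cal_reference_ct)) {
    if (length(v) < 1) stop("missing Ct replicates")
    if (any(v <= 0 | v >= 45)) stop("Ct values must lie in (0, 45)")
  }
  dct <- mean(target_ct) - mean(reference_ct)
  dct_cal <- mean(cal_target_ct) - mean(cal_reference_ct)
  dd <- dct - dct_cal
  sd_dct <- sqrt(stats::sd(target_ct)^2 + stats::sd(reference_ct)^2)
  if (is.na(sd_dct)) sd_dct <- 0
  list(fold = 2^(-dd), ddct = dd, dct = dct, sd_dct = sd_dct,
       fold_lo = 2^(-(dd + sd_dct)), fold_hi = 2^(-(dd - sd_dct)))
}

#' ddCt fold changes for a long-format Ct table
#'
#' @param ct `data.frame(sample, gene, ct)`, one row per replicate.
#' @param reference Reference (normalizer) gene name, e.g. beta-tubulin.
#' @param calibrator Calibrator sample id (fold 1 by construction).
#' @return `data.frame(sample, gene, fold, ddct, sd_dct)` for every
#'   non-reference gene and sample.
#' @export
ddct_table <- function(ct, reference = "beta_tubulin", calibrator) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct)))
  if (!reference %in% ct$gene) stop("reference gene '", reference,
                                    "' absent from table")
  if (!calibrator %in% ct$sample) stop("calibrator sample '", calibrator,
                                       "' absent from table")
  targets <- setdiff(unique(ct$gene), reference)
  samples <- unique(ct$sample)
  grab <- function(s, g) ct$ct[ct$sample == s & ct$gene == g]
  rows <- list()
  for (g in targets) {
    for (s in samples) {
      tv <- grab(s, g); rv <- grab(s, reference)
      if (length(tv) == 0) next
      if (length(rv) == 0) stop("sample '", s, "' lacks reference replicates")
      res <- ddct(tv, rv, grab(calibrator, g), grab(calibrator, reference))
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, gene = g, fold = res$fold, ddct = res$ddct,
        sd_dct = res$sd_dct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
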