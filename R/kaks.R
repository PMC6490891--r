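STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$tabs)) return(.codon_env$tabs)
  gc_map <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- names(gc_map)
  # Fractional synonymous sites per codon: at each position the fraction of
  # the possible single-base changes that are synonymous, with changes to
  # stop codons excluded from both numerator and denominator.
  syn_sites <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (cod %in% STOP_CODONS) { syn_sites[cod] <- NA_real_; next }
    s <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(bases, substr(cod, p, p)), function(b) {
        x <- cod; substr(x, p, p) <- b; x
      }, character(1))
      alts <- alts[!alts %in% STOP_CODONS]
      if (length(alts) == 0) next
      s <- s + sum(gc_map[alts] == gc_map[cod]) / length(alts)
    }
    syn_sites[cod] <- s
  }
  # Pairwise expected synonymous/non-synonymous differences, averaged over
  # all minimal mutational pathways between the two codons; pathways that
  # pass through a stop codon are excluded (all-pathway fallback if every
  # pathway is blocked).
  sense <- setdiff(codons, STOP_CODONS)
  SD <- matrix(0, 61, 61, dimnames = list(sense, sense))
  ND <- SD
  perms <- list(`1` = matrix(1, 1, 1),
                `2` = rbind(c(1, 2), c(2, 1)),
                `3` = rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      if (j <= i) next
      a <- sense[i]; b <- sense[j]
      diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      k <- length(diffpos)
      if (k == 0) next
      paths <- perms[[as.character(k)]]
      tally <- function(require_no_stop) {
        sd_tot <- 0; nd_tot <- 0; n_path <- 0
        for (r in seq_len(nrow(paths))) {
          cur <- a; sd <- 0; nd <- 0; ok <- TRUE
          for (p in diffpos[paths[r, ]]) {
            nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
            if (require_no_stop && nxt %in% STOP_CODONS) { ok <- FALSE; break }
            if (gc_map[[nxt]] == gc_map[[cur]]) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
          }
          if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
                    n_path <- n_path + 1 }
        }
        c(sd_tot, nd_tot, n_path)
      }
      t1 <- tally(TRUE)
      if (t1[3] == 0) t1 <- tally(FALSE)
      SD[i, j] <- SD[j, i] <- t1[1] / t1[3]
      ND[i, j] <- ND[j, i] <- t1[2] / t1[3]
    }
  }
  .codon_env$tabs <- list(syn_sites = syn_sites, SD = SD, ND = ND)
  .codon_env$tabs
}

.split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1, n, 3), seq(3, n, 3))
}

#' Jukes-Cantor multiple-hit correction
#' @param p Proportion of observed differences per site.
#' @return `-(3/4) log(1 - (4/3) p)`; `NA` (saturation) when `p >= 3/4`.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori (1986) Ka/Ks estimation on a codon alignment
#'
#' Counts fractional synonymous (S) and non-synonymous (N) sites per codon
#' (averaged over the two sequences), counts synonymous/non-synonymous
#' differences averaged over all minimal mutational pathways between each
#' codon pair (pathways through stop codons excluded), and applies the
#' Jukes-Cantor correction to the per-site proportions. Codons containing
#' a gap or a stop in either row are skipped entirely.
#'
#' @param aln A `codon_alignment` from [codon_align()], or a list with
#'   gapped `aligned_a` / `aligned_b` codon-aligned nucleotide strings.
#' @param eps Tolerance handed to [classify_selection()].
#' @return List with `s_sites`, `n_sites`, `sd`, `nd`, `n_codons`
#'   (compared codons), `ka`, `ks`, `omega`, `call`, and `saturated`
#'   (TRUE when a Jukes-Cantor proportion reached 3/4 and the rate is NA).
#' @export
ng86 <- function(aln, eps = 0) {
  tabs <- .codon_tables()
  ca <- toupper(aln$aligned_a); cb <- toupper(aln$aligned_b)
  if (nchar(ca) != nchar(cb) || nchar(ca) %% 3 != 0) {
    stop("codon alignment rows must have equal length divisible by 3")
  }
  cod_a <- .split_codons(ca); cod_b <- .split_codons(cb)
  usable <- !grepl("-", cod_a, fixed = TRUE) &
    !grepl("-", cod_b, fixed = TRUE) &
    !cod_a %in% STOP_CODONS & !cod_b %in% STOP_CODONS &
    grepl("^[ACGT]{3}$", cod_a) & grepl("^[ACGT]{3}$", cod_b)
  cod_a <- cod_a[usable]; cod_b <- cod_b[usable]
  n_cod <- length(cod_a)
  if (n_cod == 0) stop("no comparable codons in alignment")
  S <- (sum(tabs$syn_sites[cod_a]) + sum(tabs$syn_sites[cod_b])) / 2
  N <- 3 * n_cod - S
  idx <- cbind(match(cod_a, rownames(tabs$SD)), match(cod_b, colnames(tabs$SD)))
  Sd <- sum(tabs$SD[idx]); Nd <- sum(tabs$ND[idx])
  ks <- jukes_cantor(Sd / S)
  ka <- jukes_cantor(Nd / N)
  saturated <- is.na(ks) || is.na(ka)
  omega <- if (saturated || ks == 0) NA_real_ else ka / ks
  list(s_sites = S, n_sites = N, sd = Sd, nd = Nd, n_codons = n_cod,
       ka = ka, ks = ks, omega = omega,
       call = classify_selection(ka, ks, eps = eps), saturated = saturated)
}

#' Classify selection pressure from Ka and Ks
#'
#' omega = Ka/Ks; `omega > 1 + eps` is positive selection,
#' `omega < 1 - eps` purifying, values within `eps` of 1 neutral, and the
#' call is `undefined` when Ks is 0 or either rate is unavailable.
#'
#' @param ka,ks Substitution rates per site (either may be NA).
#' @param eps Half-width of the neutral band around omega = 1 (default 0).
#' @export
classify_selection <- function(ka, ks, eps = 0) {
  if (is.na(ka) || is.na(ks) || ks == 0) return("undefined")
  omega <- ka / ks
  if (omega > 1 + eps) "positive"
  else if (omega < 1 - eps) "purifying"
  else "neutral"
}

#' Date a duplication event from Ks under a synonymous clock
#'
#' T = Ks / (2 lambda), reported in million years. The default clock rate
#' is 6.96e-9 synonymous substitutions per site per year, the standard
#' Solanaceae calibration.
#'
#' @param ks Synonymous substitutions per site (NA propagates).
#' @param lambda Clock rate per site per year (> 0).
#' @return Time in million years ago (MYA).
#' @export
duplication_time <- function(ks, lambda = 6.96e-9) {
  stopifnot(lambda > 0)
  ks / (2 * lambda) / 1e6
}

#' Discover syntenic paralog pairs by homology criteria
#'
#' All-vs-all protein-guided codon alignment of the coding sequences;
#' a pair becomes an edge when nucleotide identity and coverage both
#' exceed the thresholds strictly (> 70 / > 70 by default). Each retained
#' pair is annotated with its NG86 estimates, duplication time, the size
#' of its connected component in the duplication graph, and a
#' `strongly_connected` flag marking components with at least two edges
#' (i.e. a minimum of two duplication events).
#'
#' @param cds Sequence table of coding sequences (from [parse_fasta()]).
#' @param min_identity,min_coverage Strict thresholds in percent.
#' @param lambda Clock rate for [duplication_time()].
#' @param require_strong Drop pairs outside strongly connected components.
#' @return Data frame, one row per retained pair, ordered by
#'   `(gene_a, gene_b)`.
#' @export
find_paralog_pairs <- function(cds, min_identity = 70, min_coverage = 70,
                               lambda = 6.96e-9, require_strong = FALSE) {
  if (nrow(cds) < 2) stop("need at least two sequences")
  ids <- cds$id
  rows <- list()
  for (i in seq_len(nrow(cds) - 1)) {
    for (j in (i + 1):nrow(cds)) {
      caln <- codon_align(cds[i, ], cds[j, ])
      st <- homology_stats(caln)
      if (st[["identity_pct"]] > min_identity &&
          st[["coverage_pct"]] > min_coverage) {
        est <- ng86(caln)
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j],
          identity_pct = st[["identity_pct"]],
          coverage_pct = st[["coverage_pct"]],
          s_sites = est$s_sites, n_sites = est$n_sites,
          sd = est$sd, nd = est$nd, ka = est$ka, ks = est$ks,
          omega = est$omega, selection = est$call,
          t_mya = duplication_time(est$ks, lambda),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      s_sites = numeric(), n_sites = numeric(),
                      sd = numeric(), nd = numeric(), ka = numeric(),
                      ks = numeric(), omega = numeric(),
                      selection = character(), t_mya = numeric(),
                      component = integer(), component_edges = integer(),
                      strongly_connected = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  # connected components of the duplication graph (union-find)
  verts <- sort(unique(c(out$gene_a, out$gene_b)))
  parent <- seq_along(verts)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(out))) {
    ra <- find(match(out$gene_a[r], verts))
    rb <- find(match(out$gene_b[r], verts))
    if (ra != rb) parent[rb] <- ra
  }
  comp_of <- vapply(seq_along(verts), find, integer(1))
  comp_id <- match(comp_of, sort(unique(comp_of)))
  edge_comp <- comp_id[match(out$gene_a, verts)]
  edges_per <- table(edge_comp)
  out$component <- edge_comp
  out$component_edges <- as.integer(edges_per[as.character(edge_comp)])
  out$strongly_connected <- out$component_edges >= 2
  if (require_strong) out <- out[out$strongly_connected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.species_prefix <- function(symbol) substr(symbol, 1, 2)

#' Summary statistics over a paralog-pair table
#'
#' Accepts either the output of [find_paralog_pairs()] (columns `gene_a`,
#' `gene_b`) or a published-style table with a single `pair` column of the
#' form `SYMA-SYMB`; requires `omega` and `t_mya` columns. Selection calls
#' are derived from `omega` with [classify_selection()].
#'
#' @param pairs Paralog-pair data frame, e.g. [paralog_pair_fixture()].
#' @param eps Neutral band for selection classification.
#' @return List: `n_pairs`, `mean_omega`, `min_omega`, `max_omega`,
#'   `n_purifying`, `n_positive`, `pct_positive`, `mean_t_mya`,
#'   `n_intraspecies` (pairs whose two symbols share a species prefix).
#'   Values are unrounded.
#' @export
summarize_pairs <- function(pairs, eps = 0) {
  if (nrow(pairs) == 0) stop("empty paralog-pair table")
  if (!"gene_a" %in% names(pairs)) {
    halves <- strsplit(pairs$pair, "-", fixed = TRUE)
    pairs$gene_a <- vapply(halves, `[`, character(1), 1)
    pairs$gene_b <- vapply(halves, `[`, character(1), 2)
  }
  omega <- pairs$omega
  calls <- vapply(seq_len(nrow(pairs)), function(i) {
    if (is.na(omega[i])) "undefined"
    else if (omega[i] > 1 + eps) "positive"
    else if (omega[i] < 1 - eps) "purifying"
    else "neutral"
  }, character(1))
  intra <- .species_prefix(pairs$gene_a) == .species_prefix(pairs$gene_b)
  list(n_pairs = nrow(pairs),
       mean_omega = mean(omega, na.rm = TRUE),
       min_omega = min(omega, na.rm = TRUE),
       max_omega = max(omega, na.rm = TRUE),
       n_purifying = sum(calls == "purifying"),
       n_positive = sum(calls == "positive"),
       pct_positive = 100 * sum(calls == "positive") / nrow(pairs),
       mean_t_mya = mean(pairs$t_mya, na.rm = TRUE),
       n_intraspecies = sum(intra))
}
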