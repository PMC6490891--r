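AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")

.random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
.random_dna <- function(n) paste(sample(DNA4, n, replace = TRUE), collapse = "")

.CLASS_TEMPLATES <- list(
  FULL_FORWARD = c("TMD", "NBD", "TMD", "NBD"),
  FULL_REVERSE = c("NBD", "TMD", "NBD", "TMD"),
  HALF_FORWARD = c("TMD", "NBD"),
  HALF_REVERSE = c("NBD", "TMD"),
  QUARTER_NBD = "NBD",
  QUARTER_TMD = "TMD",
  ABC2_NBD_NBD = c("NBD", "NBD"),
  TMD_TMD = c("TMD", "TMD"),
  UNIQUE = c("NBD", "TMD", "NBD"))

#' Simulate a proteome with planted domain architectures
#'
#' Generates proteins whose domain-hit table encodes a chosen topology
#' class per protein (NBD segments 160 aa, TMD segments 110 aa, 25-aa
#' linkers), plus NBD-free decoys (alternating between TMD-only hits and
#' no hits at all). Hit E-values are log-uniform on [1e-50, 1e-10]. Gene
#' models are placed non-overlapping on two synthetic chromosomes,
#' alternating strands. Deterministic under a fixed seed.
#'
#' @param class_counts Named integer vector of planted topology classes,
#'   e.g. `c(FULL_FORWARD = 3, HALF_REVERSE = 5)`; the `UNIQUE` template
#'   is NBD-TMD-NBD.
#' @param decoys Number of NBD-free decoy proteins.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, writes `proteins.fasta`,
#'   `domains.domtbl`, `genes.gff3` and `truth.tsv`.
#' @return List: `proteins` (sequence table), `domtbl` (domain-table
#'   text), `genes` (gene models), `truth`
#'   (`data.frame(protein_id, class, is_decoy)`).
#' @export
gen_proteome <- function(class_counts, decoys = 0, seed = 1, out_dir = NULL) {
  stopifnot(all(names(class_counts) %in% names(.CLASS_TEMPLATES)),
            all(class_counts >= 0), decoys >= 0)
  set.seed(seed)
  seg_len <- c(NBD = 160L, TMD = 110L)
  linker <- 25L
  plan <- rep(names(class_counts), class_counts)
  n_all <- length(plan) + decoys
  ids <- sprintf("SYN%03d", seq_len(n_all))
  prot_rows <- list(); hit_lines <- character(0); truth <- list()
  make_protein <- function(id, domains, record_hits = TRUE) {
    pos <- 30L  # N-terminal leader
    segs <- .random_aa(pos)
    for (d in domains) {
      a1 <- pos + 1L
      a2 <- pos + seg_len[[d]]
      segs <- paste0(segs, .random_aa(seg_len[[d]]))
      pos <- a2
      if (record_hits) {
        acc <- if (d == "TMD") "PF00664" else
          if (length(domains) == 2 && all(domains == "NBD")) "PF01061" else
          "PF00005"
        ev <- 10^stats::runif(1, -50, -10)
        hit_lines <<- c(hit_lines, sprintf("%s\t%s\t%.3e\t%d\t%d",
                                           id, acc, ev, a1, a2))
      }
      segs <- paste0(segs, .random_aa(linker))
      pos <- pos + linker
    }
    segs
  }
  for (i in seq_along(plan)) {
    prot_rows[[i]] <- data.frame(
      id = ids[i], desc = plan[i],
      seq = make_protein(ids[i], .CLASS_TEMPLATES[[plan[i]]]),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(protein_id = ids[i], class = plan[i],
                             is_decoy = FALSE, stringsAsFactors = FALSE)
  }
  for (k in seq_len(decoys)) {
    i <- length(plan) + k
    with_tmd_hit <- k %% 2 == 1
    prot_rows[[i]] <- data.frame(
      id = ids[i], desc = "decoy",
      seq = make_protein(ids[i], "TMD", record_hits = with_tmd_hit),
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(protein_id = ids[i], class = NA_character_,
                             is_decoy = TRUE, stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, prot_rows)
  truth <- do.call(rbind, truth)
  # non-overlapping gene models on two chromosomes, both strands
  cursor <- c(chr1 = 10000L, chr2 = 10000L)
  genes <- list()
  for (i in seq_len(n_all)) {
    chrom <- if (i %% 2 == 1) "chr1" else "chr2"
    len_nt <- 3L * nchar(proteins$seq[i])
    genes[[i]] <- data.frame(gene_id = ids[i], seq_id = chrom,
                             start = cursor[[chrom]],
                             end = cursor[[chrom]] + len_nt - 1L,
                             strand = if (i %% 4 %in% c(0, 1)) "+" else "-",
                             stringsAsFactors = FALSE)
    cursor[[chrom]] <- cursor[[chrom]] + len_nt + 5000L
  }
  genes <- do.call(rbind, genes)
  domtbl <- paste(hit_lines, collapse = "\n")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(out_dir, "proteins.fasta"))
    writeLines(hit_lines, file.path(out_dir, "domains.domtbl"))
    write_gff3(genes, file.path(out_dir, "genes.gff3"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(proteins = proteins, domtbl = domtbl, genes = genes, truth = truth)
}

#' Simulate a pair of coding sequences diverged at controlled omega and Ks
#'
#' Draws a random ancestor of sense codons and evolves it independently
#' along two branches by single-base codon substitutions: proposals that
#' create stop codons are rejected, synonymous changes are accepted with
#' relative rate 1 and non-synonymous with relative rate `omega_true`,
#' and each branch accumulates synonymous events until the realized
#' count reaches `ks_true / 2` per synonymous site of the ancestor.
#'
#' @param n_codons Number of codons (>= 50).
#' @param omega_true True Ka/Ks of the substitution process.
#' @param ks_true Target synonymous substitutions per synonymous site
#'   (total between the two tips).
#' @param seed Integer seed.
#' @return List: `cds` (two-row sequence table `a`, `b`), `ancestor`,
#'   `omega_true`, `ks_true`, `syn_events`, `nonsyn_events` (per-branch
#'   realized counts).
#' @export
gen_diverged_pair <- function(n_codons = 500, omega_true = 1, ks_true = 0.2,
                              seed = 1) {
  stopifnot(n_codons >= 50, omega_true >= 0, ks_true >= 0)
  if (ks_true >= 2) stop("ks_true too large: synonymous sites would saturate")
  set.seed(seed)
  gc_map <- Biostrings::GENETIC_CODE
  sense <- setdiff(names(gc_map), STOP_CODONS)
  tabs <- .codon_tables()
  anc <- sample(sense, n_codons, replace = TRUE)
  target_syn <- ks_true / 2 * sum(tabs$syn_sites[anc])
  p_syn <- min(1, if (omega_true > 0) 1 / omega_true else 1)
  p_non <- min(1, omega_true)
  evolve <- function(cod) {
    syn <- 0; non <- 0
    max_iter <- 10000 + 2000 * ceiling(target_syn)
    iter <- 0
    while (syn < target_syn && iter < max_iter) {
      iter <- iter + 1
      ci <- sample.int(n_codons, 1)
      p <- sample.int(3, 1)
      old <- cod[ci]
      b <- sample(setdiff(DNA4, substr(old, p, p)), 1)
      new <- old
      substr(new, p, p) <- b
      if (new %in% STOP_CODONS) next
      if (gc_map[[new]] == gc_map[[old]]) {
        if (stats::runif(1) < p_syn) { cod[ci] <- new; syn <- syn + 1 }
      } else {
        if (stats::runif(1) < p_non) { cod[ci] <- new; non <- non + 1 }
      }
    }
    if (syn < target_syn) stop("could not reach the requested Ks (saturation)")
    list(cod = cod, syn = syn, non = non)
  }
  ba <- evolve(anc); bb <- evolve(anc)
  cds <- data.frame(id = c("a", "b"), desc = "",
                    seq = c(paste(ba$cod, collapse = ""),
                            paste(bb$cod, collapse = "")),
                    stringsAsFactors = FALSE)
  list(cds = cds, ancestor = paste(anc, collapse = ""),
       omega_true = omega_true, ks_true = ks_true,
       syn_events = c(ba$syn, bb$syn), nonsyn_events = c(ba$non, bb$non))
}

# Resample windows of `seq` until no catalog motif matches on either
# strand; errors after `max_iter` repair steps.
.motif_free_background <- function(len, catalog, max_iter = 5000) {
  seq <- .random_dna(len)
  tab <- data.frame(id = "bg", desc = "", seq = seq, stringsAsFactors = FALSE)
  for (iter in seq_len(max_iter)) {
    hits <- scan_promoters(tab, catalog, "both")
    if (nrow(hits) == 0) return(tab$seq)
    for (r in seq_len(nrow(hits))) {
      w <- nchar(hits$match[r])
      substr(tab$seq, hits$start[r], hits$start[r] + w - 1L) <- .random_dna(w)
    }
  }
  stop("failed to build a motif-free background; try a longer sequence ",
       "or a smaller catalog")
}

#' Simulate promoters with planted motif instances
#'
#' Backgrounds are uniform random DNA rejection-filtered (by local window
#' resampling) until they contain no catalog match on either strand.
#' Planted signals are instantiated uniformly over their IUPAC expansions,
#' placed one per block at random offsets (non-overlapping), on random
#' strands, with positions and strands recorded in the truth table.
#'
#' @param n Number of promoters.
#' @param length Promoter length in bp (default 1500).
#' @param catalog Motif catalog (default [cis_element_catalog()]).
#' @param plant `"all"` (every catalog motif once per promoter),
#'   `"none"`, or a character vector of motif names.
#' @param seed Integer seed.
#' @return List: `promoters` (sequence table), `truth`
#'   (`data.frame(promoter, motif, start, strand, instance)`).
#' @export
gen_promoters <- function(n, length = 1500, catalog = cis_element_catalog(),
                          plant = "all", seed = 1) {
  set.seed(seed)
  plant_names <- if (identical(plant, "all")) catalog$name
                 else if (identical(plant, "none")) character(0)
                 else plant
  stopifnot(all(plant_names %in% catalog$name))
  if (length(plant_names) > 0) {
    block <- length %/% length(plant_names)
    if (block < max(nchar(catalog$signal)) + 1) {
      stop("planted motifs do not fit in the promoter length")
    }
  }
  ids <- sprintf("prom%02d", seq_len(n))
  rows <- list(); truth <- list()
  for (i in seq_len(n)) {
    seq <- .motif_free_background(length, catalog)
    for (k in seq_along(plant_names)) {
      sig <- catalog$signal[catalog$name == plant_names[k]]
      inst <- paste(vapply(strsplit(toupper(sig), "")[[1]], function(ch) {
        sample(setdiff(IUPAC_EXPANSION[[ch]], "N"), 1)
      }, character(1)), collapse = "")
      w <- nchar(inst)
      off <- sample.int(block - w + 1L, 1)
      pos <- (k - 1L) * block + off
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") inst else .revcomp(inst)
      substr(seq, pos, pos + w - 1L) <- ins
      truth[[length(truth) + 1]] <- data.frame(
        promoter = ids[i], motif = plant_names[k], start = pos,
        strand = strand, instance = inst, stringsAsFactors = FALSE)
    }
    rows[[i]] <- data.frame(id = ids[i], desc = "synthetic promoter",
                            seq = seq, stringsAsFactors = FALSE)
  }
  list(promoters = do.call(rbind, rows),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(promoter = character(), motif = character(),
                    start = integer(), strand = character(),
                    instance = character(), stringsAsFactors = FALSE))
}

#' Simulate a read-count matrix from a known RPKM truth
#'
#' Deterministic mode rounds `rpkm * N * L / 1e9` to integers, so
#' [rpkm()] recovers the truth within rounding; noisy mode draws Poisson
#' counts around the same means.
#'
#' @param rpkm_truth Target RPKM matrix (genes x samples).
#' @param library_size Reads per sample (length = ncol).
#' @param gene_length Gene length in bp (length = nrow).
#' @param noisy Poisson sampling instead of rounding.
#' @param seed Integer seed (used in noisy mode).
#' @return Integer count matrix with the input dimnames.
#' @export
gen_counts <- function(rpkm_truth, library_size, gene_length, noisy = FALSE,
                       seed = 1) {
  rpkm_truth <- as.matrix(rpkm_truth)
  stopifnot(all(rpkm_truth >= 0),
            length(library_size) == ncol(rpkm_truth),
            length(gene_length) == nrow(rpkm_truth))
  mu <- t(t(rpkm_truth * gene_length) * library_size) / 1e9
  if (noisy) {
    set.seed(seed)
    counts <- matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
  } else {
    counts <- round(mu)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- dimnames(rpkm_truth)
  counts
}
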