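#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of mismatching sites per pair, with pairwise deletion of
#' columns containing a gap in either sequence.
#'
#' @param msa Aligned sequence table (all sequences equal length, >= 3).
#' @return Symmetric numeric matrix with taxa ids as dimnames.
#' @export
p_distance_matrix <- function(msa) {
  if (nrow(msa) < 3) stop("need at least 3 taxa")
  if (length(unique(nchar(msa$seq))) != 1) {
    stop("alignment rows differ in length")
  }
  chars <- lapply(msa$seq, function(s) strsplit(s, "")[[1]])
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- chars[[i]] != "-" & chars[[j]] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", msa$id[i], "' and '",
             msa$id[j], "'")
      }
      d[i, j] <- d[j, i] <- sum(chars[[i]][ok] != chars[[j]][ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with a deterministic tie-break (on equal Q the
#' pair with the smallest row-then-column index is joined) and negative
#' branch lengths clamped to zero (recorded in the `clamped` attribute).
#' The last three lineages are joined by the closed form
#' `v_a = (d_ab + d_ac - d_bc) / 2`, giving the usual unrooted tree with a
#' basal trifurcation.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An [ape::read.tree()]-style `phylo` object (attribute
#'   `clamped`: number of negative branch lengths clamped to 0).
#' @export
neighbor_joining <- function(dm) {
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12))) {
    stop("distance matrix is not symmetric")
  }
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  n <- nrow(dm)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frags <- labels  # newick fragment per active node
  D <- dm
  clamped <- 0L
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { clamped <- clamped + 1L; vi <- 0 }
    if (vj < 0) { clamped <- clamped + 1L; vj <- 0 }
    newfrag <- paste0("(", frags[i], ":", fmt(vi), ",",
                      frags[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (v in c(v1, v2, v3)) if (v < 0) clamped <- clamped + 1L
  v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0)
  nwk <- paste0("(", frags[1], ":", fmt(v1), ",", frags[2], ":", fmt(v2),
                ",", frags[3], ":", fmt(v3), ");")
  phy <- ape::read.tree(text = nwk)
  attr(phy, "clamped") <- clamped
  phy
}

# Canonical non-trivial bipartitions of an unrooted tree, as strings.
# Each internal edge splits the taxa; the side not containing the
# alphabetically first taxon is the key.
.bipartitions <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4) return(character(0))
  pp <- ape::prop.part(phy)
  all_tips <- sort(phy$tip.label)
  anchor <- all_tips[1]
  keys <- vapply(pp, function(idx) {
    side <- sort(phy$tip.label[idx])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2 || length(side) > nt - 2) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and reports for each internal bipartition of
#' the point-estimate tree the percentage of replicates containing it.
#' Supports are attached as internal node labels. Reproducible under a
#' fixed seed.
#'
#' @param msa Aligned sequence table.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @param dist_fun Distance function (default [p_distance_matrix()]).
#' @return List: `tree` (phylo with node labels = supports),
#'   `supports` (named numeric, percent in [0, 100] per bipartition).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              dist_fun = p_distance_matrix) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  point <- neighbor_joining(dist_fun(msa))
  bips <- .bipartitions(point)
  counts <- setNames(numeric(length(bips)), bips)
  ncol_aln <- nchar(msa$seq[1])
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    boot <- msa
    boot$seq <- vapply(msa$seq, function(s) {
      paste(strsplit(s, "")[[1]][idx], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    rep_bips <- .bipartitions(neighbor_joining(dist_fun(boot)))
    hit <- bips %in% rep_bips
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_reps
  # attach as node labels on the point tree
  nt <- length(point$tip.label)
  n_internal <- point$Nnode
  labs <- rep("", n_internal)
  pp <- ape::prop.part(point)
  all_tips <- sort(point$tip.label)
  anchor <- all_tips[1]
  for (k in seq_along(pp)) {
    side <- sort(point$tip.label[pp[[k]]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    key <- paste(side, collapse = "|")
    if (key %in% names(supports)) labs[k] <- sprintf("%g", supports[[key]])
  }
  point$node.label <- labs
  list(tree = point, supports = supports)
}

#' Write a tree as Newick with supports as internal node labels
#' @param tree A `phylo` object.
#' @param path Output path or `NULL` to return the string.
#' @param digits Branch-length precision (default 6 decimals).
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
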