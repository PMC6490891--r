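test_that("RPKM closed form, zeros and scale invariance", {
  counts <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  r <- rpkm(counts, gene_length = c(1000, 500), library_size = 1e6)
  expect_equal(r["g1", "s1"], 10)
  expect_equal(r["g2", "s1"], 0)

  set.seed(61)
  C <- matrix(rpois(12, 50), 4, 3)
  L <- c(500, 1000, 1500, 2000)
  N <- c(2e6, 1e6, 5e6)
  expect_equal(rpkm(2 * C, L, 2 * N), rpkm(C, L, N))
  expect_equal(rpkm(3 * C, L, N), 3 * rpkm(C, L, N))  # linear in counts
  expect_error(rpkm(C, L, c(0, 1e6, 1e6)), "library size is zero")
  expect_error(rpkm(C, L[1:2], N), "one entry per gene")
})

test_that("heatmap matrix transforms, orders deterministically and puts
           identical rows adjacent", {
  expr <- rbind(a = c(0, 3), b = c(100, 1), c = c(0, 3))
  colnames(expr) <- c("s1", "s2")
  hm <- heatmap_matrix(expr)
  expect_equal(hm$matrix[, 1][rownames(hm$matrix) == "a"], log2(1),
               ignore_attr = TRUE)
  ra <- which(rownames(hm$matrix) == "a")
  rc <- which(rownames(hm$matrix) == "c")
  expect_equal(abs(ra - rc), 1)  # identical rows adjacent
  hm2 <- heatmap_matrix(expr)
  expect_identical(hm$row_order, hm2$row_order)

  single <- heatmap_matrix(matrix(5, 1, 2, dimnames = list("g", c("a", "b"))))
  expect_equal(single$row_order, 1L)
  expect_error(heatmap_matrix(matrix(numeric(0), 0, 2)), "empty")
})

test_that("expression sets partition genes by group membership", {
  expr <- rbind(g_all = c(5, 5, 5, 5), g_none = c(0, 0, 0, 0),
                g_pla = c(3, 0.2, 0, 0), g_mix = c(2, 0, 0, 9))
  colnames(expr) <- c("pl1", "pl2", "pe1", "pe2")
  groups <- c(pl1 = "placenta", pl2 = "placenta",
              pe1 = "pericarp", pe2 = "pericarp")
  sets <- expression_sets(expr, groups, threshold = 1)
  expect_equal(sets[["pericarp&placenta"]], c("g_all", "g_mix"))
  expect_equal(sets[["placenta"]], "g_pla")
  expect_false("g_none" %in% unlist(sets))
  # regions are disjoint
  expect_equal(anyDuplicated(unlist(sets)), 0)
  expect_error(expression_sets(expr, c(bad = "g1", pl1 = "g2")),
               "unknown sample")
  all_zero <- expression_sets(expr * 0, groups)
  expect_equal(length(all_zero), 0)
})

test_that("planted expression memberships are recovered at threshold 1", {
  set.seed(62)
  n_genes <- 20
  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "C")
  truth_regions <- sample(c("A", "B", "C", "A&B", "A&C", "B&C", "A&B&C"),
                          n_genes, replace = TRUE)
  X <- matrix(0, n_genes, 4,
              dimnames = list(sprintf("g%02d", 1:n_genes), names(groups)))
  for (i in seq_len(n_genes)) {
    for (g in strsplit(truth_regions[i], "&", fixed = TRUE)[[1]]) {
      cols <- names(groups)[groups == g]
      X[i, sample(cols, 1)] <- runif(1, 1, 50)
    }
  }
  counts <- gen_counts(X, library_size = rep(2e7, 4),
                       gene_length = rep(1000, n_genes))
  sets <- expression_sets(rpkm(counts, rep(1000, n_genes), rep(2e7, 4)),
                          groups)
  got <- unlist(lapply(names(sets), function(r)
    setNames(rep(r, length(sets[[r]])), sets[[r]])))
  expect_equal(got[rownames(X)], setNames(truth_regions, rownames(X)))
})

test_that("ortholog matching is reciprocal-best-hit at inclusive 98/70", {
  set.seed(63)
  base <- random_dna(500)
  mutate_pct <- function(s, pct) {
    n <- round(nchar(s) * pct / 100)
    pos <- sample(nchar(s), n)
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  a <- seq_table(c("ca1", "ca2"), c(base, random_dna(500)))
  b <- seq_table(c("cc1", "cc2", "cc3"),
                 c(mutate_pct(base, 1), mutate_pct(base, 3), random_dna(500)))
  m <- match_orthologs(a, b)
  # ca1 pairs with cc1 (99% identity); cc2 at 97% fails the cutoff
  expect_equal(m$id_a, "ca1")
  expect_equal(m$id_b, "cc1")
  expect_gte(m$identity_pct, 98)

  ident <- match_orthologs(seq_table("x", base), seq_table("y", base))
  expect_equal(ident$identity_pct, 100)
  expect_equal(ident$coverage_pct, 100)
})

test_that("high-identity pairs sharing too little sequence fail coverage", {
  set.seed(64)
  shared <- random_dna(300)
  # the shorter sequence carries 200 bases absent from the longer one, so
  # at most ~300 of its 500 bases can sit in aligned columns (~60%)
  a <- seq_table("a1", paste0(random_dna(200), shared))
  b <- seq_table("b1", paste0(shared, random_dna(600)))
  aln <- global_align(a, b, align_params("DNA"))
  expect_lt(aln$coverage_pct, 70)
  expect_gte(aln$identity_pct, 98)
  expect_equal(nrow(match_orthologs(a, b)), 0)
})

test_that("ddCt worked examples and monotonicity", {
  same <- ddct(c(20, 20, 20), c(18, 18, 18), c(20, 20, 20), c(18, 18, 18))
  expect_equal(same$fold, 1)
  up <- ddct(c(20, 20, 20), c(18, 18, 18), c(21, 21, 21), c(18, 18, 18))
  expect_equal(up$fold, 2)        # ddCt = -1 -> one-cycle doubling
  expect_equal(up$sd_dct, 0)
  # fold is strictly decreasing in target Ct
  folds <- vapply(c(19, 20, 21), function(ct)
    ddct(rep(ct, 3), c(18, 18, 18), c(21, 21, 21), c(18, 18, 18))$fold,
    numeric(1))
  expect_true(all(diff(folds) < 0))
  expect_true(all(folds > 0))
  expect_error(ddct(numeric(0), 1, 1, 1), "missing Ct")
  expect_error(ddct(c(50, 50), c(18, 18), c(20, 20), c(18, 18)), "0, 45")
})

test_that("ddct_table normalizes against the reference and calibrator", {
  ct <- rbind(
    data.frame(sample = "dpa6", gene = "CaABCG28", ct = c(24, 24.2, 23.8)),
    data.frame(sample = "dpa6", gene = "beta_tubulin", ct = c(20, 20, 20)),
    data.frame(sample = "dpa16", gene = "CaABCG28", ct = c(22, 22, 22)),
    data.frame(sample = "dpa16", gene = "beta_tubulin", ct = c(20, 20, 20)))
  out <- ddct_table(ct, reference = "beta_tubulin", calibrator = "dpa6")
  expect_equal(out$fold[out$sample == "dpa6"], 1)
  expect_equal(out$fold[out$sample == "dpa16"], 2^(4 - 2))
  expect_error(ddct_table(ct, reference = "actin", calibrator = "dpa6"),
               "reference gene")
  expect_error(ddct_table(ct, reference = "beta_tubulin", calibrator = "x"),
               "calibrator")
})
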