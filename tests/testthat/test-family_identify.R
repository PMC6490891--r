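make_hit <- function(id, dom = "NBD", ev = 1e-10, a1 = 10, a2 = 170) {
  data.frame(protein_id = id, domain_name = dom, evalue = ev,
             ali_start = a1, ali_end = a2, stringsAsFactors = FALSE)
}

test_that("filter_candidates applies the E-value rule with the boundary kept", {
  prots <- seq_table(c("p1", "p2", "p3"),
                     c(strrep("MKV", 50), strrep("MLA", 50), strrep("MVV", 50)))
  hits <- rbind(make_hit("p1", ev = 1e-6),
                make_hit("p2", ev = 1e-4),    # fails: E > 1e-5
                make_hit("p3", ev = 1e-5))    # boundary: kept
  out <- filter_candidates(hits, prots)
  expect_equal(out$protein_id, c("p1", "p3"))
})

test_that("TMD-only proteins are not family candidates", {
  prots <- seq_table("p1", strrep("MKV", 40))
  out <- filter_candidates(make_hit("p1", dom = "TMD"), prots)
  expect_equal(nrow(out), 0)
})

test_that("redundant entries collapse to one survivor", {
  s <- strrep("MKVA", 40)
  prots <- seq_table(c("pB", "pA"), c(s, s))      # identical sequences
  out <- filter_candidates(rbind(make_hit("pA"), make_hit("pB")), prots)
  expect_equal(out$protein_id, "pA")              # smallest id survives

  prots2 <- seq_table(c("loc1.1", "loc1.2"), c(s, paste0(s, "KKKK")))
  out2 <- filter_candidates(rbind(make_hit("loc1.1"), make_hit("loc1.2")),
                            prots2)
  expect_equal(out2$protein_id, "loc1.2")         # longest isoform survives
})

test_that("filter_candidates errors on hits without a FASTA record", {
  prots <- seq_table("p1", strrep("MKV", 40))
  expect_error(filter_candidates(make_hit("ghost"), prots), "ghost")
})

test_that("candidate output is invariant to input order", {
  set.seed(21)
  prots <- seq_table(sprintf("p%02d", 1:8),
                     vapply(rep(120, 8), function(n)
                       paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                    n, replace = TRUE), collapse = ""),
                       character(1)))
  hits <- do.call(rbind, lapply(prots$id, make_hit))
  a <- filter_candidates(hits, prots)
  perm <- sample(nrow(hits))
  b <- filter_candidates(hits[perm, ], prots[sample(nrow(prots)), ])
  expect_equal(a, b)
})

test_that("exactly the planted NBD-bearing proteins survive filtering", {
  sim <- gen_proteome(c(FULL_FORWARD = 4, HALF_REVERSE = 3, QUARTER_NBD = 2),
                      decoys = 5, seed = 17)
  hits <- parse_domtblout(sim$domtbl)
  out <- filter_candidates(hits, sim$proteins)
  planted <- sim$truth$protein_id[!sim$truth$is_decoy]
  expect_setequal(out$protein_id, planted)
})

test_that("assign_subfamily: identity wins, ties break to smallest ref id", {
  set.seed(5)
  refs <- seq_table(c("AT_G1", "AT_B1", "AT_C1"),
                    vapply(rep(150, 3), function(n)
                      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                   n, replace = TRUE), collapse = ""),
                      character(1)))
  refs$subfamily <- c("G", "B", "C")
  hit <- assign_subfamily(refs$seq[1], refs)
  expect_equal(hit$subfamily, "G")

  # two identical references under different labels: smaller id wins
  refs2 <- seq_table(c("ref_b", "ref_a"), rep(refs$seq[1], 2))
  refs2$subfamily <- c("B", "C")
  tie <- assign_subfamily(refs$seq[1], refs2)
  expect_equal(tie$ref_id, "ref_a")
  expect_equal(tie$subfamily, "C")

  expect_error(assign_subfamily("", refs), "empty query")
})

test_that("assign_subfamily recovers planted labels for mutated queries", {
  set.seed(33)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  refs <- seq_table(sprintf("AT_%s1", c("A", "B", "C", "G")),
                    vapply(rep(200, 4), function(n)
                      paste(sample(aa, n, replace = TRUE), collapse = ""),
                      character(1)))
  refs$subfamily <- c("A", "B", "C", "G")
  n_queries <- 200
  correct <- 0
  for (k in seq_len(n_queries)) {
    pick <- sample(4, 1)
    q <- strsplit(refs$seq[pick], "")[[1]]
    n_mut <- round(length(q) * stats::runif(1, 0, 0.10))
    pos <- sample(length(q), n_mut)
    q[pos] <- sample(aa, n_mut, replace = TRUE)
    res <- assign_subfamily(paste(q, collapse = ""), refs)
    if (res$subfamily == refs$subfamily[pick]) correct <- correct + 1
  }
  expect_gte(correct / n_queries, 0.95)
})

test_that("assign_names numbers members positionally within subfamilies", {
  members <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                        subfamily = c("G", "G", "G", "E"),
                        stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = c("p1", "p2", "p3", "p4"),
                   seq_id = c("chr1", "chr1", "scaffold_12", "chr2"),
                   start = c(500L, 100L, 50L, 1L),
                   end = c(600L, 200L, 90L, 30L),
                   strand = "+", stringsAsFactors = FALSE)
  out <- assign_names(members, gm, "Ca")
  sym <- setNames(out$symbol, out$protein_id)
  expect_equal(sym[["p2"]], "CaABCG1")   # chr1:100 before chr1:500
  expect_equal(sym[["p1"]], "CaABCG2")
  expect_equal(sym[["p3"]], "CaABCG3")   # scaffold after chromosomes
  expect_equal(sym[["p4"]], "CaABCE1")   # lone member gets index 1
})

test_that("assign_names breaks coordinate ties by protein id and warns on
           members without models", {
  members <- data.frame(protein_id = c("pB", "pA", "pZ"),
                        subfamily = "B", stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = c("pA", "pB"), seq_id = "chr1",
                   start = c(100L, 100L), end = c(200L, 200L),
                   strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- assign_names(members, gm, "Cb"), "without a gene model")
  sym <- setNames(out$symbol, out$protein_id)
  expect_equal(sym[["pA"]], "CbABCB1")
  expect_equal(sym[["pB"]], "CbABCB2")
  expect_equal(sym[["pZ"]], "CbABCB3")
})
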