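test_that("the packaged catalog has the expected shape", {
  cat23 <- cis_element_catalog()
  expect_equal(nrow(cat23), 23)
  expect_true(all(grepl("^[ACGTRYSWKMBDHVN]+$", cat23$signal)))
  expect_equal(sum(grepl("auxin", cat23$annotation)), 4)
  expect_false(any(duplicated(cat23$name)))
})

test_that("compile_iupac expands degenerate letters and rejects others", {
  m <- compile_iupac("GRWAAW")
  expect_equal(m$length, 6)
  expect_equal(oracle_scan_strand("GGTAAA", "GRWAAW"), 1)
  expect_equal(length(scan_promoters(seq_table("x", "GGTAAA"),
                                     data.frame(name = "m", signal = "GRWAAW"),
                                     strands = "+")$start), 1)
  # literal patterns match only themselves
  lit <- scan_promoters(seq_table("x", "CAATCCAT"),
                        data.frame(name = "m", signal = "CAAT"),
                        strands = "+")
  expect_equal(lit$start, 1)
  # pattern N matches any base, including an N in the sequence
  expect_equal(nrow(scan_promoters(seq_table("x", "ANC"),
                                   data.frame(name = "m", signal = "ANA"),
                                   strands = "+")), 0)
  nhit <- scan_promoters(seq_table("x", "ANA"),
                         data.frame(name = "m", signal = "ANA"),
                         strands = "+")
  expect_equal(nhit$start, 1)
  # sequence N is not matched by a concrete pattern letter
  expect_equal(nrow(scan_promoters(seq_table("x", "CANT"),
                                   data.frame(name = "m", signal = "CAAT"),
                                   strands = "+")), 0)
  expect_error(compile_iupac("ACGU"), "illegal IUPAC character 'U'")
})

test_that("single-occurrence and reverse-strand examples behave", {
  h <- scan_promoters(seq_table("p1", "GGCAATGG"),
                      data.frame(name = "CAATBOX1", signal = "CAAT"),
                      strands = "+")
  expect_equal(h$start, 3)
  expect_equal(h$strand, "+")
  expect_equal(h$match, "CAAT")

  h2 <- scan_promoters(seq_table("p1", "ACGTCAT"),
                       data.frame(name = "ASF1", signal = "TGACG"),
                       strands = "both")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 2)
  expect_equal(h2$match, "CGTCA")
})

test_that("overlapping and self-overlapping matches are all reported", {
  h <- scan_promoters(seq_table("p", "AAAA"),
                      data.frame(name = "m", signal = "AA"), strands = "+")
  expect_equal(h$start, 1:3)
})

test_that("the scanner equals the naive oracle on random sequences", {
  set.seed(51)
  cat23 <- cis_element_catalog()
  for (k in 1:60) {
    s <- random_dna(200)
    mine <- scan_promoters(seq_table("r", s), cat23, strands = "both")
    orc <- oracle_scan("r", s, cat23)
    mine <- mine[order(mine$start, mine$motif, mine$strand),
                 c("promoter", "motif", "start", "strand")]
    rownames(mine) <- rownames(orc) <- NULL
    expect_equal(mine, orc)
  }
})

test_that("strand symmetry: hits map onto the reverse complement", {
  set.seed(52)
  cat23 <- cis_element_catalog()
  for (k in 1:10) {
    s <- random_dna(150)
    rc <- oracle_revcomp(s)
    fw <- scan_promoters(seq_table("p", s), cat23, strands = "+")
    rv <- scan_promoters(seq_table("p", rc), cat23, strands = "-")
    # a + hit at i with width w corresponds to a - hit at L - i - w + 2
    w <- nchar(fw$match)
    mapped <- sort(nchar(s) - fw$start - w + 2)
    expect_equal(sort(rv$start), mapped)
  }
})

test_that("planted motifs are all recovered and backgrounds are clean", {
  gp <- gen_promoters(2, length = 1200, seed = 53)
  hits <- scan_promoters(gp$promoters)
  found <- merge(gp$truth, hits,
                 by = c("promoter", "motif", "start", "strand"))
  expect_equal(nrow(found), nrow(gp$truth))  # 100% recall at exact site
  expect_equal(sort(unique(hits$motif)), sort(cis_element_catalog()$name))

  bg <- gen_promoters(2, length = 400, plant = "none", seed = 54)
  expect_equal(nrow(scan_promoters(bg$promoters)), 0)
})

test_that("common_elements intersects presence across promoters", {
  hits <- data.frame(promoter = c("p1", "p2", "p3", "p1", "p2"),
                     motif = c("CAATBOX1", "CAATBOX1", "CAATBOX1",
                               "ARFAT", "ARFAT"),
                     start = 1L, strand = "+", match = "x",
                     stringsAsFactors = FALSE)
  expect_equal(common_elements(hits, c("p1", "p2", "p3")), "CAATBOX1")
  expect_equal(common_elements(hits, c("p1", "p2")),
               c("ARFAT", "CAATBOX1"))
  # a promoter with no hits empties the intersection
  expect_equal(length(common_elements(hits, c("p1", "p4"))), 0)
  expect_error(common_elements(hits, character(0)), "empty")
})

test_that("promoter extraction: plus strand, truncation, minus strand
           round-trip", {
  genome <- seq_table("chr1", random_dna(4000))
  genes <- data.frame(gene_id = c("gplus", "gshort", "gminus"),
                      seq_id = "chr1",
                      start = c(2001L, 1001L, 100L),
                      end = c(2900L, 1900L, 1000L),
                      strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, genome, upstream_length = 1500)
  expect_equal(nchar(pr$seq[1]), 1500)
  expect_equal(pr$seq[1], substr(genome$seq, 501, 2000))
  expect_false(pr$truncated[1])
  # truncation at the contig edge
  expect_equal(nchar(pr$seq[2]), 1000)
  expect_true(pr$truncated[2])
  # minus strand: reverse complement of the downstream flank
  expect_equal(pr$seq[3], oracle_revcomp(substr(genome$seq, 1001, 2500)))
})

test_that("a planted upstream sequence round-trips through extraction on
           both strands", {
  set.seed(55)
  upstream <- random_dna(300)
  gene_body <- random_dna(600)
  tail_seq <- random_dna(100)
  plus_chr <- paste0(random_dna(50), upstream, gene_body, tail_seq)
  minus_chr <- paste0(tail_seq, oracle_revcomp(gene_body),
                      oracle_revcomp(upstream), random_dna(50))
  genome <- seq_table(c("cp", "cm"), c(plus_chr, minus_chr))
  genes <- data.frame(gene_id = c("gp", "gm"), seq_id = c("cp", "cm"),
                      start = c(351L, 101L), end = c(950L, 700L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  pr <- extract_promoters(genes, genome, upstream_length = 300)
  expect_equal(pr$seq[1], upstream)
  expect_equal(pr$seq[2], upstream)
})

test_that("extraction errors on absent contigs and zero upstream bases", {
  genome <- seq_table("chr1", random_dna(100))
  g <- data.frame(gene_id = "g", seq_id = "chrX", start = 10L, end = 20L,
                  strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_promoters(g, genome), "not found")
  g2 <- data.frame(gene_id = "g", seq_id = "chr1", start = 1L, end = 20L,
                   strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_promoters(g2, genome), "no upstream")
})
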