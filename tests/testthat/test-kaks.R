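test_that("site counts match hand-enumerated cases", {
  tt <- codon_site_counts("TTT")
  expect_equal(unname(tt), c(1 / 3, 8 / 3))
  # GGA: fourfold-degenerate third position contributes a full synonymous site
  gga <- codon_site_counts("GGA")
  expect_equal(unname(gga[["syn"]]), 1)
  expect_error(codon_site_counts("TAA"), "sense")
})

test_that("site counts agree with an independent brute-force enumerator", {
  skip_if_not_installed("seqinr")
  code <- mito_genetic_code()
  bases <- c("A", "C", "G", "T")
  oracle <- function(codon) {
    # independent path: seqinr translation, explicit neighbor enumeration
    aa0 <- seqinr::translate(strsplit(codon, "")[[1]], numcode = 2)
    s <- n <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- b
        aa1 <- seqinr::translate(strsplit(alt, "")[[1]], numcode = 2)
        if (aa1 == "*") next
        if (aa1 == aa0) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
    c(s, n)
  }
  for (codon in code$sense) {
    expect_equal(unname(codon_site_counts(codon)), oracle(codon),
                 info = codon)
  }
})

test_that("pairwise Ka/Ks behaves on constructed pairs", {
  cds <- paste0("ATG", strrep("GGA", 20), "TAA")
  same <- pairwise_kaks(cds, cds)
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ka_ks))
  # Jukes-Cantor closed form at pS = 0.05
  expect_equal(boulenophrys:::jc_correct(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(round(boulenophrys:::jc_correct(0.05), 4), 0.0517)
  expect_true(is.na(boulenophrys:::jc_correct(0.8)))
  # only fourfold third-position changes: Ka = 0, Ks > 0
  a <- paste(rep("GGA", 100), collapse = "")
  b <- paste(rep(c("GGC", "GGA"), 50), collapse = "")
  res <- pairwise_kaks(a, b)
  expect_equal(res$ka, 0)
  expect_gt(res$ks, 0)
  expect_equal(res$nonsyn_diffs, 0)
  expect_error(pairwise_kaks("ATGAAA", "ATG"), "lengths differ")
})

test_that("pairwise Ka/Ks is symmetric in its arguments", {
  set.seed(51)
  code <- mito_genetic_code()
  for (i in 1:5) {
    a <- paste(sample(code$sense, 50, TRUE), collapse = "")
    b <- paste(sample(code$sense, 50, TRUE), collapse = "")
    expect_equal(pairwise_kaks(a, b), pairwise_kaks(b, a))
  }
})

test_that("codons with gaps, N or stops are removed pairwise", {
  a <- "ATGAAACCC"
  b <- "ATGA-ACCC"
  res <- pairwise_kaks(a, b)
  expect_equal(res$n_codons, 2L)   # middle codon dropped
  res2 <- pairwise_kaks("ATGAANCCC", "ATGAAACCC")
  expect_equal(res2$n_codons, 2L)
})

test_that("gene_kaks aggregates pairs and ranks by constraint", {
  tbl <- dplyr::bind_rows(
    simulate_gene_alignment(150, 6, omega = 0.6, depth = 0.08, seed = 61),
    dplyr::mutate(simulate_gene_alignment(150, 6, omega = 0.05, depth = 0.08,
                                          seed = 62),
                  gene = "G2"))
  est <- gene_kaks(tbl)
  expect_identical(nrow(est), 2L)
  expect_identical(est$n_pairs, c(15L, 15L))
  expect_gt(est$ka_ks[est$gene == "G1"], est$ka_ks[est$gene == "G2"])
  expect_true(all(est$ka_ks < 1))
  # mean-of-ratios alternative stays defined and positively correlated
  est2 <- gene_kaks(tbl, method = "mean_ratios")
  expect_gt(est2$ka_ks[1], est2$ka_ks[2])
  expect_error(gene_kaks(tbl[tbl$taxon == "t1", ]), "fewer than 2")
})
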