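test_that("concatenation records widths and pads missing taxa", {
  dat <- fx_quartet()
  cds <- pcg_cds_table(dat$genomes)
  block <- concatenate_pcgs(cds)
  widths <- tapply(nchar(cds$cds), cds$gene, unique)
  expect_equal(block$n_sites, sum(widths))
  expect_equal(nrow(block$partitions), 13L)
  expect_equal(block$partitions$end - block$partitions$start + 1L,
               as.integer(widths[block$partitions$gene]))
  # drop one taxon's second gene -> gap padding over those columns
  g2 <- block$partitions$gene[2]
  cds_miss <- cds[!(cds$taxon == "A" & cds$gene == g2), ]
  block2 <- concatenate_pcgs(cds_miss)
  pr <- block2$partitions[block2$partitions$gene == g2, ]
  seg <- substr(block2$seqs[["A"]], pr$start, pr$end)
  expect_identical(unique(strsplit(seg, "")[[1]]), "-")
  expect_match(attr(block2, "padded"), paste0("A:", g2))
  expect_error(concatenate_pcgs(dplyr::bind_rows(cds, cds[1, ])), "duplicate")
})

test_that("distance models match their closed forms", {
  expect_equal(unname(distance_matrix(
    alignment_block(c(a = "ACGTACGT", b = "ACGTACGT")), "p")["a", "b"]), 0)
  # p = 0.10: JC69 distance -(3/4) log(1 - 4p/3)
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  d <- distance_matrix(alignment_block(c(a = a, b = b)), "JC69")
  expect_equal(unname(d["a", "b"]), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(round(unname(d["a", "b"]), 4), 0.1073)
  # K2P with transitions only (P = 0.1, Q = 0): d = -log(1 - 2P)/2
  b2 <- paste0(strrep("G", 10), strrep("A", 90))   # A->G transitions
  d2 <- distance_matrix(alignment_block(c(a = a, b = b2)), "K2P")
  expect_equal(unname(d2["a", "b"]), -0.5 * log(1 - 0.2) - 0.25 * log(1),
               tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly", {
  # 4-taxon tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 5
  dm["A", "C"] <- dm["C", "A"] <- 7
  dm["A", "D"] <- dm["D", "A"] <- 8
  dm["B", "C"] <- dm["C", "B"] <- 8
  dm["B", "D"] <- dm["D", "B"] <- 9
  dm["C", "D"] <- dm["D", "C"] <- 9
  tr <- nj_tree(dm)
  truth <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):0);")
  expect_equal(robinson_foulds(tr, truth), 0L)
  # path lengths reproduce the input distances exactly
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm)
  # random additive matrices from random trees, property-style
  set.seed(71)
  for (i in 1:8) {
    rt <- ape::rtree(7 + i)
    dd <- ape::cophenetic.phylo(rt)
    expect_equal(robinson_foulds(nj_tree(dd), rt), 0L)
  }
})

test_that("three taxa give the closed three-point solution", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("negative NJ branches are clamped without losing path length", {
  dm <- matrix(c(0, 1, 6, 6,
                 1, 0, 6, 6,
                 6, 6, 0, 1,
                 6, 6, 1, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "C"] <- dm["C", "A"] <- 2   # wildly non-additive
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("saturated distances error unless imputation is requested", {
  dm <- matrix(c(0, NaN, 1, NaN, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(nj_tree(dm), "saturated")
  tr <- nj_tree(dm, impute_saturated = TRUE)
  expect_equal(ape::Ntip(tr), 3L)
})

test_that("bootstrap support is reproducible and sensible", {
  dat <- fx_quartet()
  block <- concatenate_pcgs(pcg_cds_table(dat$genomes))
  t1 <- bootstrap_tree(block, replicates = 25, seed = 9)
  t2 <- bootstrap_tree(block, replicates = 25, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # clean structured data: the single internal split is maximally supported
  expect_true(any(sup >= 95))
  expect_error(bootstrap_tree(block, replicates = 0), ">= 1")
})

test_that("bootstrap supports are invariant to taxon-order permutation", {
  dat <- fx_quartet()
  block <- concatenate_pcgs(pcg_cds_table(dat$genomes))
  perm <- alignment_block(block$seqs[rev(block$taxa)],
                          partitions = block$partitions)
  t1 <- bootstrap_tree(block, replicates = 20, seed = 5)
  t2 <- bootstrap_tree(perm, replicates = 20, seed = 5)
  expect_equal(robinson_foulds(t1, t2), 0L)
})

test_that("clade checks root on the outgroup and respect singletons", {
  tr <- megophryidae_tree()
  res <- check_clades(tr, list(
    omeimontis_group = c("Boulenophrys_sangzhiensis", "Boulenophrys_omeimontis",
                         "Boulenophrys_spinata"),
    boettgeri_group = c("Boulenophrys_tuberogranulata", "Boulenophrys_jinggangensis",
                        "Boulenophrys_boettgeri", "Boulenophrys_kuatunensis",
                        "Boulenophrys_baishanzuensis"),
    not_a_clade = c("Boulenophrys_sangzhiensis", "Microhyla_fissipes"),
    singleton = "Boulenophrys_spinata"),
    outgroup = "Microhyla_fissipes")
  expect_identical(res$monophyletic, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(check_clades(tr, list(x = "nobody"), "Microhyla_fissipes"),
               "unknown taxa")
  expect_error(check_clades(tr, list(x = "Boulenophrys_spinata"), "nobody"),
               "unknown outgroup")
})
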