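test_that("the default root realizes the study architecture", {
  g <- fx_root_bs()
  counts <- table(g$features$type)
  expect_equal(counts[["PCG"]], 13L)
  expect_equal(counts[["tRNA"]], 22L)
  expect_equal(counts[["rRNA"]], 2L)
  expect_equal(counts[["control"]], 1L)
  expect_equal(g$length, 16950L)
  expect_no_issues(validate_mitogenome(g, "strict"))
  expect_equal(glance(spacer_report(g)),
               tibble::tibble(overlap_bp_total = 38L, overlap_pairs = 13L,
                              ign_bp_total = 37L, ign_locations = 11L))
})

test_that("generated PCGs translate without internal stops", {
  for (g in list(fx_root_bs(), fx_root_bt())) {
    for (gene in g$features$name[g$features$type == "PCG"]) {
      aa <- translate_cds(extract_cds(g, gene))
      expect_length(attr(aa, "internal_stops"), 0L)
    }
  }
})

test_that("root composition tracks the target within two points", {
  g <- fx_root_bs()
  comp <- base_composition(g$sequence)
  target <- c(A = 27.45, C = 26.97, G = 14.81, T = 30.77)
  expect_lt(abs(comp$pct_a - target[["A"]]), 2)
  expect_lt(abs(comp$pct_t - target[["T"]]), 2)
  expect_lt(abs(comp$pct_g - target[["G"]]), 2)
  expect_lt(abs(comp$pct_c - target[["C"]]), 2)
  # heavy strand is T-biased and C-biased, as targeted
  expect_lt(comp$at_skew, 0)
  expect_lt(comp$gc_skew, 0)
})

test_that("generation and evolution are seed-deterministic", {
  spec <- sim_spec(seed = 77)
  expect_identical(generate_root(spec)$sequence, generate_root(spec)$sequence)
  expect_false(identical(generate_root(sim_spec(seed = 78))$sequence,
                         generate_root(spec)$sequence))
  tr <- ape::read.tree(text = "((A:0.03,B:0.03):0.01,(C:0.03,D:0.03):0.01);")
  spec2 <- sim_spec(tree = tr, seed = 77)
  root <- generate_root(spec2)
  d1 <- evolve_genomes(root, spec2)
  d2 <- evolve_genomes(root, spec2)
  expect_identical(d1$genomes$A$sequence, d2$genomes$A$sequence)
})

test_that("zero-length branches leave all leaves identical to the root", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  spec <- sim_spec(tree = tr, seed = 5)
  root <- generate_root(spec)
  dat <- evolve_genomes(root, spec)
  for (g in dat$genomes) expect_identical(g$sequence, root$sequence)
})

test_that("evolved leaves keep valid annotations and codon structure", {
  dat <- fx_quartet()
  tmpl <- dat$root$features[dat$root$features$type == "PCG", ]
  for (g in dat$genomes) {
    expect_no_issues(validate_mitogenome(g, "strict"))
    cl <- classify_pcgs(g)
    expect_identical(cl$start_codon, tmpl$start_codon)
    expect_identical(normalize_stop_codon(cl$stop_codon), tmpl$stop_codon)
  }
  # sequences actually diverged
  expect_false(identical(dat$genomes$A$sequence, dat$genomes$C$sequence))
})

test_that("selective constraint shapes divergence within genes", {
  # strong constraint (COI-like) vs weak (ATP8-like) on the same tree
  lo <- simulate_gene_alignment(300, 2, omega = 0.05, depth = 0.15, seed = 81)
  hi <- simulate_gene_alignment(300, 2, omega = 0.90, depth = 0.15, seed = 81)
  p_lo <- pairwise_kaks(lo$cds[1], lo$cds[2])
  p_hi <- pairwise_kaks(hi$cds[1], hi$cds[2])
  expect_lt(p_lo$pn, p_hi$pn)
})

test_that("an architecture whose codon requirements clash is rejected", {
  ft <- tibble::tibble(
    name = c("g1", "g2"), type = "PCG",
    start = c(1L, 10L), end = c(12L, 21L), strand = "H",
    start_codon = c("ATG", "ATG"), stop_codon = c("TAA", "TAA"),
    anticodon = NA_character_)
  # g1's stop (10..12 = TAA) collides with g2's start (10..12 = ATG)
  expect_error(generate_root(sim_spec(architecture = ft, seed = 1)),
               "infeasible")
})
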