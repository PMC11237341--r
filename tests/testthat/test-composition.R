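test_that("base composition equals independent letter counting", {
  row <- base_composition("AATT")
  expect_equal(row$pct_a, 50)
  expect_equal(row$pct_t, 50)
  expect_equal(row$pct_g, 0)
  expect_equal(row$pct_at, 100)
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE,
                    prob = c(0.3, 0.25, 0.15, 0.3)), collapse = "")
  row <- base_composition(s)
  counts <- table(strsplit(s, "")[[1]])   # independent counter
  expect_equal(row$pct_a, 100 * counts[["A"]] / 10000)
  expect_equal(row$pct_g, 100 * counts[["G"]] / 10000)
  expect_error(base_composition(""), "empty")
  expect_error(base_composition("NNNN"), "undefined")
})

test_that("skew formulas match their definition and boundary behavior", {
  expect_equal(unlist(skews("ACGTTGCA")), c(at_skew = 0, gc_skew = 0))
  gg <- skews("GGGG")
  expect_equal(gg$gc_skew, 1)
  expect_true(is.na(gg$at_skew))
  # printed whole-genome percentages reproduce the printed skews
  sk <- skew_from_counts(27.45, 30.77, 14.81, 26.97)
  expect_equal(round(sk$at_skew, 3), -0.057)
  expect_equal(round(sk$gc_skew, 3), -0.291)
})

test_that("skews are antisymmetric under reverse complement", {
  set.seed(21)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE,
                      prob = runif(4, 0.1, 0.4)), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd <- skews(s); rev <- skews(rc)
    expect_equal(rev$at_skew, -fwd$at_skew)
    expect_equal(rev$gc_skew, -fwd$gc_skew)
  }
})

test_that("region table pools genes and codon positions correctly", {
  g <- fx_root_bs()
  tab <- region_table(g)
  expect_true(all(c("PCG-all", "PCGs-1st", "PCGs-2nd", "PCGs-3rd",
                    "12S", "16S", "rRNAs", "tRNAs", "D-loop") %in% tab$region))
  # PCG-all equals the composition of the concatenated heavy-strand genes
  pcg <- g$features[g$features$type == "PCG", ]
  concat <- paste(vapply(seq_len(nrow(pcg)), function(i) {
    substr(g$sequence, pcg$start[i], pcg$end[i])
  }, ""), collapse = "")
  expect_equal(as.data.frame(tab[tab$region == "PCG-all", -1]),
               as.data.frame(base_composition(concat, "PCG-all")[, -1]))
  expect_equal(tab$length[tab$region == "PCG-all"], 11378L)
  # frame-derived codon-position lengths for this architecture
  expect_equal(tab$length[tab$region == "PCGs-1st"], 3795L)
  expect_equal(tab$length[tab$region == "PCGs-2nd"], 3793L)
  expect_equal(tab$length[tab$region == "PCGs-3rd"], 3790L)
  expect_equal(tab$length[tab$region == "rRNAs"], 2519L)
  expect_equal(tab$length[tab$region == "D-loop"], 1496L)
  # percentages are faithful to integer base counts
  for (i in seq_len(nrow(tab))) {
    pct_sum <- tab$pct_a[i] + tab$pct_t[i] + tab$pct_g[i] + tab$pct_c[i]
    expect_equal(pct_sum, 100, tolerance = 1e-9)
  }
})

test_that("a two-gene toy genome pools exactly", {
  ft <- tibble::tibble(name = c("g1", "g2"), type = "PCG",
                       start = c(1L, 13L), end = c(12L, 24L), strand = "H",
                       start_codon = "ATG", stop_codon = "TAA",
                       anticodon = NA_character_)
  g <- mito_genome(ft, sequence = "ATGCCCAAATAAATGGGGTTTTAA", taxon = "toy")
  tab <- region_table(g)
  expect_equal(as.data.frame(tab[tab$region == "PCG-all", -1]),
               as.data.frame(base_composition("ATGCCCAAATAAATGGGGTTTTAA", "x")[, -1]))
  # codon position 1 collects bases 1,4,7,... of each CDS
  pos1 <- paste0(substring("ATGCCCAAATAA", c(1, 4, 7, 10), c(1, 4, 7, 10)),
                 collapse = "")
  pos1 <- paste0(pos1, paste0(substring("ATGGGGTTTTAA", c(1, 4, 7, 10),
                                        c(1, 4, 7, 10)), collapse = ""))
  expect_equal(as.data.frame(tab[tab$region == "PCGs-1st", -1]),
               as.data.frame(base_composition(pos1, "x")[, -1]))
})

test_that("uniform random sequence has near-zero skews", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 40000, TRUE), collapse = "")
  sk <- skews(s)
  expect_lt(abs(sk$at_skew), 0.02)
  expect_lt(abs(sk$gc_skew), 0.02)
})
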