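test_that("feature lengths follow the inclusive-coordinate convention", {
  bs <- toad_feature_table("sangzhiensis")
  expect_equal(feature_length(bs, 16950)[bs$name == "ND5"], 1818L)
  one <- tibble::tibble(name = "x", type = "tRNA", start = 5L, end = 5L, strand = "H")
  expect_equal(feature_length(one, 100L), 1L)
  # wrapping feature: 16940..16950 (11 bp) plus 1..10 (10 bp) = 21 bp
  wrap <- tibble::tibble(name = "dl", type = "control",
                         start = 16940L, end = 10L, strand = "H")
  expect_equal(feature_length(wrap, 16950L), 21L)
  oob <- tibble::tibble(name = "x", type = "tRNA", start = 1L, end = 20000L, strand = "H")
  expect_error(feature_length(oob, 16950L), "outside")
})

test_that("signed spacers reproduce printed intergenic cells", {
  bs <- toad_feature_table("sangzhiensis")
  expect_equal(spacer(bs[bs$name == "ATP8", ], bs[bs$name == "ATP6", ]), -10L)
  expect_equal(spacer(bs[bs$name == "tRNA-Val", ], bs[bs$name == "16S", ]), 3L)
  abut <- tibble::tibble(name = c("a", "b"), type = "tRNA",
                         start = c(1L, 71L), end = c(70L, 100L), strand = "H")
  expect_equal(spacer(abut[1, ], abut[2, ]), 0L)
  expect_error(spacer(bs, bs[1, ]), "one pair")
})

test_that("every printed length and spacer cell is recomputed from coordinates", {
  cells <- printed_cells()
  for (sp in c("bs", "bt")) {
    ft <- toad_feature_table(
      if (sp == "bs") "sangzhiensis" else "tuberogranulata")
    L <- if (sp == "bs") 16950L else 16841L
    expect_identical(ft$name, cells$name)
    expect_equal(feature_length(ft, L), cells[[paste0("length_", sp)]])
    rep <- spacer_report(ft, L)
    # the wrap-around pair (D-loop -> tRNA-Phe) closes the circle with spacer 0
    expect_equal(rep$per_pair$spacer, c(cells[[paste0("spacer_", sp)]][-39], 0L))
  }
})

test_that("spacer_report aggregates overlaps and intergenic nucleotides", {
  bs <- spacer_report(toad_feature_table("sangzhiensis"), 16950)
  expect_equal(glance(bs),
               tibble::tibble(overlap_bp_total = 38L, overlap_pairs = 13L,
                              ign_bp_total = 37L, ign_locations = 11L))
  bt <- spacer_report(toad_feature_table("tuberogranulata"), 16841)
  expect_equal(bt$overlap_bp_total, 44L)
  expect_equal(bt$overlap_pairs, 14L)
  # the column itself sums to 33 over 10 locations (coordinates win over text)
  expect_equal(bt$ign_bp_total, 33L)
  expect_equal(bt$ign_locations, 10L)
  abutting <- tibble::tibble(name = c("a", "b", "c"), type = "tRNA",
                             start = c(1L, 41L, 71L), end = c(40L, 70L, 100L),
                             strand = "H")
  expect_equal(unlist(glance(spacer_report(abutting, 100L))),
               c(overlap_bp_total = 0L, overlap_pairs = 0L,
                 ign_bp_total = 0L, ign_locations = 0L))
})

test_that("feature lengths, IGNs and overlaps tile the circle exactly once", {
  for (args in list(list("sangzhiensis", 16950L), list("tuberogranulata", 16841L))) {
    ft <- toad_feature_table(args[[1]])
    rep <- spacer_report(ft, args[[2]])
    expect_equal(sum(feature_length(ft, args[[2]])) +
                   rep$ign_bp_total - rep$overlap_bp_total,
                 args[[2]])
  }
  g <- fx_root_bs()
  rep <- spacer_report(g)
  expect_equal(sum(feature_length(g)) + rep$ign_bp_total - rep$overlap_bp_total,
               g$length)
})

test_that("spacer accounting is invariant under rotation of the origin", {
  g <- fx_root_bs()
  base <- glance(spacer_report(g))
  for (offset in c(1L, 500L, 7711L, 16949L)) {
    rot <- rotate_genome(g, offset)
    expect_equal(glance(spacer_report(rot)), base, info = paste("offset", offset))
  }
})

test_that("strict validation checks the canonical complement and codon metadata", {
  bs <- mito_genome(toad_feature_table("sangzhiensis"), genome_length = 16950)
  expect_no_issues(validate_mitogenome(bs, "strict"))
  no_nd6 <- bs
  no_nd6$features <- no_nd6$features[no_nd6$features$name != "ND6", ]
  issues <- validate_mitogenome(no_nd6, "strict")
  expect_true(any(issues$check == "complement" & issues$feature == "PCG"))
  bad <- bs
  bad$features$end[bad$features$name == "ND2"] <- 100L
  issues <- validate_mitogenome(bad, "lenient")
  expect_identical(issues$check, "coordinates")
  expect_identical(issues$feature, "ND2")
})

test_that("tidy/glance expose the table-1 view of a genome", {
  g <- fx_root_bs()
  td <- tidy(g)
  expect_identical(nrow(td), 39L)
  expect_true(all(c("length", "spacer") %in% names(td)))
  gl <- glance(g)
  expect_identical(gl$n_pcg, 13L)
  expect_identical(gl$n_trna, 22L)
  expect_lt(gl$at_skew, 0)
  expect_lt(gl$gc_skew, 0)
})
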