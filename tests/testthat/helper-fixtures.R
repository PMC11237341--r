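# Shared fixtures, generated once per test session and cached.
fx <- new.env()

fx_get <- function(name, build) {
  if (is.null(fx[[name]])) fx[[name]] <- build()
  fx[[name]]
}

# synthetic genomes realizing the two study architectures
fx_root_bs <- function() fx_get("root_bs", function() {
  generate_root(sim_spec(seed = 101))
})

fx_root_bt <- function() fx_get("root_bt", function() {
  generate_root(sim_spec(architecture = toad_feature_table("tuberogranulata"),
                         seed = 102))
})

# small 4-taxon dataset for IO / pipeline tests
fx_quartet <- function() fx_get("quartet", function() {
  tr <- ape::read.tree(text = "((A:0.04,B:0.04):0.02,(C:0.04,D:0.04):0.02);")
  simulate_dataset(sim_spec(tree = tr, seed = 103))
})

# full 29-taxon dataset on the study-shaped tree
fx_megophryidae <- function() fx_get("megophryidae", function() {
  simulate_dataset(sim_spec(seed = 42))
})

# printed per-feature length/spacer cells for both species
printed_cells <- function() {
  readr::read_tsv(test_path("fixtures", "printed_feature_cells.tsv"),
                  col_types = "ciiii")
}

expect_no_issues <- function(issues) {
  expect_identical(nrow(issues), 0L)
}
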