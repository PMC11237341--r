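#' Run the full characterization pipeline
#'
#' Chains the stages over a set of annotated genomes and writes the
#' standard table bundle: `table1.tsv` (per-feature characteristics:
#' coordinates, length, codons, strand, signed spacer), `table2.tsv`
#' (per-genome composition), `table3.tsv` (per-region composition),
#' `rscu.tsv`, and — when at least four genomes are given — `kaks.tsv`,
#' the supermatrix with partition files, and `tree.nwk` (NJ, with
#' bootstrap support when `bootstrap > 0`). A `summary.json` records
#' spacer reports, validation issues, versions, seed and per-stage
#' timings; `MANIFEST` lists the files completed.
#'
#' @param genomes List of `mito_genome` objects with sequence.
#' @param outdir Output directory (created if needed).
#' @param bootstrap Bootstrap replicates for the tree stage (0 = none).
#' @param seed Seed for the bootstrap stage.
#' @param outgroup Optional outgroup taxon for tree rooting in the report.
#' @param lenient Validate genomes leniently instead of strictly.
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
run_characterization <- function(genomes, outdir, bootstrap = 0L, seed = 1L,
                                 outgroup = NULL, lenient = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  written <- character(0)
  stage <- function(nm, expr) {
    s <- proc.time()[["elapsed"]]
    val <- expr
    timings[[nm]] <<- round(proc.time()[["elapsed"]] - s, 3)
    val
  }
  emit <- function(df, file) {
    path <- file.path(outdir, file)
    readr::write_tsv(df, path)
    written <<- c(written, file)
    path
  }

  validation <- stage("validate", purrr::map(genomes, validate_mitogenome,
    mode = if (lenient) "lenient" else "strict"))
  n_issues <- sum(vapply(validation, nrow, integer(1)))

  table1 <- stage("table1", purrr::map_dfr(genomes, function(g) {
    dplyr::mutate(tidy(g), taxon = g$taxon, .before = 1)
  }))
  emit(dplyr::mutate(table1, stop_codon = format_stop_codon(.data$stop_codon)),
       "table1.tsv")

  table2 <- stage("table2", genome_composition(genomes))
  emit(round_composition(table2), "table2.tsv")

  table3 <- stage("table3", purrr::map_dfr(genomes, function(g) {
    dplyr::mutate(region_table(g), taxon = g$taxon, .before = 1)
  }))
  emit(round_composition(table3), "table3.tsv")

  rscu_tbl <- stage("rscu", purrr::map_dfr(genomes, function(g) {
    dplyr::mutate(rscu(g), taxon = g$taxon, .before = 1)
  }))
  emit(rscu_tbl, "rscu.tsv")

  spacers <- purrr::map(genomes, spacer_report)
  names(spacers) <- vapply(genomes, function(g) g$taxon, "")

  kaks_tbl <- NULL
  tree <- NULL
  if (length(genomes) >= 4L) {
    cds_tbl <- pcg_cds_table(genomes)
    kaks_tbl <- stage("kaks", gene_kaks(cds_tbl))
    emit(kaks_tbl, "kaks.tsv")
    block <- stage("supermatrix", concatenate_pcgs(cds_tbl))
    sm <- write_supermatrix(block, file.path(outdir, "supermatrix"),
                            format = "relaxed_phylip")
    write_supermatrix(block, file.path(outdir, "supermatrix"),
                      format = "nexus")
    written <- c(written, basename(sm), "supermatrix.nex")
    tree <- stage("tree", if (bootstrap > 0) {
      bootstrap_tree(block, replicates = bootstrap, seed = seed)
    } else {
      nj_tree(distance_matrix(block), impute_saturated = TRUE)
    })
    write_newick(tree, file.path(outdir, "tree.nwk"))
    written <- c(written, "tree.nwk")
  }

  summary <- list(
    package_version = as.character(packageVersion("boulenophrys")),
    r_version = R.version.string,
    seed = seed, bootstrap = bootstrap,
    n_genomes = length(genomes),
    validation_issues = n_issues,
    spacer_reports = purrr::map(spacers, function(s) glance(s)),
    timings = timings,
    elapsed = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  written <- c(written, "summary.json")
  writeLines(sort(unique(written)), file.path(outdir, "MANIFEST"))

  invisible(list(table1 = table1, table2 = table2, table3 = table3,
                 rscu = rscu_tbl, kaks = kaks_tbl, tree = tree,
                 spacers = spacers, validation = validation,
                 outdir = outdir, files = sort(unique(written))))
}

#' Round a composition table to report precision
#'
#' Percentages to 2 decimals, skews to 3 decimals (half-up, the precision
#' used by published composition tables).
#'
#' @param df Tibble with composition columns.
#' @return Tibble with rounded columns.
#' @export
round_composition <- function(df) {
  half_up <- function(x, d) floor(abs(x) * 10^d + 0.5) / 10^d * sign(x)
  for (col in intersect(c("pct_t", "pct_c", "pct_a", "pct_g", "pct_at"), names(df))) {
    df[[col]] <- half_up(df[[col]], 2L)
  }
  for (col in intersect(c("at_skew", "gc_skew"), names(df))) {
    df[[col]] <- half_up(df[[col]], 3L)
  }
  df
}
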