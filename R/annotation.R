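#' Read an annotated feature table
#'
#' Reads the TSV dialect used for mitogenome feature tables: one row per
#' feature with columns `name`, `type` (PCG/tRNA/rRNA/control/origin),
#' `start`, `end` (1-based inclusive), `strand` (H/L), and optional
#' `start_codon`, `stop_codon` (printed form such as `"TA(A)"` accepted),
#' `anticodon`. Rows are kept in genome order.
#'
#' @param path Path to a TSV file.
#' @return A tibble of features with normalized stop descriptors and a
#'   logical `wraps` column (TRUE when `end < start`, i.e. the feature
#'   crosses the circular origin).
#' @export
read_feature_table <- function(path) {
  ft <- readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(), type = readr::col_character(),
      start = readr::col_integer(), end = readr::col_integer(),
      strand = readr::col_character(),
      start_codon = readr::col_character(),
      stop_codon = readr::col_character(),
      anticodon = readr::col_character()
    )
  )
  as_feature_table(ft)
}

#' Coerce a data frame to a feature table
#'
#' @param x Data frame with at least `name`, `type`, `start`, `end`,
#'   `strand`.
#' @return Tibble with the canonical column set.
#' @export
as_feature_table <- function(x) {
  x <- as_tibble(x)
  required <- c("name", "type", "start", "end", "strand")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste("feature table lacks columns:", paste(missing, collapse = ", ")))
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  x$stop_codon <- normalize_stop_codon(x$stop_codon)
  if (!"wraps" %in% names(x)) x$wraps <- FALSE
  x$wraps <- x$wraps | (x$end < x$start)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  dplyr::select(x, "name", "type", "start", "end", "strand",
                "start_codon", "stop_codon", "anticodon", "wraps")
}

#' Bundled feature tables for the two Boulenophrys mitogenomes
#'
#' Feature tables (gene, coordinates, strand, codon metadata) for
#' *B. sangzhiensis* (16,950 bp, GenBank OQ830572) and
#' *B. tuberogranulata* (16,841 bp, GenBank OQ830573), as published with
#' the genome records.
#'
#' @param species `"sangzhiensis"` or `"tuberogranulata"`.
#' @return A feature-table tibble (39 rows: 13 PCGs, 22 tRNAs, 2 rRNAs,
#'   the control region, and the light-strand replication origin OL).
#' @export
toad_feature_table <- function(species = c("sangzhiensis", "tuberogranulata")) {
  species <- match.arg(species)
  path <- system.file("extdata",
                      paste0("feature_table_", species, ".tsv"),
                      package = "boulenophrys", mustWork = TRUE)
  read_feature_table(path)
}

#' Construct a mitogenome object
#'
#' A `mito_genome` bundles a heavy-strand nucleotide sequence (optional —
#' coordinate-only accounting works without it), an ordered feature table,
#' and provenance.
#'
#' @param features Feature table (see [as_feature_table()]).
#' @param sequence Heavy-strand nucleotide string over A/C/G/T/N, or NULL.
#' @param taxon,accession Provenance strings.
#' @param circular Logical; vertebrate mitogenomes are circular.
#' @param genome_length Required when `sequence` is NULL and features do
#'   not determine the length (defaults to `max(end)` of non-wrapping
#'   features).
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(features, sequence = NULL, taxon = NA_character_,
                        accession = NA_character_, circular = TRUE,
                        genome_length = NULL) {
  features <- as_feature_table(features)
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence)) abort("sequence contains non-ACGTN symbols")
    len <- nchar(sequence)
    if (!is.null(genome_length) && genome_length != len) {
      abort("genome_length disagrees with sequence length")
    }
  } else {
    len <- genome_length %||% max(features$end[!features$wraps])
  }
  structure(
    list(taxon = taxon, accession = accession, sequence = sequence,
         circular = circular, length = as.integer(len), features = features),
    class = "mito_genome"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s (%s), %d bp, %s, %d features%s\n",
              x$taxon %||% NA, x$accession %||% NA, x$length,
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$sequence)) ", no sequence" else ""))
  invisible(x)
}

#' Feature lengths on a (possibly circular) genome
#'
#' Length in bp of each feature: `end - start + 1` for ordinary features,
#' `(genome_length - start + 1) + end` for features wrapping the circular
#' origin.
#'
#' @param features Feature table or `mito_genome`.
#' @param genome_length Genome length in bp (taken from the genome when a
#'   `mito_genome` is given).
#' @return Integer vector of lengths, one per feature row.
#' @examples
#' feature_length(toad_feature_table("sangzhiensis"), 16950)
#' @export
feature_length <- function(features, genome_length = NULL) {
  if (inherits(features, "mito_genome")) {
    genome_length <- features$length
    features <- features$features
  }
  features <- as_feature_table(features)
  if (is.null(genome_length)) abort("genome_length is required")
  bad <- features$start < 1L | features$end < 1L |
    features$start > genome_length | features$end > genome_length
  if (any(bad)) {
    abort(paste("feature coordinates outside [1, genome_length]:",
                paste(features$name[bad], collapse = ", ")))
  }
  as.integer(ifelse(features$wraps,
                    genome_length - features$start + 1L + features$end,
                    features$end - features$start + 1L))
}

#' Signed spacer between two adjacent features
#'
#' `start(B) - end(A) - 1`: negative values are overlaps, zero means the
#' features abut, positive values are intergenic nucleotides (IGN). This is
#' the signed "intergenic nucleotide" column of a characterization table.
#'
#' @param feature_a,feature_b Single-row feature tables (A precedes B in
#'   genome order).
#' @return Integer spacer in bp.
#' @export
spacer <- function(feature_a, feature_b) {
  feature_a <- as_feature_table(feature_a)
  feature_b <- as_feature_table(feature_b)
  if (nrow(feature_a) != 1L || nrow(feature_b) != 1L) {
    abort("spacer() compares exactly one pair of adjacent features")
  }
  as.integer(feature_b$start - feature_a$end - 1L)
}

#' Overlap / intergenic-spacer accounting for a whole genome
#'
#' Computes the signed spacer for every adjacent feature pair in genome
#' order (including the wrap-around pair from the last feature back to the
#' first on circular genomes) and aggregates overlaps and intergenic
#' nucleotides.
#'
#' @param genome A `mito_genome`, or a feature table (then `genome_length`
#'   and `circular` must be supplied).
#' @param genome_length,circular Used when `genome` is a bare feature table.
#' @return An object of class `spacer_report`: list with
#'   `overlap_bp_total`, `overlap_pairs`, `ign_bp_total`, `ign_locations`,
#'   and `per_pair` (tibble `feature_a`, `feature_b`, `spacer`). Use
#'   [tidy()] / [glance()] to get tibbles.
#' @examples
#' rep <- spacer_report(toad_feature_table("sangzhiensis"), 16950)
#' glance(rep)
#' @export
spacer_report <- function(genome, genome_length = NULL, circular = TRUE) {
  if (inherits(genome, "mito_genome")) {
    features <- genome$features
    genome_length <- genome$length
    circular <- genome$circular
  } else {
    features <- as_feature_table(genome)
    if (is.null(genome_length)) abort("genome_length is required")
  }
  if (nrow(features) < 2L) abort("need at least two features")
  if (anyDuplicated(features$name)) {
    abort("duplicate feature names; disambiguate (e.g. tRNA-Ser1/tRNA-Ser2)")
  }
  st <- ifelse(features$wraps, features$start - genome_length, features$start)
  if (is.unsorted(st)) abort("features are not sorted in genome order")
  n <- nrow(features)
  a <- seq_len(n - 1L)
  sp <- as.integer(features$start[a + 1L] - features$end[a] - 1L)
  per_pair <- tibble(feature_a = features$name[a],
                     feature_b = features$name[a + 1L],
                     spacer = sp)
  if (circular) {
    # spacer across the origin: when either flanking feature wraps, the
    # coordinates already sit on the same lap; otherwise the first feature
    # starts one full circle later
    wrap_sp <- as.integer(
      if (features$wraps[1L] || features$wraps[n]) {
        features$start[1L] - features$end[n] - 1L
      } else {
        features$start[1L] + genome_length - features$end[n] - 1L
      })
    per_pair <- dplyr::bind_rows(per_pair,
      tibble(feature_a = features$name[n], feature_b = features$name[1L],
             spacer = wrap_sp))
  }
  structure(
    list(overlap_bp_total = -sum(per_pair$spacer[per_pair$spacer < 0L]),
         overlap_pairs = sum(per_pair$spacer < 0L),
         ign_bp_total = sum(per_pair$spacer[per_pair$spacer > 0L]),
         ign_locations = sum(per_pair$spacer > 0L),
         per_pair = per_pair),
    class = "spacer_report"
  )
}

#' @export
print.spacer_report <- function(x, ...) {
  cat(sprintf(paste0("<spacer_report> overlaps: %d bp over %d pairs; ",
                     "IGN: %d bp over %d locations\n"),
              x$overlap_bp_total, x$overlap_pairs,
              x$ign_bp_total, x$ign_locations))
  invisible(x)
}

#' @rdname spacer_report
#' @param x A `spacer_report`.
#' @param ... Unused.
#' @method tidy spacer_report
#' @export
tidy.spacer_report <- function(x, ...) x$per_pair

#' @rdname spacer_report
#' @method glance spacer_report
#' @export
glance.spacer_report <- function(x, ...) {
  tibble(overlap_bp_total = x$overlap_bp_total,
         overlap_pairs = x$overlap_pairs,
         ign_bp_total = x$ign_bp_total,
         ign_locations = x$ign_locations)
}

#' Validate a mitogenome annotation
#'
#' Lenient mode checks coordinate sanity only; strict mode additionally
#' requires the canonical vertebrate complement (13 PCGs, 22 tRNAs, 2
#' rRNAs, 1 control region), valid strand labels, codon metadata on PCGs,
#' and anticodons on tRNAs.
#'
#' @param genome A `mito_genome`.
#' @param mode `"strict"` or `"lenient"`.
#' @return A tibble of issues (`check`, `feature`, `message`); zero rows
#'   when the annotation is clean. Issues are returned, never raised.
#' @export
validate_mitogenome <- function(genome, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  f <- genome$features
  L <- genome$length
  issue <- function(check, feature, message) {
    tibble(check = check, feature = feature, message = message)
  }
  issues <- list()
  oob <- f$start < 1L | f$end < 1L | f$start > L | f$end > L
  for (nm in f$name[oob]) {
    issues <- c(issues, list(issue("coordinates", nm, "outside [1, genome length]")))
  }
  rev_bad <- !f$wraps & f$end < f$start
  for (nm in f$name[rev_bad]) {
    issues <- c(issues, list(issue("coordinates", nm, "end < start for non-wrapping feature")))
  }
  if (any(f$wraps) && !genome$circular) {
    issues <- c(issues, list(issue("coordinates", f$name[f$wraps][1],
                                   "wrapping feature on a linear genome")))
  }
  if (mode == "strict") {
    counts <- table(factor(f$type, levels = c("PCG", "tRNA", "rRNA", "control", "origin")))
    want <- c(PCG = 13L, tRNA = 22L, rRNA = 2L, control = 1L)
    for (ty in names(want)) {
      if (counts[[ty]] != want[[ty]]) {
        issues <- c(issues, list(issue(
          "complement", ty,
          sprintf("expected %d %s features, found %d", want[[ty]], ty, counts[[ty]]))))
      }
    }
    bad_strand <- !f$strand %in% c("H", "L")
    for (nm in f$name[bad_strand]) {
      issues <- c(issues, list(issue("strand", nm, "strand must be H or L")))
    }
    pcg <- f[f$type == "PCG", ]
    no_codon <- is.na(pcg$start_codon) | is.na(pcg$stop_codon)
    for (nm in pcg$name[no_codon]) {
      issues <- c(issues, list(issue("codons", nm, "PCG lacks start/stop codon metadata")))
    }
    trna <- f[f$type == "tRNA", ]
    for (nm in trna$name[is.na(trna$anticodon)]) {
      issues <- c(issues, list(issue("codons", nm, "tRNA lacks anticodon")))
    }
    if (anyDuplicated(f$name)) {
      issues <- c(issues, list(issue("names", f$name[duplicated(f$name)][1],
                                     "duplicate feature name")))
    }
  }
  if (length(issues) == 0) {
    tibble(check = character(0), feature = character(0), message = character(0))
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Rotate the circular origin of a genome
#'
#' Moves the origin so that old position `offset + 1` becomes position 1.
#' Feature coordinates (and the sequence, when present) are shifted
#' accordingly; features crossing the new origin are flagged as wrapping.
#' Spacer accounting is invariant under this operation.
#'
#' @param genome A circular `mito_genome`.
#' @param offset Integer in `[0, length)`.
#' @return A rotated `mito_genome` (feature order preserved relative to the
#'   rotation).
#' @export
rotate_genome <- function(genome, offset) {
  stopifnot(inherits(genome, "mito_genome"), genome$circular)
  L <- genome$length
  offset <- as.integer(offset %% L)
  if (offset == 0L) return(genome)
  shift <- function(p) ((p - offset - 1L) %% L) + 1L
  f <- genome$features
  f$start <- shift(f$start)
  f$end <- shift(f$end)
  f$wraps <- f$end < f$start
  # genome order restarts from the feature now nearest position 1
  f <- f[order(ifelse(f$wraps, f$start - L, f$start)), ]
  seq2 <- genome$sequence
  if (!is.null(seq2)) {
    seq2 <- paste0(substr(seq2, offset + 1L, L), substr(seq2, 1L, offset))
  }
  mito_genome(f, sequence = seq2, taxon = genome$taxon,
              accession = genome$accession, circular = TRUE,
              genome_length = L)
}

#' @method tidy mito_genome
#' @export
tidy.mito_genome <- function(x, ...) {
  f <- x$features
  f$length <- feature_length(f, x$length)
  rep <- spacer_report(x)
  sp <- rep$per_pair$spacer
  f$spacer <- if (length(sp) == nrow(f)) sp else c(sp, NA_integer_)
  f
}

#' @method glance mito_genome
#' @export
glance.mito_genome <- function(x, ...) {
  comp <- if (!is.null(x$sequence)) base_composition(x$sequence) else NULL
  tibble(
    taxon = x$taxon, accession = x$accession, length = x$length,
    n_features = nrow(x$features),
    n_pcg = sum(x$features$type == "PCG"),
    n_trna = sum(x$features$type == "tRNA"),
    n_rrna = sum(x$features$type == "rRNA"),
    pct_at = if (is.null(comp)) NA_real_ else comp$pct_at,
    at_skew = if (is.null(comp)) NA_real_ else comp$at_skew,
    gc_skew = if (is.null(comp)) NA_real_ else comp$gc_skew
  )
}
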