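#' Base composition of a nucleotide sequence
#'
#' Percentages of A, T, G and C over the counted (non-N) positions,
#' together with the A+T percentage and the AT/GC strand skews
#' (`(A - T)/(A + T)` and `(G - C)/(G + C)`). The reported `length` is the
#' full sequence length including Ns.
#'
#' @param seq Nucleotide string (A/C/G/T/N).
#' @param region Label for the output row.
#' @return One-row tibble: `region`, `length`, `pct_t`, `pct_c`, `pct_a`,
#'   `pct_g`, `pct_at`, `at_skew`, `gc_skew` (column order of published
#'   composition tables).
#' @examples
#' base_composition("AATT")
#' @export
base_composition <- function(seq, region = "sequence") {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) abort("empty sequence")
  counts <- base_counts(seq)
  denom <- sum(counts)
  if (denom == 0L) abort("sequence is all N: composition undefined")
  composition_row(region, nchar(seq), counts)
}

base_counts <- function(seq) {
  vapply(c(A = "A", T = "T", G = "G", C = "C"),
         function(b) as.numeric(stringr::str_count(seq, stringr::fixed(b))),
         numeric(1))
}

composition_row <- function(region, length, counts) {
  denom <- sum(counts)
  pct <- 100 * counts / denom
  sk <- skew_from_counts(counts[["A"]], counts[["T"]],
                         counts[["G"]], counts[["C"]])
  tibble(region = region, length = as.integer(length),
         pct_t = pct[["T"]], pct_c = pct[["C"]],
         pct_a = pct[["A"]], pct_g = pct[["G"]],
         pct_at = pct[["A"]] + pct[["T"]],
         at_skew = sk$at_skew, gc_skew = sk$gc_skew)
}

#' AT and GC skew
#'
#' `AT skew = (A - T)/(A + T)` and `GC skew = (G - C)/(G + C)`. A skew with
#' zero denominator is undefined and returned as `NA`, never as zero.
#'
#' @param seq Nucleotide string.
#' @return One-row tibble with `at_skew` and `gc_skew`.
#' @examples
#' skews("GGGG") # gc_skew 1, at_skew NA
#' @export
skews <- function(seq) {
  counts <- base_counts(toupper(seq))
  as_tibble(skew_from_counts(counts[["A"]], counts[["T"]],
                             counts[["G"]], counts[["C"]]))
}

#' Skews from base counts or percentages
#'
#' The skew formulas are scale-free, so they apply equally to raw counts
#' and to the percentages printed in a composition table.
#'
#' @param a,t,g,c Counts or percentages of each base.
#' @return List with `at_skew` and `gc_skew` (`NA` when undefined).
#' @examples
#' skew_from_counts(27.45, 30.77, 14.81, 26.97)
#' @export
skew_from_counts <- function(a, t, g, c) {
  list(
    at_skew = ifelse(a + t > 0, (a - t) / (a + t), NA_real_),
    gc_skew = ifelse(g + c > 0, (g - c) / (g + c), NA_real_)
  )
}

region_seq <- function(genome, row) {
  s <- genome$sequence
  if (is.null(s)) abort("genome carries no sequence")
  if (row$wraps) {
    paste0(substr(s, row$start, genome$length), substr(s, 1L, row$end))
  } else {
    substr(s, row$start, row$end)
  }
}

#' Coding-strand sequence of a protein-coding gene
#'
#' Extracts the gene's sub-sequence from the heavy strand and
#' reverse-complements it when the gene is light-strand encoded, so the
#' result always reads 5'->3' on the coding strand (starts with the start
#' codon).
#'
#' @param genome A `mito_genome` with sequence.
#' @param gene Gene name as in the feature table.
#' @return Nucleotide string.
#' @export
extract_cds <- function(genome, gene) {
  f <- genome$features
  i <- which(f$name == gene)
  if (length(i) != 1L) abort(paste("unknown or ambiguous gene:", gene))
  s <- region_seq(genome, f[i, ])
  if (f$strand[i] == "L") revcomp(s) else s
}

#' Region-by-region composition table
#'
#' One composition row per protein-coding gene, plus pooled rows for all
#' PCGs, the three codon positions of the pooled PCGs, each rRNA, the
#' concatenated rRNAs, the concatenated tRNAs, and the control region.
#' Per-region rows are computed on the heavy-strand sequence of the region
#' regardless of coding strand (the convention under which the single
#' light-strand gene ND6 shows its characteristic positive GC skew).
#' Codon-position rows are pooled per gene on the coding strand by reading
#' frame; the trailing 1-2 nt of incomplete stop codons fall at positions
#' 1 (and 2) of their final, incomplete codon.
#'
#' @param genome A `mito_genome` with sequence.
#' @return A tibble of composition rows, class `region_composition`.
#' @export
region_table <- function(genome) {
  f <- genome$features
  pcg <- f[f$type == "PCG", ]
  rows <- list()
  pcg_h <- character(nrow(pcg))
  for (i in seq_len(nrow(pcg))) {
    pcg_h[i] <- region_seq(genome, pcg[i, ])
    rows <- c(rows, list(base_composition(pcg_h[i], pcg$name[i])))
  }
  rows <- c(rows, list(base_composition(paste(pcg_h, collapse = ""), "PCG-all")))

  pos_seqs <- c(`1` = "", `2` = "", `3` = "")
  for (i in seq_len(nrow(pcg))) {
    cds <- extract_cds(genome, pcg$name[i])
    chars <- strsplit(cds, "")[[1]]
    frame <- ((seq_along(chars) - 1L) %% 3L) + 1L
    for (p in 1:3) {
      pos_seqs[[p]] <- paste0(pos_seqs[[p]], paste(chars[frame == p], collapse = ""))
    }
  }
  for (p in 1:3) {
    rows <- c(rows, list(base_composition(pos_seqs[[p]], paste0("PCGs-", p, c("st", "nd", "rd")[p]))))
  }

  rr <- f[f$type == "rRNA", ]
  if (nrow(rr) > 0) {
    rr_seqs <- vapply(seq_len(nrow(rr)), function(i) region_seq(genome, rr[i, ]), "")
    for (i in seq_len(nrow(rr))) {
      rows <- c(rows, list(base_composition(rr_seqs[i], rr$name[i])))
    }
    rows <- c(rows, list(base_composition(paste(rr_seqs, collapse = ""), "rRNAs")))
  }

  tr <- f[f$type == "tRNA", ]
  if (nrow(tr) > 0) {
    tr_seq <- paste(vapply(seq_len(nrow(tr)), function(i) region_seq(genome, tr[i, ]), ""),
                    collapse = "")
    rows <- c(rows, list(base_composition(tr_seq, "tRNAs")))
  }

  ctrl <- f[f$type == "control", ]
  for (i in seq_len(nrow(ctrl))) {
    rows <- c(rows, list(base_composition(region_seq(genome, ctrl[i, ]), ctrl$name[i])))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("region_composition", class(out))
  out
}

#' Whole-genome composition table for a set of genomes
#'
#' One row per genome, mirroring a multi-species base-composition table.
#'
#' @param genomes List of `mito_genome` objects with sequence.
#' @return Tibble with `species`, `accession`, and the composition columns.
#' @export
genome_composition <- function(genomes) {
  purrr::map_dfr(genomes, function(g) {
    dplyr::bind_cols(tibble(species = g$taxon, accession = g$accession),
                     base_composition(g$sequence, "genome")[, -1])
  })
}

#' Published whole-genome composition of 29 megophryid taxa
#'
#' The printed multi-species composition table (total length, base
#' percentages, A+T%, AT skew, GC skew, accession) covering the two newly
#' sequenced Boulenophrys mitogenomes, 26 further megophryids, and the
#' Microhyla fissipes outgroup.
#'
#' @return Tibble with 29 rows.
#' @export
megophryidae_composition <- function() {
  path <- system.file("extdata", "composition_megophryidae.tsv",
                      package = "boulenophrys", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(), accession = readr::col_character(),
    .default = readr::col_double()
  ))
}
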