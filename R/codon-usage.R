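#' Codon usage and RSCU over a set of coding sequences
#'
#' Counts codons across one or more in-frame CDS and computes relative
#' synonymous codon usage. RSCU of a codon is its observed count times the
#' size of its synonymous family, divided by the family's total count, so
#' uniform use within a family gives RSCU 1 for every member. Terminal stop
#' codons (complete or incomplete) and codons containing N are excluded
#' from the counts; amino acids never observed get RSCU 0 for all their
#' codons and are flagged in the `observed` column.
#'
#' @param cds_set Character vector of coding-strand CDS (each starting with
#'   its start codon), or a single string.
#' @param code Genetic code, as from [mito_genetic_code()].
#' @return A tibble of class `codon_usage`: `codon` (DNA), `codon_rna`
#'   (display form with U), `aa`, `count`, `aa_total`, `rscu`, `observed`,
#'   sorted by amino acid then codon.
#' @examples
#' codon_usage(c("ATGGCCGCCGCTTAA"))
#' @export
codon_usage <- function(cds_set, code = mito_genetic_code()) {
  if (length(cds_set) == 0L || all(nchar(cds_set) == 0L)) {
    abort("empty CDS set")
  }
  counts <- setNames(integer(64), ALL_CODONS())
  for (cds in toupper(cds_set)) {
    codons <- split_codons(cds)
    if (length(codons) == 0L) next
    last <- codons[length(codons)]
    if (nchar(cds) %% 3L == 0L && last %in% code$stops) {
      codons <- codons[-length(codons)]   # drop terminal complete stop
    }
    codons <- codons[!grepl("N", codons)]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa_map <- code$codon_to_aa
  out <- tibble(codon = names(aa_map), aa = unname(aa_map),
                count = as.integer(counts[names(aa_map)]))
  out <- out[out$aa != "*", ]
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$aa),
    aa_total = sum(.data$count),
    family = dplyr::n(),
    rscu = ifelse(.data$aa_total > 0,
                  .data$count * .data$family / .data$aa_total, 0),
    observed = .data$aa_total > 0
  )
  out <- dplyr::ungroup(out)
  out$codon_rna <- chartr("T", "U", out$codon)
  out <- dplyr::arrange(out, .data$aa, .data$codon)
  out <- dplyr::select(out, "codon", "codon_rna", "aa", "count",
                       "aa_total", "family", "rscu", "observed")
  class(out) <- c("codon_usage", class(out))
  out
}

#' RSCU table for all protein-coding genes of a genome
#'
#' Convenience wrapper: extracts the 13 PCG coding sequences and calls
#' [codon_usage()].
#'
#' @param genome A `mito_genome` with sequence.
#' @inheritParams codon_usage
#' @return A `codon_usage` tibble.
#' @export
rscu <- function(genome, code = mito_genetic_code()) {
  pcg <- genome$features$name[genome$features$type == "PCG"]
  codon_usage(vapply(pcg, function(g) extract_cds(genome, g), ""), code)
}

#' Start/stop classification for every PCG of a genome
#'
#' Runs [classify_codons()] on each protein-coding gene and returns the
#' table-ready start and stop cells (incomplete stops in printed form,
#' e.g. `"TA(A)"`).
#'
#' @param genome A `mito_genome` with sequence.
#' @return Tibble: `gene`, `start_codon`, `stop_codon`, `issues`.
#' @export
classify_pcgs <- function(genome) {
  pcg <- genome$features$name[genome$features$type == "PCG"]
  purrr::map_dfr(pcg, function(g) {
    cl <- classify_codons(extract_cds(genome, g))
    tibble(gene = g, start_codon = cl$start_codon,
           stop_codon = format_stop_codon(cl$stop_codon),
           issues = paste(cl$issues, collapse = "; "))
  })
}
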