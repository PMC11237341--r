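#' The vertebrate mitochondrial genetic code
#'
#' Returns the translation table used throughout the package (NCBI
#' translation table 2). Compared to the standard code: AGA and AGG are stop
#' codons, TGA encodes tryptophan, and ATA encodes methionine. The allowed
#' start set covers the alternative initiation codons seen in vertebrate
#' mitochondria (ATG, ATA, ATT, ATC, GTG, TTG).
#'
#' @param table_id Integer NCBI translation table id. Only table 2 is
#'   supported; the argument exists so callers can state their assumption.
#' @return A list with elements `table_id`, `codon_to_aa` (named character
#'   vector over the 64 codons, stops as `"*"`), `stops`, `sense` (the 60
#'   sense codons), and `allowed_starts`.
#' @examples
#' code <- mito_genetic_code()
#' code$codon_to_aa[c("TGA", "ATA", "AGA")]
#' @export
mito_genetic_code <- function(table_id = 2L) {
  if (!identical(as.integer(table_id), 2L)) {
    abort("only the vertebrate mitochondrial code (table 2) is supported")
  }
  if (is.null(the$code)) {
    aa <- as.character(Biostrings::getGeneticCode("2"))
    names(aa) <- names(Biostrings::getGeneticCode("2"))
    stopifnot(length(aa) == 64L)
    the$code <- list(
      table_id = 2L,
      codon_to_aa = aa,
      stops = names(aa)[aa == "*"],
      sense = names(aa)[aa != "*"],
      allowed_starts = c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG")
    )
  }
  the$code
}

ALL_CODONS <- function() names(mito_genetic_code()$codon_to_aa)

#' Translate an in-frame coding sequence
#'
#' Translates complete codons under the vertebrate mitochondrial code; a
#' trailing partial codon (incomplete stop) is ignored. Stop codons
#' translate to `"*"`; codons containing N translate to `"X"`.
#'
#' @param cds Coding-strand nucleotide string (A/C/G/T/N).
#' @param code Genetic code, as from [mito_genetic_code()].
#' @return Amino-acid string. Attribute `"internal_stops"` carries the
#'   1-based codon indices of internal stop codons, if any.
#' @export
translate_cds <- function(cds, code = mito_genetic_code()) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) abort("cds shorter than one codon")
  if (grepl("[^ACGTN]", cds)) abort("cds contains non-ACGTN symbols")
  codons <- split_codons(cds)
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"
  out <- paste(aa, collapse = "")
  internal <- which(aa == "*")
  internal <- internal[internal < length(aa)]
  attr(out, "internal_stops") <- internal
  out
}

# complete codons only; trailing 1-2 nt dropped
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Classify start and stop codons of a CDS
#'
#' Mirrors the start/stop columns of a mitogenome characterization table.
#' The start codon is the first triplet; non-canonical starts are reported
#' as issues, not errors. The stop is the final complete triplet when the
#' length is a multiple of three and that triplet is a stop under the code;
#' otherwise the trailing 1 or 2 nucleotides form an incomplete stop
#' (`"T"` or `"TA"`), completed to TAA by polyadenylation in vivo.
#'
#' @param cds Coding-strand nucleotide string, length >= 6.
#' @param code Genetic code.
#' @return A list with `start_codon`, `stop_codon` (3-mer or `"T"`/`"TA"`,
#'   `NA` if the terminal triplet is not a stop), and `issues` (character).
#' @examples
#' classify_codons("ATGAAATAA")
#' @export
classify_codons <- function(cds, code = mito_genetic_code()) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) abort("cds shorter than two codons")
  start <- substr(cds, 1L, 3L)
  issues <- character(0)
  if (!start %in% code$allowed_starts) {
    issues <- c(issues, paste0("non-canonical start codon ", start))
  }
  rem <- nchar(cds) %% 3L
  if (rem == 0L) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (last %in% code$stops) {
      stop_codon <- last
    } else {
      stop_codon <- NA_character_
      issues <- c(issues, "no terminal stop codon")
    }
  } else {
    stop_codon <- substr(cds, nchar(cds) - rem + 1L, nchar(cds))
    if (!stop_codon %in% c("T", "TA")) {
      issues <- c(issues,
                  paste0("incomplete terminal codon ", stop_codon,
                         " cannot extend to TAA"))
    }
  }
  list(start_codon = start, stop_codon = stop_codon, issues = issues)
}

#' Display form of a stop-codon descriptor
#'
#' Incomplete stops are shown with their polyadenylated completion in
#' parentheses, as characterization tables print them: `"T"` becomes
#' `"T(AA)"` and `"TA"` becomes `"TA(A)"`.
#' @param stop Character vector of stop descriptors.
#' @return Character vector.
#' @export
format_stop_codon <- function(stop) {
  dplyr::case_match(stop, "T" ~ "T(AA)", "TA" ~ "TA(A)", .default = stop)
}

#' Normalize a printed stop-codon cell
#'
#' Inverse of [format_stop_codon()]: strips the parenthesized completion,
#' so `"TA(A)"` becomes `"TA"`.
#' @param stop Character vector as printed.
#' @return Character vector of descriptors (`"T"`, `"TA"`, or a 3-mer).
#' @export
normalize_stop_codon <- function(stop) {
  sub("\\(.*\\)$", "", stop)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
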