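#' Read / write multi-FASTA
#'
#' Thin wrappers over Biostrings. Reading uppercases sequences and errors
#' on duplicate identifiers; order is preserved.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(x))) abort("duplicate FASTA identifiers")
  tibble(name = names(x), sequence = unname(toupper(as.character(x))))
}

#' @rdname read_fasta
#' @param records Tibble with `name`/`sequence` columns, or a named
#'   character vector.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.data.frame(records)) {
    records <- setNames(records$sequence, records$name)
  }
  if (anyDuplicated(names(records))) abort("duplicate FASTA identifiers")
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path, width = 70L)
  invisible(path)
}

#' Construct an alignment block
#'
#' Equal-length gapped sequences over a shared taxon set, with optional
#' per-gene partition ranges (1-based, contiguous, covering the columns).
#'
#' @param seqs Named character vector (taxa -> aligned rows).
#' @param partitions Optional tibble `gene`, `start`, `end`.
#' @return Object of class `alignment_block` with elements `taxa`, `seqs`,
#'   `n_sites`, `partitions`.
#' @export
alignment_block <- function(seqs, partitions = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique taxon names")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) abort("ragged alignment rows")
  if (!is.null(partitions)) {
    partitions <- as_tibble(partitions)
    stopifnot(all(c("gene", "start", "end") %in% names(partitions)))
    covered <- as.integer(unlist(purrr::map2(partitions$start, partitions$end, seq)))
    if (!identical(sort(covered), seq_len(widths[[1]]))) {
      abort("partitions must cover every column exactly once")
    }
  }
  structure(list(taxa = names(seqs), seqs = toupper(seqs),
                 n_sites = unname(widths[[1]]), partitions = partitions),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d taxa x %d sites%s\n",
              length(x$taxa), x$n_sites,
              if (is.null(x$partitions)) "" else
                sprintf(", %d partitions", nrow(x$partitions))))
  invisible(x)
}

# header documenting the settings used downstream by external ML/BI runs
supermatrix_settings_header <- function() {
  c("Concatenated protein-coding supermatrix export.",
    "Suggested downstream settings: ML (RAxML) with 1000 bootstrap",
    "replicates; BI (MrBayes) with 1.0e7 generations, sampling every 1000,",
    "25% burn-in; partition scheme as in the accompanying partition file.")
}

#' Export a supermatrix with partition definitions
#'
#' Writes the alignment in relaxed PHYLIP (`<prefix>.phy`) or NEXUS
#' (`<prefix>.nex`, DATA + SETS blocks) format and, when partitions are
#' present, a RAxML-style partition file (`<prefix>.partitions.txt`) with
#' one charset per gene — or three stride-3 charsets per gene when
#' `by_codon = TRUE`. A small settings sidecar documents the intended
#' downstream ML/BI configuration.
#'
#' @param block An `alignment_block`.
#' @param prefix Output path prefix.
#' @param format `"relaxed_phylip"` or `"nexus"`.
#' @param partitions Write the partition file? (Requires partition ranges.)
#' @param by_codon Split each gene charset by codon position.
#' @return Character vector of the files written, invisibly.
#' @export
write_supermatrix <- function(block, prefix,
                              format = c("relaxed_phylip", "nexus"),
                              partitions = TRUE, by_codon = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(block, "alignment_block"))
  files <- character(0)
  if (format == "relaxed_phylip") {
    path <- paste0(prefix, ".phy")
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(sprintf("%d %d", length(block$taxa), block$n_sites), con)
    writeLines(sprintf("%s  %s", block$taxa, block$seqs[block$taxa]), con)
    files <- c(files, path)
  } else {
    path <- paste0(prefix, ".nex")
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines("#NEXUS", con)
    writeLines(paste0("[", supermatrix_settings_header(), "]"), con)
    writeLines(sprintf("BEGIN DATA;\n  DIMENSIONS NTAX=%d NCHAR=%d;",
                       length(block$taxa), block$n_sites), con)
    writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;\n  MATRIX", con)
    writeLines(sprintf("    %s  %s", block$taxa, block$seqs[block$taxa]), con)
    writeLines("  ;\nEND;", con)
    if (partitions && !is.null(block$partitions)) {
      writeLines("BEGIN SETS;", con)
      writeLines(charset_lines(block$partitions, by_codon, nexus = TRUE), con)
      writeLines("END;", con)
    }
    files <- c(files, path)
  }
  if (partitions && !is.null(block$partitions)) {
    ppath <- paste0(prefix, ".partitions.txt")
    writeLines(charset_lines(block$partitions, by_codon, nexus = FALSE), ppath)
    files <- c(files, ppath)
  }
  spath <- paste0(prefix, ".settings.txt")
  writeLines(supermatrix_settings_header(), spath)
  files <- c(files, spath)
  invisible(files)
}

charset_lines <- function(parts, by_codon, nexus) {
  fmt_one <- function(label, range) {
    if (nexus) sprintf("  CHARSET %s = %s;", label, range)
    else sprintf("DNA, %s = %s", label, range)
  }
  out <- character(0)
  for (i in seq_len(nrow(parts))) {
    g <- parts$gene[i]; a <- parts$start[i]; b <- parts$end[i]
    if (by_codon) {
      for (p in 1:3) {
        out <- c(out, fmt_one(sprintf("%s_pos%d", g, p),
                              sprintf("%d-%d\\3", a + p - 1L, b)))
      }
    } else {
      out <- c(out, fmt_one(g, sprintf("%d-%d", a, b)))
    }
  }
  out
}

#' Read a relaxed-PHYLIP alignment
#'
#' @param path File written by [write_supermatrix()] (names up to 256
#'   characters, whitespace-delimited).
#' @return An `alignment_block` (without partitions).
#' @export
read_relaxed_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  fields <- strsplit(trimws(body), "\\s+")
  seqs <- setNames(vapply(fields, `[[`, "", 2L), vapply(fields, `[[`, "", 1L))
  if (length(seqs) != hdr[1] || any(nchar(seqs) != hdr[2])) {
    abort("PHYLIP dimensions disagree with matrix")
  }
  alignment_block(seqs)
}

#' Read a NEXUS alignment
#'
#' Re-reads NEXUS files written by [write_supermatrix()] (via
#' `ape::read.nexus.data`); charsets in a SETS block are restored as
#' per-gene partitions when present.
#'
#' @param path NEXUS file path.
#' @return An `alignment_block`.
#' @export
read_nexus_alignment <- function(path) {
  dat <- ape::read.nexus.data(path)
  seqs <- vapply(dat, function(x) toupper(paste(x, collapse = "")), "")
  lines <- readLines(path)
  cs <- grep("^\\s*CHARSET\\s", lines, ignore.case = TRUE, value = TRUE)
  parts <- NULL
  if (length(cs) > 0) {
    m <- regmatches(cs, regexec(
      "CHARSET\\s+(\\S+)\\s*=\\s*([0-9]+)-([0-9]+)\\s*;", cs, ignore.case = TRUE))
    keep <- lengths(m) == 4L   # plain per-gene ranges only (no \3 strides)
    if (any(keep)) {
      parts <- tibble(gene = vapply(m[keep], `[[`, "", 2L),
                      start = as.integer(vapply(m[keep], `[[`, "", 3L)),
                      end = as.integer(vapply(m[keep], `[[`, "", 4L)))
    }
  }
  alignment_block(seqs, partitions = parts)
}

#' Write / read Newick trees
#'
#' Wrappers over ape keeping branch lengths and internal node (support)
#' labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional file path; when NULL the Newick string is returned.
#' @return `write_newick()`: the Newick string (invisibly when written to
#'   a file); `read_newick()`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname write_newick
#' @param text Newick string (alternative to `path`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
}
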