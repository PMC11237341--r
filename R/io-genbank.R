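# Minimal but standard GenBank flat-file dialect
# (LOCUS / DEFINITION / FEATURES / ORIGIN). No installed R package parses
# local GenBank flat files, so reader and writer live here; locations use
# the standard forms `a..b`, `complement(...)` for light-strand features
# and `join(a..L,1..b)` for features crossing the circular origin.

gb_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
            control = "D-loop", origin = "rep_origin")
gb_type <- setNames(names(gb_key), gb_key)

gb_location <- function(row, L) {
  loc <- if (row$wraps) {
    sprintf("join(%d..%d,1..%d)", row$start, L, row$end)
  } else {
    sprintf("%d..%d", row$start, row$end)
  }
  if (row$strand == "L") sprintf("complement(%s)", loc) else loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits LOCUS, DEFINITION, FEATURES (source, CDS, tRNA, rRNA, D-loop,
#' rep_origin) and ORIGIN records. CDS features carry `/gene`,
#' `/codon_start=1`, `/transl_table=2`, and a `/note` with the incomplete
#' stop descriptor when the stop is incomplete; tRNAs carry `/anticodon`.
#'
#' @param genome A `mito_genome` with sequence.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$sequence)) abort("genome carries no sequence")
  L <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  locus_name <- if (!is.na(genome$accession)) genome$accession else "MITOGENOME"
  w("LOCUS       %-16s %d bp    DNA     %s VRT 01-JAN-2024",
    locus_name, L, if (genome$circular) "circular" else "linear  ")
  w("DEFINITION  %s mitochondrion, complete genome.",
    if (is.na(genome$taxon)) "unknown organism" else genome$taxon)
  if (!is.na(genome$accession)) w("ACCESSION   %s", genome$accession)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", L)
  if (!is.na(genome$taxon)) {
    w("                     /organism=\"%s\"", genome$taxon)
  }
  w("                     /mol_type=\"genomic DNA\"")
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    row <- f[i, ]
    w("     %-15s %s", gb_key[[row$type]], gb_location(row, L))
    w("                     /gene=\"%s\"", row$name)
    if (row$type == "PCG") {
      w("                     /codon_start=1")
      w("                     /transl_table=2")
      if (!is.na(row$stop_codon) && row$stop_codon %in% c("T", "TA")) {
        w("                     /note=\"incomplete stop codon: %s\"",
          format_stop_codon(row$stop_codon))
      }
    }
    if (row$type == "tRNA" && !is.na(row$anticodon)) {
      w("                     /anticodon=\"%s\"", row$anticodon)
    }
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  for (start in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, start, min(start + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w("%9d %s", start, paste(blocks, collapse = " "))
  }
  w("//")
  invisible(path)
}

parse_gb_location <- function(loc, name = "?") {
  strand <- "H"
  wraps <- FALSE
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    m <- regmatches(parts, regexec("^([0-9]+)\\.\\.([0-9]+)$", parts))
    if (length(parts) != 2L || any(lengths(m) != 3L)) {
      abort(paste0("unparseable join location for feature ", name, ": ", loc))
    }
    start <- as.integer(m[[1]][2])
    end <- as.integer(m[[2]][3])
    wraps <- TRUE
  } else {
    m <- regmatches(loc, regexec("^([0-9]+)\\.\\.([0-9]+)$", loc))[[1]]
    if (length(m) != 3L) {
      abort(paste0("unparseable location for feature ", name, ": ", loc))
    }
    start <- as.integer(m[2]); end <- as.integer(m[3])
  }
  list(start = start, end = end, strand = strand, wraps = wraps)
}

#' Read a GenBank flat file into a mitogenome
#'
#' Parses the dialect written by [write_genbank()] (and the common subset
#' of standard GenBank records): `complement(...)` locations map to strand
#' L, `join(a..L,1..b)` across the origin maps to a wrapping feature, and
#' CDS start/stop codons are derived from the sequence itself (so printed
#' and derived codon cells can be cross-checked). An incomplete-stop
#' `/note` is honored when present.
#'
#' @param path Path to a GenBank flat file.
#' @return A `mito_genome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) abort("not a GenBank flat file: no LOCUS line")
  circular <- grepl("circular", locus[1])
  accession <- NA_character_
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line) > 0) accession <- trimws(sub("^ACCESSION", "", acc_line[1]))
  taxon <- NA_character_
  org <- grep("/organism=", lines, value = TRUE)
  if (length(org) > 0) taxon <- sub('.*?/organism="([^"]*)".*', "\\1", org[1])

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L) abort("GenBank record has no ORIGIN sequence")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at) > 0) end_at[1] else length(lines) + 1L
  seq_lines <- lines[(origin_at[1] + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) abort("GenBank record has an empty sequence")

  feat_at <- grep("^FEATURES", lines)
  rows <- list()
  if (length(feat_at) > 0) {
    block <- lines[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur) || cur$key == "source") return(NULL)
      if (!cur$key %in% names(gb_type)) return(NULL)
      quals <- paste(cur$quals, collapse = " ")
      get_qual <- function(q) {
        m <- regmatches(quals, regexec(paste0('/', q, '="([^"]*)"'), quals))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      name <- get_qual("gene") %||% NA_character_
      if (is.na(name)) name <- get_qual("product")
      loc <- parse_gb_location(cur$loc, name)
      note <- get_qual("note")
      stop_note <- NA_character_
      if (!is.na(note) && grepl("incomplete stop codon:", note)) {
        stop_note <- normalize_stop_codon(trimws(sub(".*incomplete stop codon:", "", note)))
      }
      tibble(name = name, type = gb_type[[cur$key]],
             start = loc$start, end = loc$end, strand = loc$strand,
             start_codon = NA_character_, stop_codon = stop_note,
             anticodon = get_qual("anticodon"), wraps = loc$wraps)
    }
    for (ln in block) {
      if (grepl("^     \\S", ln)) {
        rows <- c(rows, list(flush(cur)))
        key <- sub("^\\s+", "", substr(ln, 1L, 20L))
        key <- strsplit(key, "\\s+")[[1]][1]
        cur <- list(key = key, loc = trimws(substr(ln, 21L, nchar(ln))), quals = character(0))
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else {
          cur$loc <- paste0(cur$loc, txt)
        }
      }
    }
    rows <- c(rows, list(flush(cur)))
  }
  features <- dplyr::bind_rows(rows)
  g <- mito_genome(features, sequence = sequence, taxon = taxon,
                   accession = accession, circular = circular)
  # derive CDS codon metadata from the sequence itself
  f <- g$features
  for (i in which(f$type == "PCG")) {
    cl <- classify_codons(extract_cds(g, f$name[i]))
    f$start_codon[i] <- cl$start_codon
    if (is.na(f$stop_codon[i])) f$stop_codon[i] <- cl$stop_codon
  }
  g$features <- f
  g
}
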