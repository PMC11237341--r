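# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Site counting: each of the three positions of a sense codon carries one
# site, split into synonymous and nonsynonymous fractions according to the
# three single-nucleotide changes at that position; changes that create a
# stop codon are removed from the site mass entirely, so a codon's sites
# sum to 3 minus the stop-adjusted mass. Difference counting for a codon
# pair averages over all orderings of the single-step path between them,
# skipping orderings that pass through a stop codon.

ng_tables <- function(code = mito_genetic_code()) {
  if (!is.null(the$ng)) return(the$ng)
  codons <- ALL_CODONS()
  aa <- code$codon_to_aa
  bases <- c("A", "C", "G", "T")

  site_syn <- setNames(numeric(64), codons)
  site_non <- setNames(numeric(64), codons)
  for (cd in codons) {
    if (aa[[cd]] == "*") { site_syn[cd] <- NA; site_non[cd] <- NA; next }
    s <- n <- 0
    ch <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (aa[[alt]] == "*") next            # stop mass dropped
        if (aa[[alt]] == aa[[cd]]) s <- s + 1 / 3 else n <- n + 1 / 3
      }
    }
    site_syn[cd] <- s; site_non[cd] <- n
  }

  # pairwise path-averaged difference counts
  syn_d <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  non_d <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (c1 in codons) {
    if (aa[[c1]] == "*") next
    for (c2 in codons) {
      if (aa[[c2]] == "*") next
      ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
      diff_pos <- which(ch1 != ch2)
      k <- length(diff_pos)
      if (k == 0L) { syn_d[c1, c2] <- 0; non_d[c1, c2] <- 0; next }
      path_stats <- function(include_stops) {
        acc <- NULL
        for (ord in perms[[as.character(k)]]) {
          cur <- ch1; s <- n <- 0; ok <- TRUE
          for (step in seq_len(k)) {
            p <- diff_pos[ord[step]]
            nxt <- cur; nxt[p] <- ch2[p]
            a1 <- aa[[paste(cur, collapse = "")]]
            a2 <- aa[[paste(nxt, collapse = "")]]
            if (a2 == "*" && step < k && !include_stops) { ok <- FALSE; break }
            if (a1 == a2) s <- s + 1 else n <- n + 1
            cur <- nxt
          }
          if (ok) acc <- rbind(acc, c(s, n))
        }
        acc
      }
      acc <- path_stats(FALSE)
      if (is.null(acc)) acc <- path_stats(TRUE)  # all paths hit a stop: keep all
      syn_d[c1, c2] <- mean(acc[, 1])
      non_d[c1, c2] <- mean(acc[, 2])
    }
  }
  the$ng <- list(site_syn = site_syn, site_non = site_non,
                 syn_d = syn_d, non_d = non_d)
  the$ng
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori site fractions for one sense codon: each position
#' contributes 1/3 of a site per possible change, classified synonymous or
#' nonsynonymous; changes to stop codons are excluded, so the two counts
#' sum to 3 minus the excluded mass.
#'
#' @param codon A sense codon (3-mer).
#' @param code Genetic code.
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @examples
#' codon_site_counts("TTT") # 1/3 synonymous, 8/3 nonsynonymous
#' @export
codon_site_counts <- function(codon, code = mito_genetic_code()) {
  codon <- toupper(codon)
  if (!codon %in% code$sense) abort("codon is not a sense codon under table 2")
  tb <- ng_tables(code)
  c(syn = unname(tb$site_syn[codon]), nonsyn = unname(tb$site_non[codon]))
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka and Ks for an aligned CDS pair
#'
#' Nei-Gojobori counting over the codon pairs of two equal-length, in-frame
#' aligned coding sequences, with Jukes-Cantor distance correction. Codon
#' pairs in which either codon contains a gap or N, or is a stop codon, are
#' removed pairwise (complete deletion per codon). Site totals average the
#' two sequences' per-codon site counts. A proportion of 3/4 or more cannot
#' be corrected and marks the estimate saturated.
#'
#' @param cds_a,cds_b Aligned coding-strand sequences of equal length.
#' @param code Genetic code.
#' @return One-row tibble: `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `ps`, `pn`, `ks`, `ka`, `ka_ks` (NA when Ks is 0 or
#'   saturated), `n_codons`, `saturated`.
#' @export
pairwise_kaks <- function(cds_a, cds_b, code = mito_genetic_code()) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) abort("aligned CDS lengths differ")
  tb <- ng_tables(code)
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  ok <- ca %in% code$sense & cb %in% code$sense
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) abort("no comparable sense codons")
  S <- (sum(tb$site_syn[ca]) + sum(tb$site_syn[cb])) / 2
  N <- (sum(tb$site_non[ca]) + sum(tb$site_non[cb])) / 2
  idx <- cbind(match(ca, ALL_CODONS()), match(cb, ALL_CODONS()))
  Sd <- sum(tb$syn_d[idx]); Nd <- sum(tb$non_d[idx])
  ps <- Sd / S; pn <- Nd / N
  ks <- jc_correct(ps); ka <- jc_correct(pn)
  saturated <- (!is.na(ps) & ps >= 0.75) | (!is.na(pn) & pn >= 0.75)
  tibble(syn_sites = S, nonsyn_sites = N, syn_diffs = Sd, nonsyn_diffs = Nd,
         ps = ps, pn = pn, ks = ks, ka = ka,
         ka_ks = ifelse(!is.na(ks) & !is.na(ka) & ks > 0, ka / ks, NA_real_),
         n_codons = length(ca), saturated = saturated)
}

#' Per-gene Ka/Ks across a taxon set
#'
#' Computes pairwise Ka and Ks for every taxon pair within each gene and
#' aggregates. The default aggregation is the ratio of mean Ka to mean Ks
#' over valid (unsaturated) pairs, which stays defined when individual
#' pairwise Ks estimates are noisy; `method = "mean_ratios"` averages the
#' pairwise ratios instead.
#'
#' @param cds_tbl Tibble with columns `gene`, `taxon`, `cds` (aligned,
#'   equal-length coding sequences within each gene).
#' @param method `"mean_rates"` (default) or `"mean_ratios"`.
#' @param code Genetic code.
#' @return Tibble of class `kaks_estimates`: `gene`, `ka`, `ks`, `ka_ks`,
#'   `n_pairs`, `n_excluded`.
#' @export
gene_kaks <- function(cds_tbl, method = c("mean_rates", "mean_ratios"),
                      code = mito_genetic_code()) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "taxon", "cds") %in% names(cds_tbl)))
  out <- purrr::map_dfr(split(cds_tbl, factor(cds_tbl$gene, levels = unique(cds_tbl$gene))),
    function(g) {
      if (nrow(g) < 2L) abort(paste("gene", g$gene[1], "has fewer than 2 taxa"))
      pairs <- combn(nrow(g), 2L)
      est <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
        pairwise_kaks(g$cds[pairs[1, j]], g$cds[pairs[2, j]], code)
      })
      valid <- !est$saturated & !is.na(est$ka) & !is.na(est$ks)
      ka <- mean(est$ka[valid]); ks <- mean(est$ks[valid])
      ratio <- switch(method,
        mean_rates = if (ks > 0) ka / ks else NA_real_,
        mean_ratios = mean(est$ka_ks[valid & !is.na(est$ka_ks)])
      )
      tibble(gene = g$gene[1], ka = ka, ks = ks, ka_ks = ratio,
             n_pairs = sum(valid), n_excluded = sum(!valid))
    })
  class(out) <- c("kaks_estimates", class(out))
  out
}

#' Per-gene CDS table from a set of annotated genomes
#'
#' Extracts the coding sequence of each protein-coding gene from each
#' genome into the long format consumed by [gene_kaks()] and
#' [concatenate_pcgs()]. Sequences are gap-free; within a gene they are
#' alignment-ready only when equal-length (true for simulator output,
#' which evolves without indels).
#'
#' @param genomes List of `mito_genome` objects with sequence.
#' @return Tibble `gene`, `taxon`, `cds`.
#' @export
pcg_cds_table <- function(genomes) {
  purrr::map_dfr(genomes, function(g) {
    pcg <- g$features$name[g$features$type == "PCG"]
    tibble(gene = pcg, taxon = g$taxon,
           cds = vapply(pcg, function(nm) extract_cds(g, nm), ""))
  })
}
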