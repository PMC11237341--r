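# Synthetic mitogenome generator: a feature-table architecture (default:
# the B. sangzhiensis layout), a T-rich / C-rich heavy-strand composition
# target, and protein-coding constraints (valid starts, complete or
# incomplete terminal stops, no internal stops even across overlapping
# reading frames) define the root genome; sequences then evolve along a
# tree under an HKY-like proposal with per-gene acceptance of
# nonsynonymous changes (probability min(1, omega)), stop-creating changes
# rejected, and neutral evolution outside the PCGs.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Default per-gene dN/dS map for simulation
#'
#' Purifying-selection omegas spanning the heterogeneity seen across
#' mitochondrial PCGs: highest for ATP8, lowest for COI, everything
#' below 1.
#'
#' @return Named numeric vector over the 13 PCGs.
#' @export
default_omega <- function() {
  c(ATP8 = 0.80, ATP6 = 0.45, ND2 = 0.40, ND4 = 0.35, ND3 = 0.30,
    ND5 = 0.30, ND1 = 0.25, ND4L = 0.25, ND6 = 0.25, COII = 0.15,
    Cytb = 0.12, COIII = 0.10, COI = 0.05)
}

#' Simulation specification
#'
#' Bundles everything the generator needs: an architecture (ordered
#' feature table; default is the B. sangzhiensis layout, 16,950 bp, 39
#' features), a heavy-strand composition target (default: the T-biased,
#' C-biased proportions of that genome, giving negative AT and GC skews),
#' a tree with branch lengths in substitutions/site, a
#' transition/transversion ratio, a per-gene omega map, and a seed. All
#' randomness flows from the seed.
#'
#' @param architecture Feature table (see [as_feature_table()]).
#' @param composition Named proportions for A, C, G, T summing to 1.
#' @param tree `phylo` with tip labels and edge lengths.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Named numeric vector, one entry per PCG in the
#'   architecture; values > 0.
#' @param seed Integer seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(architecture = toad_feature_table("sangzhiensis"),
                     composition = c(A = 0.2745, C = 0.2697,
                                     G = 0.1481, T = 0.3077),
                     tree = megophryidae_tree(),
                     kappa = 4, omega = default_omega(), seed = 1L) {
  architecture <- as_feature_table(architecture)
  composition <- composition[c("A", "C", "G", "T")]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-6) {
    abort("composition must name A, C, G, T and sum to 1")
  }
  if (any(omega <= 0)) abort("omega values must be > 0")
  pcg <- architecture$name[architecture$type == "PCG"]
  missing_omega <- setdiff(pcg, names(omega))
  if (length(missing_omega) > 0) {
    omega[missing_omega] <- 0.2
  }
  if (is.unsorted(ifelse(architecture$wraps,
                         architecture$start - max(architecture$end),
                         architecture$start))) {
    abort("architecture features must be in genome order")
  }
  structure(list(architecture = architecture, composition = composition,
                 tree = tree, kappa = kappa, omega = omega,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# coding-strand index -> heavy-strand position
coding_pos <- function(row, i) {
  if (row$strand == "L") row$end - i + 1L else row$start + i - 1L
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# positions (heavy strand) and required heavy-strand bases of the start
# codon and the (possibly incomplete) terminal stop of one PCG
pcg_locked <- function(row, len) {
  start_codon <- if (is.na(row$start_codon)) "ATG" else row$start_codon
  stop_d <- if (is.na(row$stop_codon)) "TAA" else row$stop_codon
  idx <- 1:3
  bases <- strsplit(start_codon, "")[[1]]
  stop_idx <- (len - nchar(stop_d) + 1L):len
  idx <- c(idx, stop_idx)
  bases <- c(bases, strsplit(stop_d, "")[[1]])
  hpos <- vapply(idx, function(i) coding_pos(row, i), integer(1))
  hbase <- if (row$strand == "L") unname(comp_base[bases]) else bases
  list(pos = hpos, base = hbase, stop_len = nchar(stop_d))
}

#' Generate the root synthetic mitogenome
#'
#' Builds a genome realizing the architecture exactly: every feature at
#' its template coordinates, PCGs starting with their template start
#' codon, ending with their template (complete or incomplete) stop, and
#' free of internal stop codons — including within overlapping reading
#' frames, which are repaired jointly. Non-coding positions are drawn iid
#' from the composition target.
#'
#' @param spec A [sim_spec()].
#' @return A `mito_genome` (taxon `"synthetic_root"`).
#' @export
generate_root <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, generate_root_impl(spec))
}

generate_root_impl <- function(spec) {
  f <- spec$architecture
  L <- max(f$end[!f$wraps])
  if (any(f$start < 1L | f$end > L)) abort("infeasible architecture: coordinates exceed genome")
  bases <- names(spec$composition)
  chars <- sample(bases, L, replace = TRUE, prob = spec$composition)
  locked <- logical(L)
  code <- mito_genetic_code()
  pcg <- f[f$type == "PCG", ]
  if (any(pcg$wraps)) abort("wrapping PCGs are not supported by the generator")
  lens <- feature_length(pcg, L)
  for (i in seq_len(nrow(pcg))) {
    lk <- pcg_locked(pcg[i, ], lens[i])
    clash <- locked[lk$pos] & chars[lk$pos] != lk$base
    if (any(clash)) {
      abort(paste("infeasible architecture: codon requirements clash at position",
                  lk$pos[clash][1]))
    }
    chars[lk$pos] <- lk$base
    locked[lk$pos] <- TRUE
  }
  # repair internal stop codons jointly across overlapping frames
  internal_codons <- function(i) {
    len <- lens[i]
    n_complete <- len %/% 3L
    if (len %% 3L == 0L) {
      if (n_complete <= 2L) integer(0) else 2L:(n_complete - 1L)
    } else 2L:n_complete
  }
  get_codon_pos <- function(row, k) {
    vapply(3L * (k - 1L) + 1:3, function(ci) coding_pos(row, ci), integer(1))
  }
  read_codon <- function(row, pos) {
    b <- chars[pos]
    if (row$strand == "L") b <- unname(comp_base[b])
    paste(b, collapse = "")
  }
  for (iter in seq_len(500L)) {
    dirty <- FALSE
    for (i in seq_len(nrow(pcg))) {
      row <- pcg[i, ]
      for (k in internal_codons(i)) {
        pos <- get_codon_pos(row, k)
        if (code$codon_to_aa[[read_codon(row, pos)]] != "*") next
        free <- pos[!locked[pos]]
        if (length(free) == 0L) {
          abort("infeasible architecture: locked positions force an internal stop")
        }
        chars[free] <- sample(bases, length(free), replace = TRUE,
                              prob = spec$composition)
        dirty <- TRUE
      }
    }
    if (!dirty) break
    if (iter == 500L) abort("could not repair internal stops in 500 sweeps")
  }
  mito_genome(f, sequence = paste(chars, collapse = ""),
              taxon = "synthetic_root", accession = "SYN0", circular = TRUE,
              genome_length = L)
}

# static per-genome description used by the mutation kernel
evolve_context <- function(genome, spec) {
  f <- genome$features
  pcg <- f[f$type == "PCG", ]
  lens <- feature_length(pcg, genome$length)
  code <- mito_genetic_code()
  genes <- purrr::map(seq_len(nrow(pcg)), function(i) {
    row <- pcg[i, ]
    len <- lens[i]
    n_complete <- len %/% 3L
    frozen_max <- if (len %% 3L == 0L) n_complete else n_complete + 1L
    list(name = row$name, start = row$start, end = row$end,
         strand = row$strand, len = len, n_complete = n_complete,
         # codon indices whose bases may not change
         frozen_first = 1L, frozen_last = frozen_max,
         omega = min(1, spec$omega[[row$name]]))
  })
  bases <- c("A", "C", "G", "T")
  # proposal weights: target composition x kappa on transitions
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  prop <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (b in bases) {
    for (b2 in setdiff(bases, b)) {
      prop[b, b2] <- spec$composition[[b2]] *
        if (transition[[b]] == b2) spec$kappa else 1
    }
    prop[b, ] <- prop[b, ] / sum(prop[b, ])
  }
  list(genes = genes, prop = prop, bases = bases, code = code)
}

mutate_chars <- function(chars, t, ctx) {
  L <- length(chars)
  n_events <- rpois(1L, L * t)
  if (n_events == 0L) return(chars)
  sites <- sample.int(L, n_events, replace = TRUE)
  u <- runif(n_events)
  for (e in seq_len(n_events)) {
    pos <- sites[e]
    b <- chars[pos]
    if (b == "N") next
    b2 <- sample(ctx$bases, 1L, prob = ctx$prop[b, ])
    accept_p <- 1
    ok <- TRUE
    for (g in ctx$genes) {
      if (pos < g$start || pos > g$end) next
      ci <- if (g$strand == "L") g$end - pos + 1L else pos - g$start + 1L
      k <- (ci - 1L) %/% 3L + 1L
      if (k <= g$frozen_first || k >= g$frozen_last) { ok <- FALSE; break }
      cpos <- 3L * (k - 1L) + 1:3
      hpos <- if (g$strand == "L") g$end - cpos + 1L else g$start + cpos - 1L
      cb <- chars[hpos]
      cb[hpos == pos] <- b2
      if (g$strand == "L") cb <- unname(comp_base[cb])
      codon_new <- paste(cb, collapse = "")
      aa_new <- ctx$code$codon_to_aa[[codon_new]]
      if (aa_new == "*") { ok <- FALSE; break }
      cb_old <- chars[hpos]
      if (g$strand == "L") cb_old <- unname(comp_base[cb_old])
      aa_old <- ctx$code$codon_to_aa[[paste(cb_old, collapse = "")]]
      if (aa_new != aa_old) accept_p <- accept_p * g$omega
    }
    if (ok && u[e] <= accept_p) chars[pos] <- b2
  }
  chars
}

#' Evolve a root genome along a tree
#'
#' Simulates substitutions along each branch (Poisson number of proposal
#' events at the branch's substitutions/site rate) under an HKY-like
#' proposal. Within PCGs, synonymous proposals are always accepted,
#' nonsynonymous ones with probability min(1, omega) for that gene
#' (multiplied across overlapping genes), and proposals creating a stop
#' codon or touching a start/stop codon are rejected; tRNA, rRNA, OL and
#' control-region positions evolve neutrally. Annotations carry over
#' unchanged (no indels, no rearrangements).
#'
#' @param root A `mito_genome` from [generate_root()].
#' @param spec The [sim_spec()]; its `tree` names the leaves and its
#'   `seed` (+1) drives the branch simulation.
#' @return List with `genomes` (named list of leaf `mito_genome`s) and
#'   `tree` (the true tree).
#' @export
evolve_genomes <- function(root, spec) {
  stopifnot(inherits(root, "mito_genome"), inherits(spec, "sim_spec"))
  tree <- spec$tree
  if (is.null(tree$edge.length)) abort("spec tree has no branch lengths")
  with_seed(spec$seed + 1L, {
    ctx <- evolve_context(root, spec)
    ntip <- length(tree$tip.label)
    root_node <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root_node]] <- strsplit(root$sequence, "")[[1]]
    edges <- stats::reorder(tree, "cladewise")
    for (i in seq_len(nrow(edges$edge))) {
      parent <- edges$edge[i, 1]; child <- edges$edge[i, 2]
      seqs[[child]] <- mutate_chars(seqs[[parent]], edges$edge.length[i], ctx)
    }
    genomes <- setNames(vector("list", ntip), tree$tip.label)
    for (tip in seq_len(ntip)) {
      nm <- tree$tip.label[tip]
      genomes[[nm]] <- mito_genome(
        root$features, sequence = paste(seqs[[tip]], collapse = ""),
        taxon = nm, accession = paste0("SYN-", tip), circular = root$circular,
        genome_length = root$length)
    }
    list(genomes = genomes, tree = tree)
  })
}

#' Simulate a complete multi-taxon mitogenome dataset
#'
#' [generate_root()] followed by [evolve_genomes()].
#'
#' @param spec A [sim_spec()].
#' @return List with `root`, `genomes`, `tree`.
#' @export
simulate_dataset <- function(spec = sim_spec()) {
  root <- generate_root(spec)
  ev <- evolve_genomes(root, spec)
  list(root = root, genomes = ev$genomes, tree = ev$tree)
}

#' Simulate a single-gene codon alignment
#'
#' Convenience wrapper for selection analyses: one protein-coding gene of
#' `n_codons` internal codons evolving on a star tree of `n_taxa` leaves
#' at depth `depth` substitutions/site with one omega.
#'
#' @param n_codons Number of internal codons.
#' @param n_taxa Number of leaves.
#' @param omega dN/dS acceptance for the gene.
#' @param depth Root-to-tip branch length (substitutions/site).
#' @param seed Integer seed.
#' @param kappa Transition/transversion ratio.
#' @return Tibble `gene`, `taxon`, `cds` (equal-length, gap-free).
#' @export
simulate_gene_alignment <- function(n_codons, n_taxa, omega, depth = 0.1,
                                    seed = 1L, kappa = 4) {
  len <- 3L * (n_codons + 2L)
  arch <- tibble(name = "G1", type = "PCG", start = 1L, end = len,
                 strand = "H", start_codon = "ATG", stop_codon = "TAA",
                 anticodon = NA_character_)
  tree <- ape::stree(n_taxa, type = "star")
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree$edge.length <- rep(depth, nrow(tree$edge))
  spec <- sim_spec(architecture = arch, tree = tree, kappa = kappa,
                   omega = c(G1 = omega), seed = seed)
  dat <- simulate_dataset(spec)
  pcg_cds_table(dat$genomes)
}
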