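#' Concatenate per-gene alignments into a supermatrix
#'
#' Builds a single concatenated alignment from a long table of per-gene
#' aligned coding sequences, recording per-gene partition ranges. Taxa
#' missing a gene are padded with gaps over that gene's columns and
#' reported in the `padded` attribute.
#'
#' @param cds_tbl Tibble with `gene`, `taxon`, `cds` (equal-length within
#'   each gene).
#' @return An `alignment_block` with per-gene partitions.
#' @export
concatenate_pcgs <- function(cds_tbl) {
  stopifnot(all(c("gene", "taxon", "cds") %in% names(cds_tbl)))
  if (anyDuplicated(cds_tbl[, c("gene", "taxon")])) {
    abort("duplicate gene/taxon combinations")
  }
  genes <- unique(cds_tbl$gene)
  taxa <- unique(cds_tbl$taxon)
  seqs <- setNames(rep("", length(taxa)), taxa)
  parts <- vector("list", length(genes))
  padded <- character(0)
  at <- 1L
  for (gi in seq_along(genes)) {
    g <- cds_tbl[cds_tbl$gene == genes[gi], ]
    w <- unique(nchar(g$cds))
    if (length(w) != 1L) {
      abort(paste("gene", genes[gi], "has rows of unequal length; align first"))
    }
    col <- setNames(g$cds, g$taxon)
    for (tx in taxa) {
      piece <- if (tx %in% names(col)) col[[tx]] else {
        padded <- c(padded, paste0(tx, ":", genes[gi]))
        strrep("-", w)
      }
      seqs[[tx]] <- paste0(seqs[[tx]], piece)
    }
    parts[[gi]] <- tibble(gene = genes[gi], start = at, end = at + w - 1L)
    at <- at + w
  }
  out <- alignment_block(seqs, partitions = dplyr::bind_rows(parts))
  attr(out, "padded") <- padded
  out
}

block_as_DNAbin <- function(block) {
  mat <- do.call(rbind, strsplit(tolower(block$seqs[block$taxa]), ""))
  rownames(mat) <- block$taxa
  ape::as.DNAbin(mat)
}

#' Pairwise distance matrix from an alignment
#'
#' p-distance, JC69, or K2P distances with pairwise deletion of gap/N
#' columns (via `ape::dist.dna`). Saturated (non-finite) entries are kept
#' as `NaN` and flagged.
#'
#' @param block An `alignment_block` (or named character vector of aligned
#'   sequences).
#' @param model `"K2P"`, `"JC69"`, or `"p"`.
#' @return A symmetric numeric matrix with taxa as dimnames; attribute
#'   `saturated` is TRUE if any entry is non-finite.
#' @export
distance_matrix <- function(block, model = c("K2P", "JC69", "p")) {
  model <- match.arg(model)
  if (!inherits(block, "alignment_block")) block <- alignment_block(block)
  if (length(block$taxa) < 2L) abort("need at least 2 taxa")
  dna <- block_as_DNAbin(block)
  ape_model <- c(K2P = "K80", JC69 = "JC69", p = "raw")[[model]]
  d <- ape::dist.dna(dna, model = ape_model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  attr(d, "saturated") <- any(!is.finite(d))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via `ape::nj`). Negative branch lengths —
#' an artifact of NJ's least-squares-like estimates — are clamped to zero
#' with the deficit transferred to the sibling edge, preserving path
#' lengths through the parent node.
#'
#' @param d Symmetric distance matrix with taxon dimnames.
#' @param impute_saturated Replace non-finite entries by 1.25 x the largest
#'   finite distance instead of erroring.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, impute_saturated = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need at least 3 taxa")
  if (any(!is.finite(d))) {
    if (!impute_saturated) {
      abort("distance matrix has saturated (non-finite) entries")
    }
    mx <- max(d[is.finite(d)])
    d[!is.finite(d)] <- 1.25 * mx
    diag(d) <- 0
  }
  clamp_negative_edges(ape::nj(stats::as.dist(d)))
}

clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    i <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[i, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), i)
    deficit <- tree$edge.length[i]
    tree$edge.length[i] <- 0
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
      if (tree$edge.length[sibs[1]] < 0) tree$edge.length[sibs[1]] <- 0
    }
    if (all(tree$edge.length >= 0)) break
  }
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (within partitions, when
#' present, so each gene keeps its width), rebuilds the NJ tree per
#' replicate, and maps bipartition frequencies onto the full-data tree as
#' percentages in `node.label`.
#'
#' @param block An `alignment_block`.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the same seed reproduces the same supports.
#' @param model Distance model (see [distance_matrix()]).
#' @return The full-data NJ `phylo` with `node.label` support percentages
#'   (root label empty) and attribute `replicates`.
#' @export
bootstrap_tree <- function(block, replicates = 100L, seed = 1L,
                           model = "K2P") {
  stopifnot(inherits(block, "alignment_block"))
  if (replicates < 1L) abort("replicates must be >= 1")
  if (length(block$taxa) < 4L) abort("bootstrap needs >= 4 taxa")
  full <- nj_tree(distance_matrix(block, model), impute_saturated = TRUE)
  rows <- strsplit(block$seqs[block$taxa], "")
  mat <- do.call(rbind, rows)
  rownames(mat) <- block$taxa
  groups <- if (is.null(block$partitions)) {
    list(seq_len(block$n_sites))
  } else {
    purrr::map2(block$partitions$start, block$partitions$end, seq)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)))
    sub <- mat[, cols, drop = FALSE]
    seqs <- setNames(apply(sub, 1, paste, collapse = ""), rownames(sub))
    boots[[r]] <- nj_tree(distance_matrix(alignment_block(seqs), model),
                          impute_saturated = TRUE)
  }
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / replicates, 1)
  full$node.label <- as.character(support)
  full$node.label[1] <- ""
  attr(full, "replicates") <- replicates
  full
}

#' Test monophyly of taxon sets
#'
#' Roots the tree on a declared outgroup and checks whether each taxon set
#' forms a clade.
#'
#' @param tree A `phylo`.
#' @param clades Named list of character vectors of taxa.
#' @param outgroup Outgroup taxon used to root the tree.
#' @return Tibble `clade`, `n_taxa`, `monophyletic`.
#' @export
check_clades <- function(tree, clades, outgroup) {
  if (!outgroup %in% tree$tip.label) abort(paste("unknown outgroup:", outgroup))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (is.null(names(clades))) {
    names(clades) <- vapply(clades, function(x) paste(head(x, 2), collapse = "+"), "")
  }
  purrr::imap_dfr(clades, function(taxa, nm) {
    unknown <- setdiff(taxa, tree$tip.label)
    if (length(unknown) > 0) {
      abort(paste("unknown taxa:", paste(unknown, collapse = ", ")))
    }
    tibble(clade = nm, n_taxa = length(taxa),
           monophyletic = length(taxa) == 1L ||
             ape::is.monophyletic(rooted, taxa))
  })
}

#' Robinson-Foulds distance between two topologies
#'
#' @param tree_a,tree_b `phylo` trees over the same taxa.
#' @return Integer RF distance (0 = identical unrooted topologies).
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  as.integer(phangorn::RF.dist(ape::unroot(tree_a), ape::unroot(tree_b)))
}

#' Reference 29-taxon megophryid tree shape
#'
#' The study-shaped topology used as the simulator default: the two
#' subfamily clades (Leptobrachiinae; Megophryinae), monophyletic genera,
#' the two Boulenophrys species groups — B. sangzhiensis with
#' B. omeimontis then B. spinata; B. tuberogranulata with
#' B. jinggangensis, B. boettgeri, B. kuatunensis and B. baishanzuensis —
#' and Microhyla fissipes as outgroup. Branch lengths are in expected
#' substitutions per site, chosen to span realistic mitogenome divergences.
#'
#' @return A `phylo` with 29 tips.
#' @export
megophryidae_tree <- function() {
  txt <- paste0(
    "(Microhyla_fissipes:0.30,(",
    "(((Leptobrachella_alpina:0.12,(Leptolalax_oshanensis:0.08,",
    "Leptolalax_pelodytoides:0.09):0.04):0.05,",
    "((Scutiger_ningshanensis:0.05,Scutiger_liupanensis:0.05):0.07,",
    "((Oreolalax_major:0.04,Oreolalax_xiangchengensis:0.04):0.02,",
    "((Oreolalax_jingdongensis:0.04,Oreolalax_omeimontis:0.05):0.015,",
    "(Oreolalax_multipunctatus:0.04,(Oreolalax_lichuanensis:0.035,",
    "(Oreolalax_schmidti:0.03,Oreolalax_rhodostigmatus:0.03):0.01):0.012):0.015",
    "):0.02):0.06):0.03):0.02,",
    "(Leptobrachium_boringii:0.05,(Leptobrachium_liui:0.045,",
    "(Leptobrachium_ailaonicum:0.04,Leptobrachium_leishanense:0.04):0.012",
    "):0.012):0.09):0.04,",
    "(Brachytarsophrys_carinense:0.10,",
    "((Atympanophrys_shapingensis:0.06,Atympanophrys_gigantica:0.06):0.05,",
    "((Boulenophrys_spinata:0.035,(Boulenophrys_sangzhiensis:0.03,",
    "Boulenophrys_omeimontis:0.03):0.01):0.025,",
    "((Boulenophrys_tuberogranulata:0.03,Boulenophrys_jinggangensis:0.03):0.008,",
    "(Boulenophrys_baishanzuensis:0.028,(Boulenophrys_boettgeri:0.025,",
    "Boulenophrys_kuatunensis:0.025):0.008):0.008):0.025):0.03):0.02):0.05",
    "):0.05);"
  )
  ape::read.tree(text = txt)
}
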