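.acgt <- c("A", "C", "G", "T")

#' Comparable sites of a sequence pair (pairwise deletion)
#'
#' Columns where both sequences carry an unambiguous A/C/G/T. Gaps and
#' IUPAC ambiguity codes are excluded pair by pair, so each pair keeps
#' as many sites as its own data allow (the "pairwise deletion"
#' convention).
#'
#' @param aln an [epf_alignment()].
#' @param i,j taxon labels or row indices (distinct).
#' @return Integer vector of column indices.
#' @export
pairwise_mask <- function(aln, i, j) {
  a <- aln[i, ]
  b <- aln[j, ]
  if (identical(i, j)) stop("pairwise_mask: i and j must differ",
                            call. = FALSE)
  which(a %in% .acgt & b %in% .acgt)
}

#' Base frequencies of an alignment
#'
#' Relative frequencies of A, C, G, T over all unambiguous residues of
#' the alignment (or a subset of rows/columns). Gaps and ambiguity
#' codes are ignored.
#'
#' @param aln an [epf_alignment()] or character matrix.
#' @param rows,cols optional subsets.
#' @return Named numeric vector `(A, C, G, T)` summing to 1.
#' @export
base_frequencies <- function(aln, rows = NULL, cols = NULL) {
  m <- unclass(aln)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  cnt <- vapply(.acgt, function(b) sum(m == b), numeric(1))
  if (sum(cnt) == 0) stop("base_frequencies: no unambiguous residues",
                          call. = FALSE)
  cnt / sum(cnt)
}

# one TN93 log term; coefficient 0 contributes nothing, a non-positive
# log argument signals saturation
.tn93_term <- function(coef, w) {
  if (coef <= 0) return(0)
  if (w <= 0) return(NA_real_)
  -coef * log(w)
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Number of substitutions per site under the TN93 model, which
#' distinguishes the two transition types (purine A/G and pyrimidine
#' C/T) from transversions and allows unequal base frequencies.
#' Computed on the pairwise-deletion mask of the pair.
#'
#' `freq_mode = "pooled"` (default) plugs in alignment-wide base
#' frequencies -- the composite flavor that pools information across
#' all sequences, the spirit of MEGA's maximum-composite-likelihood
#' distances; `"pair"` uses the frequencies of the two sequences alone.
#'
#' Saturated pairs (a logarithm argument at or below zero) cannot yield
#' a finite estimate; they return `saturation_ceiling` with attribute
#' `saturated = TRUE` and a warning.
#'
#' @param aln an [epf_alignment()].
#' @param i,j taxon labels or indices.
#' @param freq_mode `"pooled"` or `"pair"`.
#' @param saturation_ceiling distance reported for saturated pairs
#'   (substitutions/site).
#' @param freqs precomputed pooled frequencies (internal use).
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(aln, i, j, freq_mode = c("pooled", "pair"),
                          saturation_ceiling = 5, freqs = NULL) {
  freq_mode <- match.arg(freq_mode)
  mask <- pairwise_mask(aln, i, j)
  if (length(mask) == 0L) {
    stop("tn93_distance: no comparable sites for this pair", call. = FALSE)
  }
  a <- aln[i, mask]
  b <- aln[j, mask]
  L <- length(mask)
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / L
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / L
  Q <- sum(a != b) / L - P1 - P2
  pi <- if (freq_mode == "pooled") {
    if (is.null(freqs)) base_frequencies(aln) else freqs
  } else {
    f <- table(factor(c(a, b), levels = .acgt))
    as.numeric(f) / sum(f)
  }
  names(pi) <- .acgt
  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  c1 <- if (piR > 0) 2 * pi["A"] * pi["G"] / piR else 0
  c2 <- if (piY > 0) 2 * pi["C"] * pi["T"] / piY else 0
  c3 <- 2 * (piR * piY -
             (if (piR > 0) pi["A"] * pi["G"] * piY / piR else 0) -
             (if (piY > 0) pi["C"] * pi["T"] * piR / piY else 0))
  w1 <- if (c1 > 0) 1 - P1 / c1 - (if (piR > 0) Q / (2 * piR) else 0) else 1
  w2 <- if (c2 > 0) 1 - P2 / c2 - (if (piY > 0) Q / (2 * piY) else 0) else 1
  w3 <- if (c3 > 0) 1 - Q / (2 * piR * piY) else 1
  terms <- c(.tn93_term(c1, w1), .tn93_term(c2, w2), .tn93_term(c3, w3))
  if (anyNA(terms)) {
    warning(sprintf(
      "tn93_distance: saturated pair (%s, %s); reporting ceiling %.3g",
      rownames(aln)[if (is.numeric(i)) i else which(rownames(aln) == i)],
      rownames(aln)[if (is.numeric(j)) j else which(rownames(aln) == j)],
      saturation_ceiling), call. = FALSE)
    return(structure(saturation_ceiling, saturated = TRUE))
  }
  unname(sum(terms))
}

#' TN93 distance matrix of an alignment
#'
#' @inheritParams tn93_distance
#' @return Symmetric matrix of substitutions/site, zero diagonal;
#'   attribute `n_saturated` counts ceiling-capped pairs.
#' @export
tn93_matrix <- function(aln, freq_mode = c("pooled", "pair"),
                        saturation_ceiling = 5) {
  freq_mode <- match.arg(freq_mode)
  n <- nrow(aln)
  taxa <- rownames(aln)
  freqs <- if (freq_mode == "pooled") base_frequencies(aln) else NULL
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      dij <- tn93_distance(aln, i, j, freq_mode = freq_mode,
                           saturation_ceiling = saturation_ceiling,
                           freqs = freqs)
      if (isTRUE(attr(dij, "saturated"))) n_sat <- n_sat + 1L
      d[i, j] <- d[j, i] <- as.numeric(dij)
    }
  }
  attr(d, "n_saturated") <- n_sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `Q_ij = (r - 2) d_ij - R_i - R_j` is joined (ties broken
#' deterministically toward the lowest index pair), branch lengths
#' follow the usual three-point formulas, and the algorithm finishes
#' with a central trifurcation, yielding an unrooted tree. NJ recovers
#' any additive (tree-like) distance matrix exactly.
#'
#' Negative branch-length estimates, which arise from noisy distances,
#' are clamped to zero with the deficit transferred to the adjacent
#' branch of the join so path lengths through the new node are
#' preserved (the Kuhner-Felsenstein convention).
#'
#' @param d symmetric distance matrix with taxon dimnames (n >= 2;
#'   `n = 2` returns the single-edge tree).
#' @return An [ape] `phylo` object with attribute `total_length` (sum
#'   of branch lengths).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("nj_tree: need >= 2 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("nj_tree: distances must be finite",
                               call. = FALSE)
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  if (n == 2L) {
    phy <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
      edge.length = rep(d[1L, 2L] / 2, 2L),
      tip.label = taxa, Nnode = 1L), class = "phylo")
    attr(phy, "total_length") <- sum(phy$edge.length)
    return(phy)
  }
  active <- seq_len(n)          # node ids of live clusters
  D <- d
  next_id <- n + 1L
  parent <- integer(0); child <- integer(0); blen <- numeric(0)
  while (length(active) > 3L) {
    r <- length(active)
    R <- rowSums(D)
    Qm <- (r - 2) * D - outer(R, R, `+`)
    diag(Qm) <- Inf
    Qm[lower.tri(Qm)] <- Inf
    best <- which(Qm == min(Qm), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- D[i, j]; li <- 0 }
    if (lj < 0) { li <- D[i, j]; lj <- 0 }
    parent <- c(parent, next_id, next_id)
    child <- c(child, active[i], active[j])
    blen <- c(blen, li, lj)
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    active <- c(active[keep], next_id)
    next_id <- next_id + 1L
  }
  # central trifurcation over the last three clusters
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  parent <- c(parent, rep(next_id, 3L))
  child <- c(child, active)
  blen <- c(blen, pmax(0, c(la, lb, lc)))
  root <- next_id
  # renumber internals to ape convention: root = n + 1, then the rest
  internals <- c(root, setdiff(sort(unique(parent)), root))
  map <- integer(max(internals))
  map[internals] <- n + seq_along(internals)
  re <- function(v) ifelse(v > n, map[v], v)
  phy <- structure(list(
    edge = cbind(re(parent), re(child)),
    edge.length = blen,
    tip.label = taxa,
    Nnode = length(internals)), class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "total_length") <- sum(phy$edge.length)
  phy
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference TN93 + NJ tree, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the tree for
#' each pseudo-alignment, and reports for every internal edge of the
#' reference tree the percentage of replicate trees containing the same
#' bipartition. Replicates whose distance matrix cannot be computed
#' (e.g. a pair left with no comparable sites) are skipped and the
#' denominator adjusted.
#'
#' @param aln an [epf_alignment()].
#' @param replicates number of bootstrap replicates (default 500).
#' @param seed random seed; the run is bit-reproducible for a fixed
#'   seed.
#' @param freq_mode,saturation_ceiling passed to [tn93_matrix()].
#' @return The reference `phylo` tree with `node.label` set to the
#'   support percentages (root label empty) and attributes
#'   `n_replicates_used`, `seed`.
#' @export
bootstrap_support <- function(aln, replicates = 500, seed = 42,
                              freq_mode = "pooled", saturation_ceiling = 5) {
  if (ncol(aln) < 1L) stop("bootstrap_support: empty alignment",
                           call. = FALSE)
  set.seed(seed)
  ref <- nj_tree(suppressWarnings(
    tn93_matrix(aln, freq_mode, saturation_ceiling)))
  trees <- vector("list", replicates)
  used <- 0L
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(aln), replace = TRUE)
    alnb <- unclass(aln)[, cols, drop = FALSE]
    db <- tryCatch(
      suppressWarnings(tn93_matrix(alnb, freq_mode, saturation_ceiling)),
      error = function(e) NULL)
    if (is.null(db)) next
    used <- used + 1L
    trees[[used]] <- nj_tree(db)
  }
  if (used == 0L) stop("bootstrap_support: all replicates failed",
                       call. = FALSE)
  trees <- trees[seq_len(used)]
  if (used < replicates) {
    warning(sprintf("bootstrap_support: %d of %d replicates skipped",
                    replicates - used, replicates), call. = FALSE)
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / used, 1)
  support[1L] <- NA  # root trifurcation: not a bipartition
  ref$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(ref, "n_replicates_used") <- used
  attr(ref, "seed") <- seed
  attr(ref, "total_length") <- sum(ref$edge.length)
  ref
}

#' Annotate a strain phylogeny with metadata and virulence categories
#'
#' Decorates each leaf with the strain's host order, state and
#' virulence category (as bracketed Newick comments), builds a
#' side-table, and summarizes the composition of major clades so that
#' clade-versus-metadata association (or its absence) can be read off.
#' Clades are obtained by midpoint-rooting the tree and splitting the
#' shallowest internal nodes until `n_clades` groups exist.
#'
#' @param tree a `phylo` object over the strains.
#' @param meta strain metadata data frame (see [validate_tables]); when
#'   `NULL` the plain Newick string is returned unchanged.
#' @param categories optional named vector of virulence categories per
#'   strain (e.g. from [cut_and_label()]`$labels`).
#' @param n_clades number of clades for the composition summary
#'   (default 6).
#' @return If `meta` is `NULL`, a Newick string. Otherwise a list with
#'   `newick` (annotated), `table` (per-strain side table incl. clade),
#'   and `composition` (list of clade x host_order / state / category
#'   count tables).
#' @export
annotate_tree <- function(tree, meta = NULL, categories = NULL,
                          n_clades = 6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(meta)) return(ape::write.tree(tree))
  meta <- validate_strains(meta)
  missing <- setdiff(tree$tip.label, meta$strain_id)
  if (length(missing) > 0L) {
    stop("annotate_tree: taxa without metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rownames(meta) <- meta$strain_id
  tab <- meta[tree$tip.label, c("strain_id", "host_order", "state", "source")]
  tab$category <- if (is.null(categories)) NA_character_ else
    unname(categories[tree$tip.label])
  tab$clade <- .tree_clades(tree, n_clades)[tree$tip.label]
  rownames(tab) <- NULL

  nwk <- ape::write.tree(tree)
  for (k in seq_len(nrow(tab))) {
    note <- sprintf("[&host=%s,state=%s%s]", tab$host_order[k], tab$state[k],
                    if (is.na(tab$category[k])) "" else
                      paste0(",category=", tab$category[k]))
    id_re <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tab$strain_id[k])
    nwk <- sub(paste0("([(,])", id_re, ":"),
               paste0("\\1", tab$strain_id[k], note, ":"), nwk)
  }
  comp <- list(host_order = table(tab$clade, tab$host_order),
               state = table(tab$clade, tab$state))
  if (!is.null(categories)) comp$category <- table(tab$clade, tab$category)
  list(newick = nwk, table = tab, composition = comp)
}

# split a tree into k clades: midpoint-root, then repeatedly replace the
# internal node closest to the root by its children
.tree_clades <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k >= n) {
    return(setNames(paste0("clade", seq_len(n)), tree$tip.label))
  }
  rt <- tryCatch(phangorn::midpoint(tree), error = function(e) tree)
  if (!ape::is.rooted(rt)) rt <- ape::root(rt, outgroup = 1L,
                                           resolve.root = TRUE)
  depth <- ape::node.depth.edgelength(rt)
  root <- n + 1L
  groups <- root
  repeat {
    internal <- groups[groups > n]
    if (length(groups) >= k || length(internal) == 0L) break
    splitme <- internal[which.min(depth[internal])]
    kids <- rt$edge[rt$edge[, 1L] == splitme, 2L]
    groups <- c(setdiff(groups, splitme), kids)
  }
  lab <- setNames(character(n), rt$tip.label)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    tips <- if (g <= n) g else
      unlist(phangorn::Descendants(rt, g, type = "tips"))
    lab[rt$tip.label[tips]] <- paste0("clade", gi)
  }
  lab
}
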