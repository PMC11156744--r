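# shared fixtures and independent oracles used across the suite

# decimal half-up rounding to 1 dp, as values are printed in reports
round1 <- function(x) floor(x * 10 + 0.5) / 10

# small deterministic bioassay table: `dead` is a list of per-replicate
# dead counts per strain, all out of `marked`
make_bioassay <- function(dead, control_dead, day = 7L, marked = 40L) {
  rows <- lapply(names(dead), function(id) {
    data.frame(strain_id = id, replicate = seq_along(dead[[id]]),
               day = day, n_marked = marked, n_dead = dead[[id]],
               stringsAsFactors = FALSE)
  })
  ctrl <- data.frame(strain_id = "CONTROL",
                     replicate = seq_along(control_dead), day = day,
                     n_marked = marked, n_dead = control_dead,
                     stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(ctrl)))
}

# random rooted tree with edge lengths bounded away from zero, and its
# path-length (additive) distance matrix
random_additive <- function(n, seed, min_edge = 0.05, max_edge = 0.5) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), min_edge, max_edge)
  list(tree = tr, d = cophenetic(tr))
}

# exhaustive greedy minimum-variance (Ward) oracle: at every step merge
# the pair of clusters whose union minimizes the increase in total
# within-cluster sum of squares; returns the merge sequence as a list
# of sorted leaf-index sets
ward_oracle_merges <- function(x) {
  x <- as.matrix(x)
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    sub <- x[idx, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_delta <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}

# merge sequence of an hclust object in the same leaf-set form
hclust_merges <- function(hc) {
  sets <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    merged <- sort(c(get(hc$merge[k, 1L]), get(hc$merge[k, 2L])))
    sets[[k]] <- merged
    out[[k]] <- merged
  }
  out
}

# naive textbook UPGMA: average linkage with explicit group means,
# returning the cophenetic matrix
upgma_oracle_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- NULL; best_avg <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_avg - 1e-12) { best_avg <- avg; best <- c(i, j) }
      }
    }
    for (a in clusters[[best[1L]]]) for (b in clusters[[best[2L]]]) {
      coph[a, b] <- coph[b, a] <- best_avg
    }
    clusters <- c(clusters[-best],
                  list(c(clusters[[best[1L]]], clusters[[best[2L]]])))
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# a pair of sequences whose substitution pattern makes TN93 collapse to
# the Jukes-Cantor closed form: equal pooled base composition and
# differences in the ratio P1 : P2 : Q = 1 : 1 : 4
jc_limit_pair <- function() {
  a <- rep(c("A", "C", "G", "T"), 30)  # 120 sites, 30 of each base
  b <- a
  swap <- function(from, to, k) {
    idx <- which(b == from & a == b)[seq_len(k)]
    b[idx] <<- to
  }
  swap("A", "G", 2)  # purine transitions
  swap("C", "T", 2)  # pyrimidine transitions
  swap("G", "C", 2)  # transversions, composition-balancing
  swap("T", "A", 2)
  swap("A", "C", 1)
  swap("C", "A", 1)
  swap("G", "T", 1)
  swap("T", "G", 1)
  epf_alignment(rbind(s1 = a, s2 = b))
}

# bootstrap support (in %) of the bipartition separating `tips` from the
# rest, read off the annotated reference tree
clade_support <- function(tree, tips) {
  node <- ape::getMRCA(tree, tips)
  ntip <- length(tree$tip.label)
  desc <- unlist(phangorn::Descendants(tree, node, type = "tips"))
  if (!setequal(tree$tip.label[desc], tips)) {
    # the clade sits across the root; use the complement instead
    node <- ape::getMRCA(tree, setdiff(tree$tip.label, tips))
  }
  as.numeric(tree$node.label[node - ntip])
}

# alignment of two clearly separated clades joined by a long internal
# edge, plus the (binary, caterpillar-shaped) true tree
two_clade_alignment <- function(n_per_clade = 3, length = 590,
                                internal = 0.4, tip = 0.03, seed = 5) {
  caterpillar <- function(labels) {
    if (length(labels) == 1L) return(labels)
    paste0("(", labels[1L], ":", tip, ",",
           caterpillar(labels[-1L]), ":", tip, ")")
  }
  nwk <- sprintf("(%s:%f,%s:%f);",
                 caterpillar(paste0("a", seq_len(n_per_clade))),
                 internal / 2,
                 caterpillar(paste0("b", seq_len(n_per_clade))),
                 internal / 2)
  tree <- ape::read.tree(text = nwk)
  generate_alignment(seqsim_spec(n_taxa = 2 * n_per_clade,
                                 aln_length = length, tree = tree,
                                 gap_rate = 0, ambiguity_rate = 0,
                                 seed = seed))
}
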