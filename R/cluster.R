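#' Squared Euclidean distance matrix
#'
#' `d(i, j) = sum_k (x_ik - x_jk)^2`, the dissimilarity fed to Ward's
#' clustering. A plain vector (e.g. the BI scalar per strain) is treated
#' as a one-column matrix.
#'
#' @param x numeric matrix (strains x variables) or vector; names or
#'   row names label the strains.
#' @return Symmetric matrix of squared distances with zero diagonal.
#' @export
squared_euclidean <- function(x) {
  if (is.null(dim(x))) {
    x <- matrix(x, ncol = 1L, dimnames = list(names(x), NULL))
  }
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    stop("squared_euclidean: missing or non-finite cells", call. = FALSE)
  }
  as.matrix(dist(x))^2
}

#' Ward minimum-variance linkage on squared Euclidean distances
#'
#' Agglomerative clustering where each merge minimizes the increase in
#' total within-cluster variance, computed by the classical
#' Lance-Williams update applied to squared Euclidean distances
#' ([stats::hclust()] with `method = "ward.D"`). This is the
#' "Ward-on-squared-distances" dialect: merge heights equal twice the
#' within-cluster sum-of-squares increase of the merge, and are
#' nondecreasing. Implementations of "Ward" differ (some expect
#' unsquared distances); this one is pinned down so dendrograms are
#' comparable across software.
#'
#' @param d squared Euclidean distance matrix (from
#'   [squared_euclidean()]) or a `dist` object of squared distances.
#' @return An `hclust` object.
#' @export
ward_linkage <- function(d) {
  d <- as.dist(d)
  if (attr(d, "Size") < 2L) stop("ward_linkage: need >= 2 items",
                                 call. = FALSE)
  hclust(d, method = "ward.D")
}

#' UPGMA (average) linkage
#'
#' Unweighted pair-group average clustering. Merge heights are the mean
#' between-cluster distances, so on ultrametric input the cophenetic
#' distances reconstruct the input exactly; two items at distance `h`
#' merge at cophenetic height `h` (the `hclust` height is `h` as well).
#'
#' @param d distance matrix or `dist` object.
#' @return An `hclust` object.
#' @export
upgma_linkage <- function(d) {
  d <- as.dist(d)
  if (attr(d, "Size") < 2L) stop("upgma_linkage: need >= 2 items",
                                 call. = FALSE)
  hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters and label them by mean bioefficacy
#'
#' Cuts the linkage into `k` groups ([stats::cutree()]), orders the
#' clusters by descending mean BI and assigns the virulence labels HV,
#' GV, V, MV, LV, PV in that order (for `k = 6`; smaller `k` uses the
#' leading labels, larger `k` appends `C7`, `C8`, ...). Cluster numbers
#' produced by the cut are arbitrary, so the report is keyed by the BI
#' ordering instead.
#'
#' @param linkage an `hclust` object over the strains.
#' @param k number of clusters (default 6).
#' @param bi named BI vector, one value per strain (names matching the
#'   linkage labels).
#' @return List of class `epf_clusters` with `labels` (named character
#'   vector per strain) and `report` (data frame: `cluster`, `label`,
#'   `n`, `bi_min`, `bi_max`, `bi_mean`, ordered by descending mean BI).
#' @export
cut_and_label <- function(linkage, k = 6, bi) {
  stopifnot(inherits(linkage, "hclust"))
  n <- length(linkage$labels)
  if (k > n) stop("cut_and_label: k exceeds the number of strains",
                  call. = FALSE)
  groups <- cutree(linkage, k = k)
  bi <- bi[names(groups)]
  if (any(is.na(bi))) stop("cut_and_label: BI missing for some strains",
                           call. = FALSE)
  agg <- data.frame(
    cluster = sort(unique(groups)),
    n = as.integer(table(groups)),
    bi_min = as.numeric(tapply(bi, groups, min)),
    bi_max = as.numeric(tapply(bi, groups, max)),
    bi_mean = as.numeric(tapply(bi, groups, mean))
  )
  agg <- agg[order(-agg$bi_mean), , drop = FALSE]
  lab_pool <- c("HV", "GV", "V", "MV", "LV", "PV",
                if (k > 6) paste0("C", 7:k))
  agg$label <- lab_pool[seq_len(k)]
  agg <- agg[, c("cluster", "label", "n", "bi_min", "bi_max", "bi_mean")]
  rownames(agg) <- NULL
  lab_by_cluster <- setNames(agg$label, agg$cluster)
  structure(list(labels = setNames(lab_by_cluster[as.character(groups)],
                                   names(groups)),
                 report = agg, k = k),
            class = "epf_clusters")
}

#' @export
print.epf_clusters <- function(x, ...) {
  cat("Strain clusters (k =", x$k, "), by descending mean BI:\n")
  print(x$report, digits = 3)
  invisible(x)
}

#' Serialize a dendrogram as Newick
#'
#' The `hclust` tree is converted to a rooted phylogeny
#' ([ape::as.phylo()]) whose branch lengths derive from the merge
#' heights, then written as a Newick string.
#'
#' @param linkage an `hclust` object.
#' @return Newick string (terminated by `;`).
#' @export
linkage_to_newick <- function(linkage) {
  stopifnot(inherits(linkage, "hclust"))
  ape::write.tree(ape::as.phylo(linkage))
}
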