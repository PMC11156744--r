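#' Standardize a feature matrix
#'
#' Centers each variable to mean 0 and scales to variance 1 (denominator
#' `n - 1`). The six screening variables (MG, SP, MO3, MO5, MO7, BI) are
#' measured on different scales, so the PCA operates on standardized
#' data, i.e. on the correlation matrix.
#'
#' @param x numeric matrix or data frame of strains x variables.
#' @return Standardized numeric matrix.
#' @export
standardize_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("standardize_features: non-numeric input",
                           call. = FALSE)
  if (any(!is.finite(x))) {
    stop("standardize_features: missing or non-finite cells", call. = FALSE)
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("standardize_features: constant variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(x)
}

#' Principal component analysis of a strain feature matrix
#'
#' Eigendecomposition of the correlation matrix of the (standardized)
#' features. Scores are the standardized data projected on the
#' eigenvectors. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making biplot quadrants
#' reproducible across platforms.
#'
#' @param x strains x variables matrix or data frame (n >= 3). Row
#'   names, or a `strain_id` column, identify the strains.
#' @param standardize standardize first (default `TRUE`; set `FALSE` if
#'   `x` is already standardized).
#' @return Object of class `epf_pca`: list with `eigenvalues`,
#'   `proportion` and `cumulative` (percent), `eigenvectors`,
#'   `loadings` (variable-component correlations, i.e. eigenvectors
#'   scaled by the square root of the eigenvalues), `scores`, `n`.
#' @export
epf_pca <- function(x, standardize = TRUE) {
  if (is.data.frame(x) && "strain_id" %in% names(x)) {
    rn <- x$strain_id
    x <- x[, setdiff(names(x), c("strain_id", "category")), drop = FALSE]
    rownames(x) <- rn
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("epf_pca: need n >= 3 strains", call. = FALSE)
  xs <- if (standardize) standardize_features(x) else x
  n <- nrow(xs)
  C <- crossprod(xs) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(x), paste0("PC", seq_len(ncol(vecs))))
  scores <- xs %*% vecs
  structure(list(
    eigenvalues = vals,
    proportion = 100 * vals / sum(vals),
    cumulative = cumsum(100 * vals / sum(vals)),
    eigenvectors = vecs,
    loadings = sweep(vecs, 2L, sqrt(vals), `*`),
    scores = scores,
    n = n
  ), class = "epf_pca")
}

#' @export
print.epf_pca <- function(x, ...) {
  cat("PCA of", x$n, "strains,", length(x$eigenvalues), "variables\n")
  print(round(rbind(eigenvalue = x$eigenvalues,
                    `proportion %` = x$proportion,
                    `cumulative %` = x$cumulative), 2))
  invisible(x)
}

#' Components retained by the cumulative-variance rule
#'
#' The smallest leading set of components whose cumulative explained
#' variance reaches `variance_floor` percent (default 70, the floor used
#' to decide which components enter the biplot).
#'
#' @param pca an [epf_pca()] result.
#' @param variance_floor percent of total variance to reach.
#' @return Integer vector of retained component indices.
#' @export
retain_components <- function(pca, variance_floor = 70) {
  stopifnot(inherits(pca, "epf_pca"))
  m <- which(pca$cumulative >= variance_floor)[1L]
  if (is.na(m)) m <- length(pca$eigenvalues)
  seq_len(m)
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal rotation of the retained components' loadings maximizing
#' the varimax simplicity criterion ([stats::varimax()], with Kaiser
#' normalization). Rotation redistributes variance among the retained
#' components but preserves each variable's communality; a single
#' retained component is returned unrotated.
#'
#' @param pca an [epf_pca()] result.
#' @param retained indices of retained components (default: the
#'   70%-variance rule).
#' @return List with `loadings` (rotated), `rotmat`, and `sum_squares`
#'   (variance accounted for by each rotated component).
#' @export
varimax_rotation <- function(pca, retained = retain_components(pca)) {
  stopifnot(inherits(pca, "epf_pca"))
  L <- pca$loadings[, retained, drop = FALSE]
  if (length(retained) < 2L) {
    return(list(loadings = L, rotmat = diag(1), sum_squares = sum(L^2)))
  }
  v <- varimax(L)
  rl <- unclass(v$loadings)
  list(loadings = rl, rotmat = v$rotmat, sum_squares = colSums(rl^2))
}

#' Variable-component correlations with significance flags
#'
#' Pearson correlation between each original variable and the scores of
#' each retained component, with the usual t-approximation on `n - 2`
#' degrees of freedom. A variable is flagged as defining a component
#' when `p <= p_threshold` (default 0.15, a deliberately liberal screen
#' for biplot interpretation).
#'
#' @param x the feature matrix passed to [epf_pca()].
#' @param pca the [epf_pca()] result.
#' @param retained retained component indices.
#' @param p_threshold flag pairs with p at or below this.
#' @return Data frame: `variable`, `component`, `r`, `p`, `significant`.
#' @export
component_correlations <- function(x, pca,
                                   retained = retain_components(pca),
                                   p_threshold = 0.15) {
  if (is.data.frame(x) && "strain_id" %in% names(x)) {
    x <- x[, setdiff(names(x), c("strain_id", "category")), drop = FALSE]
  }
  x <- as.matrix(x)
  out <- expand.grid(variable = colnames(x),
                     component = paste0("PC", retained),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    ct <- cor.test(x[, out$variable[i]], pca$scores[, out$component[i]])
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out$significant <- out$p <= p_threshold
  out
}

#' Rank strains by virulence-oriented first component
#'
#' Orients PC1 so that the mortality/index variables load positively
#' (flipping scores and loadings if needed), then ranks strains by
#' descending PC1 score. The biplot quadrant (sign pattern on PC1/PC2)
#' is reported so that high-virulence strains -- positive on the
#' mortality axis -- can be read off directly.
#'
#' @param pca an [epf_pca()] result with at least two components.
#' @param virulence_vars variables whose PC1 loadings define the
#'   virulence direction (those present are used).
#' @return Data frame ranked by PC1: `strain_id`, `PC1`, `PC2`,
#'   `quadrant` (one of `"++", "+-", "-+", "--"`).
#' @export
select_strains <- function(pca, virulence_vars = c("MO3", "MO5", "MO7", "BI")) {
  stopifnot(inherits(pca, "epf_pca"))
  vars <- intersect(virulence_vars, rownames(pca$loadings))
  flip <- if (length(vars) > 0L &&
              sum(pca$loadings[vars, 1L]) < 0) -1 else 1
  pc1 <- flip * pca$scores[, 1L]
  pc2 <- pca$scores[, 2L]
  ids <- rownames(pca$scores)
  if (is.null(ids)) ids <- paste0("strain_", seq_along(pc1))
  out <- data.frame(
    strain_id = ids, PC1 = pc1, PC2 = pc2,
    quadrant = paste0(ifelse(pc1 >= 0, "+", "-"),
                      ifelse(pc2 >= 0, "+", "-")),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$PC1), , drop = FALSE]
}
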