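#' Z-score a condition-by-feature matrix
#'
#' Centers and scales along the requested axis: `axis = "column"` standardizes
#' each feature over conditions (the usual heat-map scaling); `axis = "row"`
#' standardizes each condition over features. Constant columns/rows (zero SD)
#' are dropped with a warning; an all-constant matrix is an error.
#'
#' @param mat numeric matrix with rownames (condition ids).
#' @param axis `"column"` or `"row"`.
#' @return Z-scored matrix with a `dropped` attribute naming removed entries.
#' @export
zscore_matrix <- function(mat, axis = c("column", "row")) {
  axis <- match.arg(axis)
  m <- if (axis == "row") t(mat) else mat
  sds <- apply(m, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (all(const)) stop("all ", if (axis == "row") "rows" else "columns",
                       " are constant; nothing to z-score")
  dropped <- colnames(m)[const]
  if (any(const)) {
    warning("dropping constant ", if (axis == "row") "row(s): " else "column(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z <- if (axis == "row") t(z) else z
  attr(z, "dropped") <- dropped
  z
}

#' Z-score hierarchical clustering of condition phenotypes
#'
#' Standardizes the feature matrix, then clusters conditions and features
#' agglomeratively (Euclidean distance, average linkage by default). Rows are
#' pre-sorted by condition id so the leaf order is deterministic regardless of
#' input order.
#'
#' @param mat condition-by-feature matrix (rownames = condition ids).
#' @param axis z-score axis, see [zscore_matrix()].
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param k optional number of condition clusters to cut.
#' @return list with `z` (z-matrix), `row_hclust`, `col_hclust`, `row_order`
#'   and `col_order` (leaf orders as labels), and `row_clusters` (when `k`
#'   given).
#' @export
zscore_cluster <- function(mat, axis = "column", distance = "euclidean",
                           linkage = "average", k = NULL) {
  if (nrow(mat) < 2) stop("need at least 2 rows (conditions) to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  z <- zscore_matrix(mat, axis = axis)
  row_h <- stats::hclust(stats::dist(z, method = distance), method = linkage)
  col_h <- if (ncol(z) >= 2) {
    stats::hclust(stats::dist(t(z), method = distance), method = linkage)
  } else NULL
  out <- list(z = z, row_hclust = row_h, col_hclust = col_h,
              row_order = rownames(z)[row_h$order],
              col_order = if (!is.null(col_h)) colnames(z)[col_h$order] else colnames(z))
  if (!is.null(k)) out$row_clusters <- stats::cutree(row_h, k = k)
  out
}

#' t-SNE embedding of condition phenotypes
#'
#' Standardizes the features, initializes from the first two principal
#' components (scaled to SD 1e-4, the conventional deterministic start) and
#' runs exact t-SNE. The same seed always reproduces the same coordinates.
#'
#' @param mat condition-by-feature matrix (rownames = condition ids), e.g.
#'   from [phenotype_matrix()].
#' @param perplexity t-SNE perplexity; requires `nrow(mat) >= 3*perplexity+1`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return `data.frame` with `condition_id`, `x`, `y`; the seed and perplexity
#'   are recorded as attributes.
#' @export
embed_conditions <- function(mat, perplexity = 30, seed = 1L, max_iter = 1000L) {
  n <- nrow(mat)
  if (n < 3 * perplexity + 1) {
    stop("too few conditions (", n, ") for perplexity ", perplexity,
         "; use perplexity <= ", floor((n - 1) / 3))
  }
  z <- zscore_matrix(mat, axis = "column")
  pc <- stats::prcomp(z, rank. = 2)$x
  init <- pc / stats::sd(pc[, 1]) * 1e-4
  fit <- withr::with_seed(as.integer(seed), {
    Rtsne::Rtsne(z, dims = 2, perplexity = perplexity, theta = 0,
                 max_iter = as.integer(max_iter), Y_init = init,
                 pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  })
  out <- data.frame(condition_id = rownames(mat), x = fit$Y[, 1],
                    y = fit$Y[, 2], stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "perplexity") <- perplexity
  out
}

#' Mean silhouette width for a labelled embedding
#'
#' Simple silhouette over Euclidean distances in the embedded plane; positive
#' values mean points sit closer to their own group than to the nearest other
#' group.
#'
#' @param coords numeric matrix / data.frame of coordinates (n x 2).
#' @param labels group labels, length n, at least 2 groups.
#' @return Mean silhouette width.
#' @export
embedding_silhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 groups")
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
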