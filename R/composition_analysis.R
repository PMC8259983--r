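#' Principal component analysis of biomass compositions
#'
#' Components are z-scored by default before the decomposition (demand
#' magnitudes span orders of magnitude, so covariance PCA would be dominated
#' by the largest constituents); `standardize = FALSE` reproduces covariance
#' PCA. Constant components are dropped with a message. When the aerobicity
#' of each condition is supplied, the sign of PC1 is fixed so that aerobic
#' conditions score negative on average, which makes loadings comparable
#' across runs: respiratory cofactors then load negative and constituents
#' favored anaerobically load positive. The rank (Spearman) correlation
#' between PC2 scores and growth rate is reported alongside Pearson's.
#'
#' @param mat condition x component matrix (see [composition_matrix()]).
#' @param standardize z-score components first (default `TRUE`).
#' @param aerobic named/ordered logical vector per condition (defaults to
#'   the matrix's `aerobic` attribute) used for the PC1 sign convention.
#' @param growth named/ordered numeric growth rates (defaults to the
#'   matrix's `growth_rate` attribute).
#' @return list with `scores`, `loadings`, `explained_variance`
#'   (proportions), `pc2_growth_correlation` (list with `spearman`,
#'   `pearson`) and `dropped` (constant components).
#' @export
pca_compositions <- function(mat, standardize = TRUE,
                             aerobic = attr(mat, "aerobic"),
                             growth = attr(mat, "growth_rate")) {
  if (nrow(mat) < 3L || ncol(mat) < 2L) {
    stop("need at least 3 conditions and 2 components for PCA")
  }
  sds <- apply(mat, 2, stats::sd)
  dropped <- character(0)
  keep <- mat
  if (standardize) {
    # z-scoring a constant component is undefined; covariance PCA
    # (standardize = FALSE) keeps them and reports zero variance instead
    dropped <- colnames(mat)[sds == 0]
    keep <- mat[, sds > 0, drop = FALSE]
    if (ncol(keep) < 2L) stop("degenerate input: matrix is (near) constant")
    if (length(dropped)) {
      message("dropping ", length(dropped), " constant component(s): ",
              paste(dropped, collapse = ", "))
    }
  }
  pc <- stats::prcomp(keep, center = TRUE, scale. = standardize)
  scores <- pc$x; loadings <- pc$rotation
  if (!is.null(aerobic) && !anyNA(aerobic)) {
    if (mean(scores[aerobic, 1]) > mean(scores[!aerobic, 1])) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  corr <- list(spearman = NA_real_, pearson = NA_real_)
  if (!is.null(growth) && ncol(scores) >= 2L) {
    corr$spearman <- suppressWarnings(
      stats::cor(scores[, 2], growth, method = "spearman"))
    corr$pearson <- suppressWarnings(stats::cor(scores[, 2], growth))
  }
  list(scores = scores, loadings = loadings, explained_variance = ev,
       pc2_growth_correlation = corr, dropped = dropped)
}

#' Flag outlier (condition, component) demands
#'
#' Each component is z-scored across conditions; pairs with
#' \eqn{|z| >} `z_thresh` are reported together with the log2 fold change of
#' the outlying value against the component's mean. Zero-variance components
#' are skipped.
#'
#' @param mat condition x component matrix.
#' @param z_thresh outlier threshold on the absolute z-score (default 3).
#' @return data.frame with columns `condition_id`, `component_id`, `z`,
#'   `log2fc_vs_mean`, ordered by decreasing `|z|`.
#' @export
find_outliers <- function(mat, z_thresh = 3) {
  mu <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  rows <- list()
  for (j in seq_len(ncol(mat))) {
    if (sds[j] == 0) next
    z <- (mat[, j] - mu[j]) / sds[j]
    hit <- which(abs(z) > z_thresh)
    for (i in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition_id = rownames(mat)[i], component_id = colnames(mat)[j],
        z = z[[i]],
        log2fc_vs_mean = log2(mat[i, j] / mu[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(condition_id = character(0),
                      component_id = character(0), z = numeric(0),
                      log2fc_vs_mean = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

max_normalize <- function(mat) {
  mx <- apply(abs(mat), 2, max)
  keep <- mx > 0
  sweep(mat[, keep, drop = FALSE], 2, mx[keep], `/`)
}

#' Hierarchically cluster condition compositions
#'
#' Outlier conditions are removed, each component is divided by its maximum
#' across the remaining conditions (so every component's range is absorbed),
#' and agglomerative clustering with Ward's linkage is cut at `k` clusters.
#' With `k = "auto"`, `k` is chosen to maximize the gap statistic computed
#' against `B` uniform reference draws over the normalized data's bounding
#' box.
#'
#' @param mat condition x component matrix.
#' @param outliers output of [find_outliers()] (or a character vector of
#'   condition ids) to exclude; `NULL` excludes nothing.
#' @param k number of clusters, or `"auto"` for gap-statistic selection.
#' @param k_range candidate cluster counts for `k = "auto"`.
#' @param B reference draws for the gap statistic.
#' @param seed RNG seed for the reference draws.
#' @param linkage hierarchical linkage method (default `"ward.D2"`).
#' @return list of class `clustering_result`: `labels` (named integer),
#'   `k`, `gap_curve` (data.frame `k`, `gap`, `SE`, or `NULL` for fixed
#'   `k`), `linkage_method`, `normalization`, `excluded_outliers`,
#'   `hclust` (the tree).
#' @export
cluster_conditions <- function(mat, outliers = NULL, k = "auto",
                               k_range = 2:8, B = 50, seed = NULL,
                               linkage = "ward.D2") {
  excl <- character(0)
  if (!is.null(outliers)) {
    excl <- if (is.data.frame(outliers)) unique(outliers$condition_id)
            else unique(outliers)
  }
  keep <- setdiff(rownames(mat), excl)
  x <- max_normalize(mat[keep, , drop = FALSE])
  if (is.numeric(k) && k > nrow(x)) {
    stop("k = ", k, " exceeds the ", nrow(x),
         " conditions left after outlier removal")
  }
  hc_cut <- function(xx, kk) {
    list(cluster = stats::cutree(
      stats::hclust(stats::dist(xx), method = linkage), k = kk))
  }
  gap_curve <- NULL
  if (identical(k, "auto")) {
    k_range <- k_range[k_range <= nrow(x) - 1L]
    if (!length(k_range)) stop("k_range has no feasible entries")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
              add = TRUE)
      set.seed(seed)
    }
    gap <- cluster::clusGap(x, FUNcluster = hc_cut, K.max = max(k_range),
                            B = B, spaceH0 = "original", verbose = FALSE)
    tab <- as.data.frame(gap$Tab)
    gap_curve <- data.frame(k = seq_len(nrow(tab)), gap = tab$gap,
                            SE = tab$SE.sim)
    cand <- gap_curve[gap_curve$k %in% k_range, ]
    # gap optimization via the original one-standard-error rule: the raw
    # argmax is known to over-segment because the curve keeps creeping up
    k <- cand$k[cluster::maxSE(cand$gap, cand$SE,
                               method = "Tibs2001SEmax")]
  }
  labels <- if (k == 1L) {
    stats::setNames(rep(1L, nrow(x)), rownames(x))
  } else {
    stats::setNames(hc_cut(x, k)$cluster, rownames(x))
  }
  structure(list(labels = labels, k = as.integer(k), gap_curve = gap_curve,
                 linkage_method = linkage, normalization = "max",
                 excluded_outliers = excl,
                 hclust = stats::hclust(stats::dist(x), method = linkage)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result> k = ", x$k, " (", x$linkage_method, "), ",
      length(x$labels), " conditions",
      if (length(x$excluded_outliers)) {
        paste0(", ", length(x$excluded_outliers), " outliers excluded")
      } else "", "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Characterize clusters by differentially demanded components
#'
#' For each cluster and component, a two-sided Wilcoxon rank-sum test
#' compares in-cluster against out-of-cluster demands, and the log2 fold
#' change of the cluster mean over the non-cluster mean is computed.
#' Components with \eqn{p <} `p_thresh` and \eqn{|log2fc| >} `lfc_thresh`
#' are marked retained. No multiple-testing correction is applied by
#' default (the stringent fixed threshold takes its place); set
#' `p_adjust_method` to change that. Singleton clusters are skipped with a
#' warning (the rank test is degenerate there).
#'
#' @param mat condition x component matrix (same normalization as used for
#'   clustering).
#' @param labels named cluster labels (e.g. `clustering_result$labels`).
#' @param p_thresh,lfc_thresh retention thresholds (defaults 1e-5, 0.15).
#' @param p_adjust_method method for [stats::p.adjust()]; `"none"` by
#'   default.
#' @return data.frame with columns `cluster`, `component_id`, `log2fc`,
#'   `p`, `retained`.
#' @export
characterize_clusters <- function(mat, labels, p_thresh = 1e-5,
                                  lfc_thresh = 0.15,
                                  p_adjust_method = "none") {
  mat <- mat[names(labels), , drop = FALSE]
  rows <- list()
  for (cl in sort(unique(labels))) {
    inn <- labels == cl
    if (sum(inn) < 2L) {
      warning("cluster ", cl, " has a single member; skipped")
      next
    }
    if (sum(!inn) < 1L) next
    for (j in seq_len(ncol(mat))) {
      a <- mat[inn, j]; b <- mat[!inn, j]
      if (stats::sd(mat[, j]) == 0) {
        p <- 1; lfc <- 0
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
        lfc <- log2(mean(a) / mean(b))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, component_id = colnames(mat)[j], log2fc = lfc, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust_method)
  out$retained <- out$p < p_thresh & abs(out$log2fc) > lfc_thresh
  rownames(out) <- NULL
  out
}

#' Conditional cofactor essentiality matrix
#'
#' A cofactor is conditionally required wherever its (clamped) synthesis
#' demand is positive: respiratory cofactors, for instance, come out
#' required only under aerobic conditions.
#'
#' @param scan an `me_scan` or a condition x component matrix.
#' @param classes component classes to include (default prosthetic groups
#'   and coenzymes).
#' @param clamp demands at or below this count as absent.
#' @return logical matrix, conditions x cofactors.
#' @export
conditional_essentiality <- function(scan,
                                     classes = c("prosthetic", "coenzyme"),
                                     clamp = 1e-12) {
  m <- if (is.matrix(scan)) scan else composition_matrix(scan)
  cls <- attr(m, "component_class")
  if (!is.null(cls)) {
    m <- m[, cls[colnames(m)] %in% classes, drop = FALSE]
  }
  m > clamp
}
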