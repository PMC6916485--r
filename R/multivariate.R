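# Pearson correlation screen with FDR control and Ward minimum-variance
# clustering of standardized biochemical variables.

#' Pairwise Pearson correlation screen
#'
#' Pairwise-complete Pearson product-moment correlations between the chosen
#' variables, two-sided p-values from the t transform
#' `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)`, and BH q-values computed across
#' the strict upper triangle (one family per screen). Pairs whose q falls
#' below the FDR threshold are flagged. A zero-variance variable yields
#' missing entries for its pairs rather than an error.
#'
#' @param data data frame holding the variables.
#' @param variables column names to correlate (default: all numeric columns).
#' @param fdr flagging threshold on q (default 0.10).
#' @return object of class `corr_screen` with matrices `rho`, `p`, `q`, `n`
#'   and logical `flagged`.
#' @export
correlation_screen <- function(data, variables = NULL, fdr = 0.10) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(all(variables %in% names(data)), length(variables) >= 2)
  k <- length(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  for (i in seq_len(k)) {
    n[i, i] <- sum(!is.na(data[[variables[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- data[[variables[i]]]; y <- data[[variables[j]]]
      keep <- !is.na(x) & !is.na(y)
      m <- sum(keep)
      n[i, j] <- n[j, i] <- m
      if (m < 3) next
      if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) next
      r <- stats::cor(x[keep], y[keep])
      rho[i, j] <- rho[j, i] <- r
      tt <- r * sqrt(m - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = m - 2)
    }
  }
  upper <- upper.tri(p)
  q <- matrix(NA_real_, k, k, dimnames = dimnames(p))
  q[upper] <- bh_adjust(p[upper])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  flagged <- !is.na(q) & q < fdr
  structure(list(variables = variables, rho = rho, p = p, q = q, n = n,
                 flagged = flagged, fdr = fdr),
            class = "corr_screen")
}

#' @export
print.corr_screen <- function(x, ...) {
  cat("<corr_screen> ", length(x$variables), " variables, ",
      sum(x$flagged[upper.tri(x$flagged)]), " pair(s) at FDR < ",
      x$fdr * 100, "%\n", sep = "")
  print(round(x$rho, 3))
  invisible(x)
}

#' Long-format export of a correlation screen
#'
#' @param x a `corr_screen`.
#' @param path optional CSV path; when given the table is also written there.
#' @return tibble with one row per unordered variable pair
#'   (`var1, var2, rho, p, q, n, flagged`).
#' @export
corr_long <- function(x, path = NULL) {
  stopifnot(inherits(x, "corr_screen"))
  k <- length(x$variables)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = x$variables[idx[, 1]], var2 = x$variables[idx[, 2]],
    rho = x$rho[idx], p = x$p[idx], q = x$q[idx],
    n = x$n[idx], flagged = x$flagged[idx]
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, na = "")
  out
}

#' Ward minimum-variance clustering of standardized rows
#'
#' Standardizes the chosen variables (mean 0, sample SD 1) and agglomerates
#' rows with Ward's minimum-variance linkage, where the cost of merging two
#' clusters is the increase in the error sum of squares (ESS) over all
#' variables. Merge heights are reported both on the linkage scale and as ESS
#' increments; Ward heights are nondecreasing. Rows with missing values in
#' the chosen variables are dropped (with a message).
#'
#' @param data data frame of observations (e.g. one row per mutant protein).
#' @param variables numeric columns to cluster on (default: all numeric).
#' @param labels leaf labels (default: `rownames`, or a `mutation` column if
#'   present).
#' @param standardize standardize columns first (default TRUE; clustering is
#'   then invariant to variable rescaling).
#' @return object of class `ward_dendrogram`: the merge sequence, linkage
#'   heights, ESS increments, leaf order and the underlying `hclust`.
#' @export
ward_cluster <- function(data, variables = NULL, labels = NULL,
                         standardize = TRUE) {
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  stopifnot(all(variables %in% names(data)))
  x <- as.matrix(as.data.frame(data)[variables])
  if (is.null(labels)) {
    labels <- if (!is.null(data[["mutation"]])) as.character(data$mutation)
    else if (!is.null(rownames(x))) rownames(x) else as.character(seq_len(nrow(x)))
  }
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " incomplete row(s)")
    x <- x[complete, , drop = FALSE]
    labels <- labels[complete]
  }
  if (nrow(x) < 2) stop("need at least 2 complete rows to cluster")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance variable(s): ",
                            paste(variables[sds == 0], collapse = ", "))
    x <- scale(x)
  }
  rownames(x) <- labels
  # ward.D2 linkage heights h relate to the ESS increase as h^2 / 2
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(merge = hc$merge, height = hc$height,
                 ess_increase = hc$height^2 / 2, order = hc$order,
                 labels = labels, hclust = hc, standardized = standardize),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("<ward_dendrogram> ", length(x$labels), " leaves, ",
      length(x$height), " merges; top ESS increase ",
      signif(max(x$ess_increase), 4), "\n", sep = "")
  invisible(x)
}

#' Cut a Ward dendrogram into k clusters
#'
#' @param dendro a `ward_dendrogram`.
#' @param k number of clusters.
#' @return named integer vector of cluster assignments.
#' @export
cut_dendrogram <- function(dendro, k) {
  stopifnot(inherits(dendro, "ward_dendrogram"))
  stats::cutree(dendro$hclust, k = k)
}

#' Export a dendrogram in Newick format
#'
#' @param dendro a `ward_dendrogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  stopifnot(inherits(dendro, "ward_dendrogram"))
  ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  invisible(path)
}
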