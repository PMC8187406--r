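# Plasma screen: internal-standard normalization of targeted MS peak
# areas, pregnancy fold-change classification, row Z-scoring and
# average-linkage clustering under Spearman rank-correlation distance.

#' Sentinel rowname of the spiked internal standard
#' @export
PLASMA_STANDARD_ROW <- "__STANDARD__"

#' Normalize peak areas to the spiked internal standard
#'
#' Every peak area is expressed as a ratio to the internal-standard
#' (e.g. bovine insulin) peak area of the same run, removing run-to-run
#' MS intensity variation. The standard row is removed from the output.
#'
#' @param q numeric matrix, peptides/proteins x animals, containing one
#'   row named by `standard` with strictly positive values.
#' @param standard rowname of the internal standard (default
#'   `"__STANDARD__"`).
#' @return The normalized matrix without the standard row.
#' @export
normalize_to_standard <- function(q, standard = PLASMA_STANDARD_ROW) {
  if (!standard %in% rownames(q))
    stopf("internal-standard row '%s' not found", standard)
  std <- q[standard, ]
  bad <- colnames(q)[is.na(std) | std <= 0]
  if (length(bad))
    stopf("non-positive or missing standard value in column(s): %s",
          paste(bad, collapse = ", "))
  out <- q[setdiff(rownames(q), standard), , drop = FALSE]
  sweep(out, 2L, std, "/")
}

#' Pregnancy fold change of normalized plasma abundances
#'
#' Computes the per-protein fold change of the pregnant (P) over the
#' non-pregnant (NP) group central value and classifies proteins with
#' fold >= `threshold` as higher in pregnancy (the threshold is
#' inclusive). Zeros are replaced by half the smallest positive value in
#' the matrix before computing folds, the standard pseudo-floor that
#' avoids division by zero for proteins undetected in one group.
#'
#' @param normalized numeric matrix from [normalize_to_standard()].
#' @param groups named character vector (names = column names) with
#'   values "NP" or "P".
#' @param threshold classification threshold (> 0; default 1.5).
#' @param central central value: "mean" (default) or "median".
#' @return data.frame per protein: `protein`, `np`, `p` (group central
#'   values), `fold`, `higher_in_pregnancy`.
#' @export
pregnancy_fold_change <- function(normalized, groups, threshold = 1.5,
                                  central = c("mean", "median")) {
  central <- match.arg(central)
  if (threshold <= 0)
    stopf("threshold must be > 0")
  if (!all(colnames(normalized) %in% names(groups)))
    stopf("groups must cover every column")
  g <- groups[colnames(normalized)]
  if (!all(g %in% c("NP", "P")))
    stopf("group labels must be 'NP' or 'P'")
  if (!any(g == "NP") || !any(g == "P"))
    stopf("both NP and P groups must be non-empty")
  pos <- normalized[normalized > 0]
  if (length(pos) && any(normalized == 0))
    normalized[normalized == 0] <- min(pos) / 2
  fun <- if (central == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  np <- fun(normalized[, g == "NP", drop = FALSE])
  p <- fun(normalized[, g == "P", drop = FALSE])
  fold <- p / np
  data.frame(protein = rownames(normalized),
             np = unname(np), p = unname(p), fold = unname(fold),
             higher_in_pregnancy = unname(fold >= threshold),
             stringsAsFactors = FALSE)
}

#' Standardize each row to zero mean and unit standard deviation
#'
#' Uses the population (divide-by-n) standard deviation for
#' bit-reproducibility of heat-map inputs. Constant rows cannot be
#' standardized and map to all zeros with a warning.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return Matrix of row Z-scores.
#' @export
row_zscore <- function(m) {
  if (ncol(m) < 2L)
    stopf("at least 2 columns are required")
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  const <- sd_pop == 0
  if (any(const))
    warnf("%d constant row(s) mapped to zeros", sum(const))
  sd_pop[const] <- 1
  out <- (m - mu) / sd_pop
  out[const, ] <- 0
  out
}

#' Average-linkage clustering under Spearman rank-correlation distance
#'
#' Agglomerative average-linkage (UPGMA-style) clustering with distance
#' d = 1 - Spearman rank correlation, applied to the rows or columns of
#' a matrix, as used for expression heat maps. Ties in inter-cluster
#' distance are broken deterministically by the lexicographically
#' smallest leaf label of the candidate pair, so the merge tree and the
#' leaf order are reproducible. The result is a standard `hclust`
#' object; convert to Newick with [cluster_newick()].
#'
#' @param m numeric matrix.
#' @param axis cluster the "rows" (default) or the "columns".
#' @return Object of class `hclust` (components `merge`, `height`,
#'   `order`, `labels`).
#' @export
hcluster <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  x <- if (axis == "rows") m else t(m)
  if (nrow(x) < 2L)
    stopf("at least 2 vectors are required on the chosen axis")
  if (ncol(x) < 3L)
    stopf("each vector needs at least 3 entries for a Spearman distance")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("v", seq_len(nrow(x)))
  const <- apply(x, 1L, function(v) length(unique(v)) == 1L)
  if (any(const))
    stopf("constant vector(s) have undefined Spearman correlation: %s",
          paste(rownames(x)[const], collapse = ", "))
  d <- 1 - stats::cor(t(x), method = "spearman")
  labels <- rownames(x)
  n <- nrow(x)

  # active-cluster bookkeeping: id < 0 is a leaf, id > 0 a prior merge
  active <- seq_len(n)
  id <- -seq_len(n)
  size <- rep(1L, n)
  minlab <- labels
  D <- d
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    # treat distances within 1e-9 of the minimum as tied so the label
    # tie-break, not floating-point noise, decides the merge
    idx <- which(D <= min(D) + 1e-9, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest (sorted) pair of
    # minimal leaf labels
    keys <- apply(idx, 1L, function(p) {
      lab <- sort(c(minlab[p[1]], minlab[p[2]]))
      paste(lab, collapse = "\r")
    })
    pick <- idx[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    height[step] <- D[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    # average linkage: distance of the merged cluster to every other
    # active cluster is the size-weighted mean of the parts
    others <- setdiff(active, c(i, j))
    newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
      (size[i] + size[j])
    D[i, others] <- newd
    D[others, i] <- newd
    D[j, ] <- Inf
    D[, j] <- Inf
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    members[[i]] <- c(members[[i]], members[[j]])
    id[i] <- step
    active <- setdiff(active, j)
  }

  order_of <- function(k) {
    if (k < 0L) return(-k)
    c(order_of(merge[k, 1L]), order_of(merge[k, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1L), labels = labels,
                 method = "average",
                 dist.method = "1 - spearman",
                 call = match.call()),
            class = "hclust")
}

#' Export a cluster tree in Newick format
#'
#' @param h `hclust` object, e.g. from [hcluster()].
#' @param path optional file path; when omitted the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
cluster_newick <- function(h, path = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
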