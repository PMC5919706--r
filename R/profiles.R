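#' Jaccard distance between binary vectors
#'
#' `1 - |a AND b| / |a OR b|`: the canonical dissimilarity for presence
#' patterns, insensitive to shared absences. Undefined (error) when both
#' vectors are all-zero; the selection stage guarantees this cannot happen
#' for binarized monthly profiles.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Distance in \[0, 1\].
#' @examples
#' jaccard_distance(c(1, 1, 0), c(1, 0, 0))  # 0.5
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  uni <- sum(a | b)
  if (uni == 0L) stop("Jaccard distance undefined for two all-zero vectors")
  1 - sum(a & b) / uni
}

#' Pairwise Jaccard distance matrix of binary profile rows
#'
#' Computed via cross-products (`|a AND b|` from `B %*% t(B)`), which is fast
#' and exactly reproduces the pairwise [jaccard_distance()].
#' @param B 0/1 matrix, observations in rows; no row may be all-zero.
#' @return A `dist` object.
#' @export
jaccard_dist_matrix <- function(B) {
  B <- unclass(B) * 1
  rs <- rowSums(B)
  if (any(rs == 0)) stop("all-zero rows have no Jaccard distance")
  inter <- tcrossprod(B)
  uni <- outer(rs, rs, "+") - inter
  stats::as.dist(1 - inter / uni)
}

#' Cluster binary monthly profiles into mobility profiles
#'
#' Agglomerative hierarchical clustering of the users x months 0/1 occupancy
#' matrix under Jaccard distance, with the dendrogram cut to exactly `k`
#' clusters. Each cluster is a mobility profile: a group of users entering
#' and leaving the target zone on a similar schedule. Clusters are labeled by
#' decreasing size (label 1 = largest; ties broken by earliest member row).
#' Per-cluster monthly in-zone count curves and their z-scored signatures are
#' attached.
#'
#' Linkages: `"average"` (default) and `"complete"` operate directly on the
#' distance matrix; `"ward"` applies the Lance-Williams Ward update to the
#' Jaccard distances as-is — strictly speaking Ward assumes squared Euclidean
#' input, so treat it as a robustness check rather than the primary linkage.
#'
#' @param B A `binary_profiles` matrix from [binarize()] (or any 0/1 matrix
#'   with no all-zero row).
#' @param k Number of profiles to cut (the analysis typically inspects 3-4).
#' @param linkage `"average"`, `"complete"` or `"ward"`.
#' @return A `mobility_profiles` object: list with `labels` (named integer
#'   vector), `k`, `linkage`, `sizes`, `curves` (k x months count matrix),
#'   `signatures` (z-scored curves), `hclust` (the tree), `target_zone`.
#' @export
hierarchical_profiles <- function(B, k, linkage = c("average", "complete",
                                                    "ward")) {
  linkage <- match.arg(linkage)
  Bm <- unclass(B) * 1L
  if (k < 1L || k > nrow(Bm)) stop("k must be in 1..nrow(B)")
  if (k > nrow(unique(Bm)))
    stop("k exceeds the number of distinct profile rows")
  d <- jaccard_dist_matrix(Bm)
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D",
                                         linkage))
  raw <- stats::cutree(hc, k = k)
  # relabel by decreasing size, ties by earliest member row
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(c) which(raw == c)[1L], integer(1))
  ord <- order(-sizes, first)
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- relab[raw]
  names(labels) <- rownames(Bm)
  curves <- profile_curves(labels, Bm)
  structure(list(labels = labels, k = k, linkage = linkage,
                 sizes = tabulate(labels, nbins = k),
                 curves = curves,
                 signatures = zscore_signature(curves),
                 hclust = hc,
                 target_zone = attr(B, "target_zone")),
            class = "mobility_profiles")
}

#' @export
print.mobility_profiles <- function(x, ...) {
  cat(sprintf("mobility_profiles: k = %d (%s linkage)%s; sizes: %s\n",
              x$k, x$linkage,
              if (is.null(x$target_zone)) "" else
                paste0(", target zone ", x$target_zone),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Per-cluster monthly in-zone count curves
#'
#' `curve_c(m)` = number of cluster-c members with a 1 at month m; the sum of
#' the curves over clusters equals the column sums of `B`.
#' @param labels Integer cluster labels, one per row of `B`.
#' @param B The 0/1 profile matrix.
#' @return k x months integer matrix (row c = cluster c's curve).
#' @export
profile_curves <- function(labels, B) {
  Bm <- unclass(B) * 1L
  k <- max(labels)
  curves <- matrix(0L, nrow = k, ncol = ncol(Bm),
                   dimnames = list(paste0("profile", seq_len(k)), NULL))
  for (c in seq_len(k))
    curves[c, ] <- colSums(Bm[labels == c, , drop = FALSE])
  curves
}

#' Mean silhouette width per candidate k
#'
#' Descriptive aid for choosing the cut (no automatic selection is done):
#' for each k the partition's mean silhouette under the Jaccard distances.
#' @param B 0/1 profile matrix.
#' @param ks Candidate cluster counts (default 2:6).
#' @param linkage Linkage passed to [hierarchical_profiles()].
#' @return data.frame `k, mean_silhouette`.
#' @export
silhouette_by_k <- function(B, ks = 2:6, linkage = "average") {
  D <- as.matrix(jaccard_dist_matrix(B))
  out <- vapply(ks, function(k) {
    lab <- hierarchical_profiles(B, k, linkage)$labels
    s <- vapply(seq_along(lab), function(i) {
      own <- lab == lab[i]; own[i] <- FALSE
      a <- if (any(own)) mean(D[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(c) mean(D[i, lab == c]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = out)
}

#' Serialize a profile dendrogram as a newick string
#'
#' Text export of the clustering tree (merge heights as branch lengths),
#' convenient for archiving the dendrogram alongside tabular outputs.
#' Requires the `ape` package.
#' @param profiles A `mobility_profiles` object.
#' @return Newick string.
#' @export
profile_dendrogram_newick <- function(profiles) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for newick export")
  ape::write.tree(ape::as.phylo(profiles$hclust))
}
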