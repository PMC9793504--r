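#' Agglomerative clustering of a distance matrix
#'
#' Hierarchical agglomeration on the precomputed dissimilarity matrix.
#' `"complete"` linkage (the default) merges by the maximum pairwise
#' distance between cluster members; `"ward"` uses the dissimilarity-based
#' Ward update (`ward.D2`), which on a non-Euclidean Optimal Matching
#' matrix is a heuristic rather than a variance decomposition.
#'
#' @param D Square symmetric distance matrix with zero diagonal (row names
#'   are the individual ids).
#' @param linkage `"complete"` or `"ward"`.
#' @return An [stats::hclust] tree.
#' @export
agglomerate <- function(D, linkage = c("complete", "ward")) {
  linkage <- match.arg(linkage)
  check_distance_matrix(D)
  method <- if (linkage == "ward") "ward.D2" else "complete"
  stats::hclust(stats::as.dist(D), method = method)
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0) || any(D < 0)) {
    stop("D must be symmetric and nonnegative with a zero diagonal",
         call. = FALSE)
  }
  invisible(D)
}

#' Cut a dendrogram into k clusters
#'
#' Labels are renumbered by decreasing cluster size, so cluster 1 is
#' always the largest group (the reference cluster for downstream
#' characterization). Ties in size are broken by order of first
#' appearance.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `cluster_solution` object; see [cluster_solution()].
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in 1..", n, call. = FALSE)
  raw <- stats::cutree(tree, k = k)
  relabel_solution(raw, method = paste0("hclust/", tree$method),
                   ids = tree$labels)
}

relabel_solution <- function(raw, method, ids = names(raw)) {
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  labels <- map[raw]
  if (is.null(ids)) ids <- as.character(seq_along(raw))
  cluster_solution(tibble::tibble(id = ids, cluster = labels), method)
}

#' Construct a cluster solution
#'
#' @param labels Tibble with columns `id` and `cluster` (integers `1..k`,
#'   numbered by decreasing cluster size).
#' @param method Description of the procedure that produced the labels.
#' @param asw Optional average silhouette width.
#' @param curve Optional model-selection curve (tibble `k`, `asw`,
#'   `min_size`, `feasible`).
#' @return An object of class `cluster_solution`.
#' @export
cluster_solution <- function(labels, method, asw = NA_real_, curve = NULL) {
  stopifnot(all(c("id", "cluster") %in% names(labels)))
  k <- max(labels$cluster)
  sizes <- as.integer(table(factor(labels$cluster, levels = seq_len(k))))
  if (any(diff(sizes) > 0)) {
    stop("cluster labels must be numbered by decreasing size", call. = FALSE)
  }
  structure(list(labels = labels, method = method, k = k, sizes = sizes,
                 asw = asw, curve = curve), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> ", x$method, ", k = ", x$k, "\n", sep = "")
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.na(x$asw)) cat(sprintf("average silhouette width: %.3f\n", x$asw))
  invisible(x)
}

#' @export
tidy.cluster_solution <- function(x, ...) x$labels

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$k, n = sum(x$sizes),
                 min_size = min(x$sizes), asw = x$asw)
}

#' Partitioning around medoids on a distance matrix
#'
#' Build and swap phases of the PAM algorithm on the precomputed
#' dissimilarities, delegated to [cluster::pam]. Deterministic given `D`.
#'
#' @param D Square symmetric distance matrix.
#' @param k Number of clusters.
#' @return A `cluster_solution` (labels renumbered by decreasing size)
#'   with an extra element `medoids` (ids of the medoids).
#' @export
pam_clusters <- function(D, k) {
  check_distance_matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must be in 1..", n, call. = FALSE)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k == n) {
    # degenerate solution: every point its own medoid, total cost 0
    out <- cluster_solution(tibble::tibble(id = ids, cluster = seq_len(n)),
                            "pam")
    out$medoids <- ids
    return(out)
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, cluster.only = FALSE)
  out <- relabel_solution(fit$clustering, method = "pam", ids = ids)
  out$medoids <- fit$medoids
  out
}

#' Silhouette widths of a partition
#'
#' For each individual, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where
#' `a(i)` is the mean distance to the other members of its own cluster
#' and `b(i)` the smallest mean distance to another cluster. Members of
#' singleton clusters get `s(i) = 0`.
#'
#' @param D Square symmetric distance matrix.
#' @param labels Integer cluster labels (vector aligned with `D`, or a
#'   tibble with `id` and `cluster` columns).
#' @return A list with `widths` (tibble `id`, `cluster`, `neighbor`,
#'   `width`) and `asw` (the average silhouette width).
#' @export
silhouette_width <- function(D, labels) {
  check_distance_matrix(D)
  labels <- labels_vector(labels, D)
  k <- length(unique(labels))
  if (k < 2) stop("silhouette needs at least 2 clusters", call. = FALSE)
  n <- nrow(D)
  cl <- sort(unique(labels))
  ind <- vapply(cl, function(c) as.numeric(labels == c), numeric(n))
  sizes <- colSums(ind)
  sums <- D %*% ind                      # n x k total distance to clusters
  own <- match(labels, cl)
  a <- numeric(n)
  for (j in seq_along(cl)) {
    rows <- own == j
    a[rows] <- if (sizes[j] > 1) sums[rows, j] / (sizes[j] - 1) else NA_real_
  }
  means <- sweep(sums, 2, sizes, "/")
  means[cbind(seq_len(n), own)] <- Inf   # exclude own cluster from b
  b <- apply(means, 1, min)
  neighbor <- cl[apply(means, 1, which.min)]
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  list(widths = tibble::tibble(id = ids, cluster = labels,
                               neighbor = neighbor, width = s),
       asw = mean(s))
}

labels_vector <- function(labels, D) {
  if (is.data.frame(labels)) {
    ids <- rownames(D)
    if (!is.null(ids) && all(ids %in% labels$id)) {
      labels <- labels$cluster[match(ids, labels$id)]
    } else {
      labels <- labels$cluster
    }
  }
  if (length(labels) != nrow(D)) {
    stop("labels do not align with the distance matrix", call. = FALSE)
  }
  as.integer(labels)
}

#' Select the number of clusters by silhouette and minimum cluster size
#'
#' Evaluates every `k` in `k_range` on the dendrogram and applies the
#' two-part selection criterion:
#'
#' * size rule: a partition is feasible when all its clusters hold at
#'   least `round(min_frac * n)` individuals (about 1% of participants,
#'   i.e. 25 of 2271);
#' * silhouette rule: increasing `k` must not distinctly decrease the
#'   average silhouette width. A candidate `k` is vetoed when its ASW
#'   falls more than `asw_drop` below the best ASW among candidate
#'   partitions with `3 <= k' <= k` — a distinct drop signals that the
#'   extra split halves a coherent group. (The `k = 2` solution is not
#'   used as the reference: splitting off the single most distant group
#'   always inflates the silhouette without saying anything about finer
#'   structure.)
#'
#' The largest `k` passing both rules is returned — the most detailed
#' typology whose groups are all large enough to characterize — and the
#' full ASW-vs-k curve is reported so the choice can be inspected and
#' overridden explicitly. If no `k` qualifies, `k = 2` is returned with
#' a warning.
#'
#' @param tree An [stats::hclust] tree from [agglomerate()].
#' @param D The distance matrix the tree was built from.
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param min_frac Minimum cluster size as a fraction of `n`
#'   (default 0.011).
#' @param asw_drop Largest tolerated decrease of the average silhouette
#'   width below the running best (default 0.05).
#' @return A `cluster_solution` with the selection curve attached.
#' @export
select_solution <- function(tree, D, k_range = 2:10, min_frac = 0.011,
                            asw_drop = 0.05) {
  check_distance_matrix(D)
  n <- nrow(D)
  stopifnot(length(k_range) > 0, all(k_range >= 2), all(k_range <= n))
  k_range <- sort(k_range)
  threshold <- round(min_frac * n)
  rows <- purrr::map_dfr(k_range, function(k) {
    sol <- cut_clusters(tree, k)
    sil <- silhouette_width(D, sol$labels)
    tibble::tibble(k = k, asw = sil$asw, min_size = min(sol$sizes),
                   feasible = min(sol$sizes) >= threshold)
  })
  anchor <- cummax(ifelse(rows$k >= 3, rows$asw, -Inf))
  rows$admissible <- rows$feasible & rows$asw >= anchor - asw_drop
  feas <- rows[rows$admissible, ]
  if (nrow(feas) == 0) {
    warning("no k in range satisfies the size and silhouette rules; ",
            "falling back to k = 2", call. = FALSE)
    best_k <- 2L
  } else {
    best_k <- max(feas$k)
  }
  sol <- cut_clusters(tree, best_k)
  sol$asw <- rows$asw[rows$k == best_k]
  sol$curve <- rows
  sol$size_threshold <- threshold
  sol
}
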