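#' Kullback-Leibler ensemble distance between two cells
#'
#' Pools the two cells' posterior ensembles in per-pair standardized log10
#' parameter space and asks how separable they are by nearest-neighbor
#' identity: for every particle, does its nearest neighbor belong to the same
#' cell? The observed two-category distribution (same-cell / other-cell,
#' aggregated over both cells) is compared against the analytic permutation
#' null - the hypergeometric expectation under random reassignment of cell
#' identities - via the Kullback-Leibler divergence. Fully overlapping
#' ensembles give a distance near zero; fully separated ensembles approach
#' the maximal two-category divergence for the given sizes.
#'
#' @param ens_i,ens_j `parameter_ensemble`s or particle matrices with equal
#'   column count.
#' @param pseudo Pseudo-count added to each category before forming the
#'   observed proportions (default 0.5), preventing infinite divergences for
#'   perfectly separated ensembles.
#' @param standardize `"pair"` z-scores using the pooled pair's statistics
#'   (default; a pair's distance does not depend on unrelated cells),
#'   `"none"` uses coordinates as given.
#' @return Nonnegative scalar distance (nats).
#' @export
kl_distance <- function(ens_i, ens_j, pseudo = 0.5,
                        standardize = c("pair", "none")) {
  standardize <- match.arg(standardize)
  xi <- if (inherits(ens_i, "parameter_ensemble")) ens_i$particles else
    as.matrix(ens_i)
  xj <- if (inherits(ens_j, "parameter_ensemble")) ens_j$particles else
    as.matrix(ens_j)
  if (ncol(xi) != ncol(xj)) stop("ensembles have different dimensionality")
  ni <- nrow(xi); nj <- nrow(xj)
  if (ni < 2 || nj < 2) stop("ensembles must have at least 2 particles")
  n <- ni + nj
  pooled <- rbind(xi, xj)
  if (standardize == "pair") {
    mu <- colMeans(pooled)
    sdv <- apply(pooled, 2, sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    pooled <- sweep(sweep(pooled, 2, mu), 2, sdv, "/")
  }
  ids <- rep(c(1L, 2L), c(ni, nj))
  same <- sum(nn_same_prob_cpp(pooled, ids))
  p_obs <- (same + pseudo) / (n + 2 * pseudo)
  # permutation null: particle from a cell of size m has (m-1)/(n-1) chance
  # that a random other particle shares its identity
  p_null <- (ni * (ni - 1) + nj * (nj - 1)) / (n * (n - 1))
  p_obs * log(p_obs / p_null) + (1 - p_obs) * log((1 - p_obs) / (1 - p_null))
}

#' Pairwise ensemble distance matrix
#'
#' @param ensembles List of `parameter_ensemble`s (or matrices). Names (or
#'   ensemble `cell_id`s) become the matrix dimnames.
#' @param ... Passed to [kl_distance()].
#' @return Symmetric matrix of class `ensemble_dist` with zero diagonal.
#' @export
ensemble_distance_matrix <- function(ensembles, ...) {
  m <- length(ensembles)
  stopifnot(m >= 2)
  ids <- names(ensembles)
  if (is.null(ids))
    ids <- vapply(seq_along(ensembles), function(i) {
      e <- ensembles[[i]]
      if (inherits(e, "parameter_ensemble")) as.character(e$cell_id) else
        paste0("cell", i)
    }, character(1))
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    d[i, j] <- d[j, i] <- kl_distance(ensembles[[i]], ensembles[[j]], ...)
  }
  class(d) <- c("ensemble_dist", "matrix")
  d
}

# medoid of a set of indices under distance matrix d
.medoid <- function(d, idx) idx[which.min(rowSums(d[idx, idx, drop = FALSE]))]

#' Cluster cells by ensemble distance
#'
#' Average-linkage hierarchical clustering on the KL ensemble distance
#' matrix. The tree is cut at each candidate number of clusters k and scored
#' by a distance-based Calinski-Harabasz criterion,
#' \eqn{CH(k) = (B/(k-1)) / (W/(n-k))}; the k maximizing CH is selected.
#' With `ch_method = "pairwise"` (default) the within-dispersion is the
#' average pairwise squared distance inside each cluster,
#' \eqn{W = \sum_c \sum_{i<j \in c} d_{ij}^2 / n_c}, which equals the classic
#' summed squared deviation from the centroid when the distances are
#' Euclidean, and \eqn{B = T - W} with T the same quantity over the pooled
#' set. With `ch_method = "medoid"` dispersion is measured against cluster
#' medoids (within: summed squared distance of members to their medoid;
#' between: size-weighted squared distance of cluster medoids to the overall
#' medoid); this variant degenerates at desk-scale n - singleton-heavy
#' partitions drive W to zero and the criterion to the k boundary - so it is
#' not the default.
#'
#' @param dmat Distance matrix from [ensemble_distance_matrix()] (any
#'   symmetric nonnegative matrix works).
#' @param k_range Candidate cluster counts (default 2:10). The scan is
#'   additionally capped at `floor(n/2)`: partitions dominated by singleton
#'   clusters have vanishing within-dispersion and blow the criterion up at
#'   the boundary regardless of structure.
#' @return Object of class `cluster_assignment`: `labels` (named integer
#'   vector), `k`, `linkage` (the hclust tree), `ch_curve` (named numeric),
#'   `medoids` (per-cluster representative ids), `degenerate` (TRUE when the
#'   matrix carries no structure, in which case k = 1), `weak` (TRUE when the
#'   criterion shows no strong interior maximum: the best score sits at the
#'   top of the scanned range or barely rises above the curve's median).
#' @param ch_method `"pairwise"` (default) or `"medoid"`; see Details.
#' @export
cluster_ensembles <- function(dmat, k_range = 2:10,
                              ch_method = c("pairwise", "medoid")) {
  ch_method <- match.arg(ch_method)
  d <- unclass(dmat)
  n <- nrow(d)
  stopifnot(isSymmetric(unname(d)), all(d >= 0), n >= 2)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("cell", seq_len(n))
  if (all(d == 0)) {
    labels <- stats::setNames(rep(1L, n), ids)
    return(structure(list(labels = labels, k = 1L, linkage = NULL,
                          ch_curve = numeric(0), medoids = ids[1],
                          degenerate = TRUE, weak = TRUE),
                     class = "cluster_assignment"))
  }
  k_range <- k_range[k_range >= 2 & k_range <= max(2, floor(n / 2))]
  stopifnot(length(k_range) >= 1)
  tree <- hclust(as.dist(d), method = "average")
  ch <- stats::setNames(numeric(length(k_range)), k_range)
  all_labels <- vector("list", length(k_range))
  overall_medoid <- .medoid(d, seq_len(n))
  total_disp <- sum(d^2) / (2 * n)
  for (t in seq_along(k_range)) {
    k <- k_range[t]
    lab <- cutree(tree, k = k)
    W <- 0; B <- 0
    for (c in unique(lab)) {
      idx <- which(lab == c)
      if (ch_method == "pairwise") {
        W <- W + sum(d[idx, idx]^2) / (2 * length(idx))
      } else {
        m <- .medoid(d, idx)
        W <- W + sum(d[idx, m]^2)
        B <- B + length(idx) * d[m, overall_medoid]^2
      }
    }
    if (ch_method == "pairwise") B <- max(total_disp - W, 0)
    ch[t] <- if (W == 0) Inf else (B / (k - 1)) / (W / (n - k))
    all_labels[[t]] <- lab
  }
  best <- which.max(ch)
  k <- k_range[best]
  labels <- stats::setNames(all_labels[[best]], ids)
  medoids <- vapply(seq_len(k), function(c) ids[.medoid(d, which(labels == c))],
                    character(1))
  finite_ch <- ch[is.finite(ch)]
  weak <- best == length(k_range) ||
    (length(finite_ch) > 1 &&
       max(finite_ch) < 1.2 * stats::median(finite_ch))
  structure(list(labels = labels, k = k, linkage = tree, ch_curve = ch,
                 medoids = medoids, degenerate = FALSE, weak = weak),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k=%d over %d cells%s\n", x$k,
              length(x$labels), if (x$degenerate) " (degenerate)" else ""))
  print(table(x$labels))
  invisible(x)
}

#' Between/within variance ratio
#'
#' Ratio of between-group to within-group dispersion for per-cell vectors
#' (e.g. ensemble-mean parameter vectors, or trace feature vectors) under a
#' clustering. Dispersion is the total sum of squared Euclidean deviations
#' from group means; the ratio is B/W.
#'
#' @param x Numeric matrix, one row per cell.
#' @param labels Cluster labels, one per row.
#' @return Scalar ratio; `Inf` when within-dispersion is zero; NA (with a
#'   warning) when every cluster is a singleton.
#' @export
variance_ratio <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  groups <- split(seq_len(nrow(x)), labels)
  if (length(groups) < 2) stop("need at least 2 clusters")
  if (all(lengths(groups) == 1L)) {
    warning("all clusters are singletons; ratio undefined")
    return(NA_real_)
  }
  gm <- colMeans(x)
  W <- 0; B <- 0
  for (idx in groups) {
    cm <- colMeans(x[idx, , drop = FALSE])
    W <- W + sum(sweep(x[idx, , drop = FALSE], 2, cm)^2)
    B <- B + length(idx) * sum((cm - gm)^2)
  }
  if (W == 0) Inf else B / W
}

#' Between/within dispersion ratio from a distance matrix
#'
#' Distance-space analogue of [variance_ratio()], used to compare how well a
#' clustering separates cells in two different representations (e.g. the KL
#' ensemble-distance space against the Euclidean trace space). Within-
#' dispersion is the average pairwise squared distance inside each cluster,
#' total dispersion the same over the pooled set, and the ratio is
#' \eqn{(T - W) / W}.
#'
#' @param dmat Symmetric distance matrix.
#' @param labels Cluster labels, one per row of `dmat`.
#' @return Scalar ratio; `Inf` when W is zero.
#' @export
dispersion_ratio <- function(dmat, labels) {
  d <- unclass(dmat)
  n <- nrow(d)
  stopifnot(n == length(labels), isSymmetric(unname(d)))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  total <- sum(d^2) / (2 * n)
  W <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    W <- W + sum(d[idx, idx]^2) / (2 * length(idx))
  }
  if (W == 0) Inf else (total - W) / W
}

#' Characterize clusters mechanistically
#'
#' Per-cluster parameter summaries (median and interquartile range of pooled
#' particles across member cells) and a per-parameter separation score: the
#' standard deviation of cluster medians divided by the mean within-cluster
#' particle standard deviation. High-ranking parameters are the ones driving
#' the split between cell states.
#'
#' @param ensembles List of `parameter_ensemble`s (or matrices), one per cell.
#' @param labels Cluster labels, one per cell.
#' @return Object of class `cluster_characterization`: `medians` (k x p),
#'   `iqrs` (k x p), `separation` (named, sorted decreasing), `ranking`
#'   (parameter names by decreasing separation).
#' @export
characterize_clusters <- function(ensembles, labels) {
  stopifnot(length(ensembles) == length(labels))
  mats <- lapply(ensembles, function(e)
    if (inherits(e, "parameter_ensemble")) e$particles else as.matrix(e))
  p <- ncol(mats[[1]])
  pn <- colnames(mats[[1]])
  if (is.null(pn)) pn <- paste0("p", seq_len(p))
  cls <- sort(unique(labels))
  med <- matrix(NA_real_, length(cls), p, dimnames = list(cls, pn))
  iqr <- med
  wsd <- med
  for (t in seq_along(cls)) {
    pool <- do.call(rbind, mats[labels == cls[t]])
    med[t, ] <- apply(pool, 2, median)
    iqr[t, ] <- apply(pool, 2, function(v) diff(quantile(v, c(.25, .75))))
    wsd[t, ] <- apply(pool, 2, sd)
  }
  sep <- apply(med, 2, sd) / pmax(colMeans(wsd), 1e-12)
  sep <- sort(sep, decreasing = TRUE)
  structure(list(medians = med, iqrs = iqr, separation = sep,
                 ranking = names(sep)),
            class = "cluster_characterization")
}

#' @export
print.cluster_characterization <- function(x, ...) {
  cat("<cluster_characterization> top separating parameters:\n")
  print(round(utils::head(x$separation, 5), 3))
  invisible(x)
}
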