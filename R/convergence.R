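#' Dual-run convergence test
#'
#' Decides whether two independent ABC-SMC runs on the same cell sampled the
#' same posterior. Both runs are pooled and z-scored per coordinate; for every
#' particle the nearest neighbor (self excluded; exact ties - duplicate
#' particles - contribute their group's same-run fraction) is found and its
#' run identity tabulated. If the two runs sample
#' one distribution, a particle's nearest neighbor is (almost) equally likely
#' to come from either run; the observed same-run count is compared to that
#' null by a chi-square goodness-of-fit test with one degree of freedom. The
#' runs are convergent when the test fails to reject.
#'
#' @param run1,run2 `parameter_ensemble`s (or plain particle matrices with
#'   identical column count).
#' @param alpha Significance level (default 0.05).
#' @param null_p `"exact"` uses the finite-sample same-run probability under
#'   permutation (for each particle of run r, (n_r - 1)/(n - 1));
#'   `"half"` uses the idealized 0.5.
#' @param variance `"permutation"` (default) computes the exact variance of
#'   the same-run count under random relabeling conditional on the realized
#'   nearest-neighbor digraph (counting mutual pairs and shared-neighbor
#'   overlaps), which calibrates the test at its nominal level;
#'   `"multinomial"` uses the naive independent-count variance, which
#'   overstates significance because nearest-neighbor identities are
#'   positively dependent.
#' @return Object of class `convergence_report`: `p_same_run`, `chi2`,
#'   `p_value`, `converged`, `n1`, `n2`, `expected_p`.
#' @export
test_convergence <- function(run1, run2, alpha = 0.05,
                             null_p = c("exact", "half"),
                             variance = c("permutation", "multinomial")) {
  null_p <- match.arg(null_p)
  variance <- match.arg(variance)
  x1 <- if (inherits(run1, "parameter_ensemble")) run1$particles else
    as.matrix(run1)
  x2 <- if (inherits(run2, "parameter_ensemble")) run2$particles else
    as.matrix(run2)
  if (ncol(x1) != ncol(x2)) stop("runs have different dimensionality")
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 20 || n2 < 20) stop("each run needs at least 20 particles")
  if (max(n1, n2) / min(n1, n2) > 4)
    warning("grossly unequal run sizes (> 4:1); null probability distorted")
  n <- n1 + n2
  pooled <- rbind(x1, x2)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1   # constant coordinate carries no info
  z <- sweep(sweep(pooled, 2, mu), 2, sdv, "/")
  ids <- rep(c(1L, 2L), c(n1, n2))
  same <- sum(nn_same_prob_cpp(z, ids))   # expected count under tie-break

  expected_same <- if (null_p == "exact")
    n1 * (n1 - 1) / (n - 1) + n2 * (n2 - 1) / (n - 1)
  else n / 2
  v <- if (variance == "permutation")
    .nn_perm_variance(nn_index_cpp(z), n1, n2)
  else {
    p <- expected_same / n
    n * p * (1 - p)
  }
  chi2 <- (same - expected_same)^2 / max(v, 1e-12)
  p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(p_same_run = same / n, chi2 = chi2, p_value = p_value,
                 converged = p_value >= alpha, n1 = n1, n2 = n2,
                 alpha = alpha, expected_p = expected_same / n),
            class = "convergence_report")
}

# Exact variance of the same-identity nearest-neighbor count under random
# relabeling (n1 of one identity, n2 of the other), conditional on the
# realized NN digraph i -> nn[i]. T = sum_i 1[label(nn_i) = label(i)] is a
# sum of pairwise label-agreement indicators; its second moment decomposes
# over ordered pairs of edges by how many distinct vertices they span:
# 2 (the same or a mutual pair), 3 (one shared vertex), or 4 (disjoint).
.nn_perm_variance <- function(nn, n1, n2) {
  n <- n1 + n2
  selfs <- which(nn == seq_len(n))   # duplicate groups can elect themselves
  edges <- setdiff(seq_len(n), selfs)
  ne <- length(edges)
  if (ne < 2) return(1e-12)
  a <- nn[edges]
  # label-agreement probabilities for 2, 3, 4 distinct items
  p2 <- (n1 * (n1 - 1) + n2 * (n2 - 1)) / (n * (n - 1))
  p3 <- (n1 * (n1 - 1) * (n1 - 2) + n2 * (n2 - 1) * (n2 - 2)) /
    (n * (n - 1) * (n - 2))
  p22 <- (n1 * (n1 - 1) * (n1 - 2) * (n1 - 3) +
            n2 * (n2 - 1) * (n2 - 2) * (n2 - 3) +
            2 * n1 * (n1 - 1) * n2 * (n2 - 1)) /
    (n * (n - 1) * (n - 2) * (n - 3))
  # mutual edges: i -> j and j -> i (both in the non-self edge set)
  has <- !is.na(match(a, edges))     # target is itself an edge-bearing vertex
  mut <- sum(nn[a[has]] == edges[has])   # ordered mutual count
  # shared-target pairs: ordered pairs with a_i = a_j, i != j
  indeg <- tabulate(a, nbins = n)
  shared_target <- sum(indeg * (indeg - 1))
  # chains: j = a_i with a_j != i (and symmetric case), targets must be
  # edge-bearing vertices
  chain <- sum(nn[a[has]] != edges[has])
  c3 <- shared_target + 2 * chain
  c2 <- mut                       # ordered mutual pairs
  c4 <- ne * (ne - 1) - c2 - c3
  e_t <- ne * p2
  e_t2 <- ne * p2 + c2 * p2 + c3 * p3 + c4 * p22
  max(e_t2 - e_t^2, 1e-12)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> p_same_run=%.3f (null %.3f), chi2=%.3f, p=%.4f -> %s\n",
    x$p_same_run, x$expected_p, x$chi2, x$p_value,
    if (x$converged) "convergent" else "NOT convergent"))
  invisible(x)
}
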