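test_that("kl_distance equals the brute-force oracle at n = 20 + 20", {
  set.seed(101)
  for (rep_ in 1:3) {
    xi <- matrix(rnorm(20 * 4, 0, 1), 20, 4)
    xj <- matrix(rnorm(20 * 4, rep_ * 0.5), 20, 4)
    expect_equal(kl_distance(xi, xj), brute_kl_oracle(xi, xj),
                 tolerance = 1e-12)
  }
})

test_that("identical-distribution ensembles concentrate near zero distance", {
  set.seed(102)
  base <- idealized_ensemble(rep(0, 17), 150, 0.1)
  same <- idealized_ensemble(rep(0, 17), 150, 0.1)
  d_same <- kl_distance(base, same)
  # permutation-null reference distribution: shuffle pooled rows
  pooled <- rbind(base, same)
  d_null <- replicate(59, {
    idx <- sample.int(300)
    kl_distance(pooled[idx[1:150], ], pooled[idx[151:300], ])
  })
  expect_lt(d_same, quantile(d_null, 0.95))
  expect_gte(d_same, 0)
})

test_that("distance saturates at the closed-form two-category KL when separated", {
  set.seed(103)
  n <- 100
  xi <- matrix(rnorm(n * 3), n, 3)
  xj <- matrix(rnorm(n * 3) + 20, n, 3)   # 10+ pooled SDs
  d <- kl_distance(xi, xj)
  p_obs <- (2 * n + 0.5) / (2 * n + 1)    # every NN is same-cell
  p_null <- (2 * n * (n - 1)) / ((2 * n) * (2 * n - 1))
  expect_equal(d, p_obs * log(p_obs / p_null) +
                 (1 - p_obs) * log((1 - p_obs) / (1 - p_null)),
               tolerance = 1e-12)
})

test_that("distance increases monotonically with ensemble separation", {
  # n = 400 particles: a 1-pooled-SD shift on one of 17 coordinates is near
  # the NN estimator's detection floor at smaller sizes
  set.seed(104)
  base <- idealized_ensemble(rep(0, 17), 400, 0.1)
  d <- vapply(c(0, 1, 2, 5), function(k) {
    shifted <- idealized_ensemble(c(k * 0.1, rep(0, 16)), 400, 0.1)
    kl_distance(base, shifted)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("distance matrix is symmetric, zero-diagonal, nonnegative", {
  set.seed(105)
  ens <- lapply(1:4, function(i) idealized_ensemble(rnorm(17, 0, 0.3), 60))
  dm <- ensemble_distance_matrix(ens)
  expect_true(isSymmetric(unname(unclass(dm))))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_true(all(dm >= 0))
})

test_that("three synthetic regimes are recovered as k = 3 with matching labels", {
  pop <- balanced_population(per_regime = 4, seed = 61)
  set.seed(62)
  ens <- lapply(seq_len(12), function(i)
    idealized_ensemble(pop$thetas[i, ], n = 200, spread = 0.2))
  names(ens) <- sprintf("cell%02d", 1:12)
  cl <- cluster_ensembles(ensemble_distance_matrix(ens))
  expect_identical(cl$k, 3L)
  expect_false(cl$weak)
  expect_gte(label_agreement(cl$labels, pop$truth), 0.95)
  # d-constants drive the separation by construction
  ch <- characterize_clusters(ens, cl$labels)
  expect_setequal(ch$ranking[1:3], c("d1", "d5", "dinh"))
})

test_that("two regimes give k = 2; a single cloud is flagged weak", {
  regs <- feedback_regimes()
  set.seed(64)
  th2 <- rbind(
    do.call(rbind, lapply(1:6, function(i) rnorm(17, regs[[1]]$offsets, 0.1))),
    do.call(rbind, lapply(1:6, function(i) rnorm(17, regs[[2]]$offsets, 0.1))))
  ens2 <- lapply(1:12, function(i) idealized_ensemble(th2[i, ], 200, 0.2))
  cl2 <- cluster_ensembles(ensemble_distance_matrix(ens2))
  expect_identical(cl2$k, 2L)
  expect_gte(label_agreement(cl2$labels, rep(1:2, each = 6)), 0.95)
  set.seed(63)
  ens1 <- lapply(1:12, function(i)
    idealized_ensemble(rnorm(17, 0, 0.05), 200, 0.25))
  cl1 <- cluster_ensembles(ensemble_distance_matrix(ens1))
  expect_true(cl1$weak)
})

test_that("clustering is invariant to cell ordering", {
  pop <- balanced_population(per_regime = 3, seed = 66)
  set.seed(67)
  ens <- lapply(seq_len(9), function(i)
    idealized_ensemble(pop$thetas[i, ], 150, 0.2))
  names(ens) <- sprintf("c%02d", 1:9)
  set.seed(68); cl <- cluster_ensembles(ensemble_distance_matrix(ens))
  perm <- c(5, 9, 1, 7, 3, 8, 2, 6, 4)
  set.seed(68); clp <- cluster_ensembles(ensemble_distance_matrix(ens[perm]))
  expect_identical(clp$k, cl$k)
  expect_gte(label_agreement(clp$labels[names(cl$labels)], cl$labels), 1)
})

test_that("a zero distance matrix is degenerate with k = 1", {
  dm <- matrix(0, 5, 5)
  cl <- cluster_ensembles(dm)
  expect_identical(cl$k, 1L)
  expect_true(cl$degenerate)
})

test_that("variance ratio has its closed form and a permutation null", {
  # two point-clusters at separation delta with within-SD sigma: B/W ~ (delta/sigma)^2 * n/4
  set.seed(106)
  sigma <- 0.05; delta <- 2
  x <- rbind(matrix(rnorm(20 * 3, 0, sigma), 20, 3),
             matrix(rnorm(20 * 3, delta / sqrt(3), sigma), 20, 3))
  lab <- rep(1:2, each = 20)
  vr <- variance_ratio(x, lab)
  expect_equal(vr, 40 * delta^2 / 4 / (2 * 20 * 3 * sigma^2),
               tolerance = 0.25)
  # zero within-spread diverges
  x0 <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  expect_identical(variance_ratio(x0, rep(1:2, each = 5)), Inf)
  # permuted labels: ratio collapses toward the no-structure level
  vr_perm <- replicate(30, variance_ratio(x, sample(lab)))
  expect_lt(median(vr_perm), vr / 100)
  expect_error(variance_ratio(x, rep(1, 40)), "2 clusters")
  expect_warning(variance_ratio(x[1:2, ], 1:2), "singleton")
})

test_that("parameter-space clustering separates better than trace clustering", {
  # compare the two clustering spaces the pipeline can operate in: KL
  # distances between posterior ensembles vs Euclidean distances between the
  # noisy calcium traces themselves
  pop <- balanced_population(per_regime = 4, seed = 71)
  set.seed(72)
  ens <- lapply(seq_len(12), function(i)
    idealized_ensemble(pop$thetas[i, ], 100, 0.2))
  rend <- render_traces(pop$thetas, stimulus_protocol(duration = 480),
                        noise_spec(), seed = 73)
  lab <- as.integer(factor(pop$truth))
  d_kl <- ensemble_distance_matrix(ens)
  d_tr <- as.matrix(dist(rend$traces))
  expect_gt(dispersion_ratio(d_kl, lab), dispersion_ratio(d_tr, lab))
  expect_error(dispersion_ratio(d_kl, rep(1, 12)), "2 clusters")
})

test_that("characterization: no-difference regimes give flat separation scores", {
  set.seed(73)
  ens <- lapply(1:9, function(i) idealized_ensemble(rep(0, 17), 100, 0.2))
  ch <- characterize_clusters(ens, rep(1:3, each = 3))
  # no parameter should stand out: scores stay near the noise level
  expect_lt(max(ch$separation), 0.5)
  # cluster medians recover the (common) generating center
  expect_lt(max(abs(ch$medians)), 0.1)
})
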