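test_that("score has its closed forms and matches a brute-force oracle", {
  cfg <- score_config(deriv_weight = 1)
  x <- c(0.1, 0.5, 0.9, 0.7, 0.4)
  expect_equal(score_trace(x, x, cfg), 0)
  # constant offset: derivative term vanishes, score = n * c^2
  expect_equal(score_trace(x + 0.3, x, cfg), length(x) * 0.3^2)
  expect_equal(score_trace(x + 0.3, x, score_config(5)), length(x) * 0.3^2)
  # random pair vs an independently coded double loop
  set.seed(61)
  a <- runif(40); b <- runif(40)
  w <- 1.7
  brute <- 0
  for (i in 1:40) brute <- brute + (a[i] - b[i])^2
  for (i in 1:39) brute <- brute +
    w * ((a[i + 1] - a[i]) - (b[i + 1] - b[i]))^2
  expect_equal(score_trace(a, b, score_config(w)), brute)
  expect_error(score_trace(a, b[1:10]), "grid")
})

test_that("with epsilon = Inf the rejection sampler reproduces its prior", {
  set.seed(71)
  d <- 3
  res <- rejection_sample(function(m) matrix(runif(m * d, -1, 1), m, d),
                          function(th) sum(th^2), Inf, 2000)
  expect_identical(res$status, "ok")
  expect_identical(res$n_proposed, 2000L)
  for (j in seq_len(d))
    expect_gt(ks.test(res$particles[, j], "punif", -1, 1)$p.value, 0.01)
})

test_that("1-D toy posterior matches the analytic truncated distribution", {
  set.seed(72)
  theta_star <- 0.3
  res <- rejection_sample(function(m) matrix(runif(m, -1, 1), m, 1),
                          function(th) abs(th - theta_star), 0.1, 1000,
                          max_proposals = 1e5)
  expect_identical(res$status, "ok")
  expect_true(all(abs(res$particles - theta_star) <= 0.1))
  expect_gt(ks.test(res$particles[, 1], "punif", theta_star - 0.1,
                    theta_star + 0.1)$p.value, 0.01)
})

test_that("unreachable thresholds are reported, not fatal", {
  res <- rejection_sample(function(m) matrix(runif(m, -1, 1), m, 1),
                          function(th) 1 + th[1]^2, epsilon = 0.5, n = 10,
                          max_proposals = 500)
  expect_identical(res$status, "threshold unreachable")
  expect_lt(nrow(res$particles), 10)
})

test_that("SMC threshold schedule is monotone and hits epsilon_final", {
  # cheap 17-D toy score so the full loop runs in milliseconds; the 90%
  # schedule shrinks the threshold only a few percent per iteration in 17-D,
  # hence the generous iteration cap
  f <- fit_cell(NULL, epsilon_final = 2,
                cfg = smc_config(n_particles = 200, max_iterations = 80),
                score_fn = function(th) sum(th^2), seed = 81)
  expect_true(f$fitted)
  expect_true(all(diff(f$thresholds) <= 1e-12))
  expect_true(all(f$scores <= 2))
  expect_true(all(abs(f$particles) <= 1))
  # reproducibility under the seed
  g <- fit_cell(NULL, 2, smc_config(n_particles = 200,
                                    max_iterations = 80),
                score_fn = function(th) sum(th^2), seed = 81)
  expect_identical(f$particles, g$particles)
})

test_that("non-fitted ensembles are flagged when max_iterations runs out", {
  f <- fit_cell(NULL, epsilon_final = 1e-8,
                cfg = smc_config(n_particles = 50, max_iterations = 3),
                score_fn = function(th) sum(th^2), seed = 82)
  expect_false(f$fitted)
})

test_that("2-parameter ABC posterior matches a dense grid-search region", {
  # reduced model: only d5 and dinh free, data = noiseless reference trace
  proto <- stimulus_protocol(atp = 10, t_on = 0, duration = 300, dt_out = 2)
  vals <- simulate_trace(rep(0, 17), proto)$values
  sfn2 <- function(th2) {
    th <- rep(0, 17); th[2:3] <- th2
    score_trace(simulate_trace(th, proto), vals)
  }
  E <- 20; ng <- 13
  edges <- seq(-1, 1, length.out = ng + 1)
  # a grid box is accepted when any of 5 probe points scores <= E, so any
  # box holding an accepted particle is in-region by witness
  probe <- function(i, j) {
    xs <- edges[i] + c(.5, .1, .9, .1, .9) * (edges[i + 1] - edges[i])
    ys <- edges[j] + c(.5, .1, .1, .9, .9) * (edges[j + 1] - edges[j])
    any(mapply(function(x, y) sfn2(c(x, y)) <= E, xs, ys))
  }
  grid_in <- outer(seq_len(ng), seq_len(ng), Vectorize(probe))
  set.seed(9)
  f <- fit_cell(NULL, E, smc_config(n_particles = 1000,
                                    max_iterations = 40),
                score_fn = function(th) sfn2(th), free = 2:3, seed = 10)
  expect_true(f$fitted)
  bx <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE),
                              1), ng)
  occ <- matrix(FALSE, ng, ng)
  for (r in seq_len(nrow(f$particles)))
    occ[bx(f$particles[r, 1]), bx(f$particles[r, 2])] <- TRUE
  jac <- sum(occ & grid_in) / sum(occ | grid_in)
  expect_gte(jac, 0.9)
})
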