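test_that("edge-wise ANCOVA F matches hand ANOVA and the lm oracle", {
  # three groups [1,2,3],[2,3,4],[3,4,5]: SSB = 6, SSW = 6, df 2/6 -> F = 3
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  set.seed(30)
  Y <- cbind(vals, matrix(runif(9 * 5), 9))
  b <- toy_bundle(Y[, 1:3], n_regions = 3)
  des <- design_spec(rep(c("g1", "g2", "g3"), each = 3))
  st <- edgewise_ancova(b, "theta", des)
  expect_equal(st$f[1], 3.0, tolerance = 1e-10)
  expect_equal(st$df_between, 2L)
  expect_equal(st$df_error, 6L)

  # independent oracle: anova(lm()) per edge, with covariates
  set.seed(31)
  n <- 24
  grp <- rep(c("a", "b", "c", "d"), each = 6)
  cov <- data.frame(age = rnorm(n, 60, 5), z = runif(n))
  Y2 <- matrix(rnorm(n * 6), n)
  b2 <- toy_bundle(Y2, n_regions = 4)
  des2 <- design_spec(grp, cov)
  st2 <- edgewise_ancova(b2, "theta", des2)
  f_oracle <- apply(Y2, 2, function(y) {
    full <- lm(y ~ factor(grp) + age + z, data = cov)
    red <- lm(y ~ age + z, data = cov)
    av <- anova(red, full)
    av$F[2]
  })
  expect_equal(st2$f, f_oracle, tolerance = 1e-10)
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(32)
  n <- 20
  grp <- rep(c("a", "b"), each = 10)
  Y <- matrix(rnorm(n * 10), n)
  b <- toy_bundle(Y, n_regions = 5)
  st <- edgewise_ancova(b, "theta", design_spec(grp))
  t2 <- apply(Y, 2, function(y) {
    t.test(y[1:10], y[11:20], var.equal = TRUE)$statistic^2
  })
  expect_equal(st$f, unname(t2), tolerance = 1e-10)
})

test_that("degenerate designs are rejected and flat edges give F = 0", {
  Y <- matrix(0.5, 8, 3)
  b <- toy_bundle(Y, n_regions = 3)
  des <- design_spec(rep(c("a", "b"), each = 4))
  expect_equal(edgewise_ancova(b, "theta", des)$f, rep(0, 3))
  grp <- rep(c("a", "b"), each = 4)
  expect_error(design_spec(grp, data.frame(d = as.numeric(grp == "a"))),
               "rank deficient")
  expect_error(design_spec(c("a", "a", "a", "b")), "at least 2 subjects")
})

test_that("omega-squared follows the one-way formula with flooring", {
  expect_equal(omega_squared(1, 3, 100), 0)
  expect_equal(omega_squared(4.2, 3, 138), 9.6 / 147.6)
  expect_equal(omega_squared(0.5, 3, 100), 0)
  # derived starting threshold for the study design (N = 138, k = 4)
  pol <- threshold_policy()
  expect_equal(connstat:::derive_f_initial(pol, 3, 138), 4.0)
  expect_gte(omega_squared(4.0, 3, 138), 0.06)
  expect_lt(omega_squared(3.9, 3, 138), 0.06)
})

test_that("suprathreshold components match hand cases and the BFS oracle", {
  mk_stats <- function(f, n_regions) {
    list(f = f, edges = connstat:::edge_index(n_regions),
         n_regions = n_regions)
  }
  # edges (1,2),(2,3),(6,7) above threshold -> sizes 2 and 1
  n <- 7
  e <- connstat:::edge_index(n)
  f <- rep(0, nrow(e))
  for (pair in list(c(1, 2), c(2, 3), c(6, 7))) {
    f[e[, 1] == pair[1] & e[, 2] == pair[2]] <- 5
  }
  comps <- suprathreshold_components(mk_stats(f, n), 1)
  expect_equal(vapply(comps, `[[`, 0L, "size"), c(2L, 1L))
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(length(suprathreshold_components(mk_stats(rep(0, nrow(e)),
                                                         n), 1)), 0L)
  # complete suprathreshold graph on 68 nodes: one component of 2278 edges
  e68 <- connstat:::edge_index(68)
  comps68 <- suprathreshold_components(mk_stats(rep(2, nrow(e68)), 68), 1)
  expect_equal(length(comps68), 1L)
  expect_equal(comps68[[1]]$size, 68L * 67L / 2L)

  # 100 random graphs against the BFS oracle
  set.seed(33)
  for (rep_i in 1:100) {
    nn <- sample(5:15, 1)
    ee <- connstat:::edge_index(nn)
    ff <- runif(nrow(ee))
    thr <- runif(1, 0.3, 0.9)
    comps <- suprathreshold_components(mk_stats(ff, nn), thr)
    sizes <- vapply(comps, `[[`, 0L, "size")
    oracle <- bfs_component_sizes(ee[ff > thr, , drop = FALSE], nn)
    expect_equal(sort(sizes, decreasing = TRUE), oracle)
  }
})

test_that("FWER p-values count null maxima at or above the observed size", {
  expect_equal(fwer_pvalue(10, c(1, 4, 9, 9)), 0)
  expect_equal(fwer_pvalue(5, c(1, 2, 5, 7, 9)), 0.6)
  expect_equal(fwer_pvalue(1, c(1, 2, 3)), 1)
  expect_error(fwer_pvalue(3, integer(0)), "empty")
})

test_that("permutation null is deterministic and threshold-monotone", {
  cfg <- null_config(44, n_per_group = 6, n_regions = 8)
  sim <- simulate_fc_directly(cfg)
  des <- cohort_design(sim$cohort)
  n1 <- permutation_null(sim$bundle, "theta", des, f_threshold = 2,
                         n_perm = 10, seed = 5)
  n2 <- permutation_null(sim$bundle, "theta", des, f_threshold = 2,
                         n_perm = 10, seed = 5)
  expect_identical(n1, n2)
  expect_equal(length(n1), 10L)
  st <- edgewise_ancova(sim$bundle, "theta", des)
  sizes <- vapply(seq(0.5, 4, by = 0.5), function(thr) {
    comps <- suprathreshold_components(st, thr)
    if (length(comps)) comps[[1]]$size else 0L
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("threshold scan starts at the configured F and steps upward", {
  cfg <- null_config(45, n_per_group = 8, n_regions = 10)
  sim <- simulate_fc_directly(cfg)
  des <- cohort_design(sim$cohort)
  r <- run_nbs(sim$bundle, "theta", des,
               threshold_policy(f_initial = 4.2, step = 0.1),
               n_perm = 20, seed = 2, max_steps = 3)
  if (nrow(r$trace) >= 2) {
    expect_equal(r$trace$f_threshold[1:2], c(4.2, 4.3))
  } else if (nrow(r$trace) == 1) {
    expect_equal(r$trace$f_threshold[1], 4.2)
  }
  # derived start without an explicit override (N = 32, k = 4 -> 1.7)
  r2 <- run_nbs(sim$bundle, "theta", des, threshold_policy(),
                n_perm = 20, seed = 2, max_steps = 1)
  f0 <- connstat:::derive_f_initial(threshold_policy(), des$df_between,
                                    des$N)
  expect_equal(r2$trace$f_threshold[1], f0)
  expect_gte(omega_squared(f0, des$df_between, des$N), 0.06)
})

test_that("planted components are recovered as significant networks", {
  hits <- vapply(1:10, function(s) {
    cfg <- null_config(600 + s, n_per_group = 15)
    eff <- planted_effect("theta", planted_star_edges(),
                          c(female_PD = 0.2))
    sim <- simulate_fc_directly(cfg, eff)
    des <- cohort_design(sim$cohort)
    r <- run_nbs(sim$bundle, "theta", des,
                 threshold_policy(f_initial = 4.0),
                 n_perm = 100, seed = s)
    r$significant &&
      edge_jaccard(r$component$edges, planted_star_edges()) >= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
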