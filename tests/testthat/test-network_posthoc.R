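test_that("mean network connectivity averages the defining edges", {
  set.seed(50)
  Y <- matrix(runif(4 * 10), 4)
  b <- toy_bundle(Y, n_regions = 5)
  e <- connstat:::edge_index(5)
  # constant edges -> constant mNC
  bc <- toy_bundle(matrix(0.42, 3, 10), n_regions = 5)
  expect_equal(mean_network_connectivity(bc, "theta", e[1:4, ])$mnc,
               rep(0.42, 3))
  # two chosen edges with values 0.2 / 0.4
  Y2 <- matrix(0, 1, 10); Y2[1, 1] <- 0.2; Y2[1, 2] <- 0.4
  b2 <- toy_bundle(Y2, n_regions = 5)
  expect_equal(mean_network_connectivity(b2, "theta", e[1:2, ])$mnc, 0.3)
  # brute-force loop oracle on a random 50-edge selection
  set.seed(51)
  Y3 <- matrix(runif(6 * 2278), 6)
  b3 <- toy_bundle(Y3, n_regions = 68)
  e68 <- connstat:::edge_index(68)
  sel <- sort(sample(nrow(e68), 50))
  mnc <- mean_network_connectivity(b3, "theta", e68[sel, ])$mnc
  oracle <- vapply(1:6, function(s) {
    m <- b3$matrices$theta[, , s]
    mean(vapply(sel, function(r) m[e68[r, 1], e68[r, 2]], 0))
  }, 0)
  expect_equal(mnc, oracle, tolerance = 1e-12)
  expect_error(mean_network_connectivity(b3, "theta",
                                         matrix(0, 0, 2)), "empty")
})

test_that("Tukey-Kramer q matches hand computation and stats oracles", {
  # groups [0,1] vs [2,3]: MSW = 0.5, SE = 0.5, diff = 2 -> q = 4
  y <- c(0, 1, 2, 3)
  des <- design_spec(rep(c("a", "b"), each = 2))
  gt <- mnc_group_test(y, des)
  expect_equal(gt$tukey$q, 4.0, tolerance = 1e-12)
  # equal-n case reduces to Tukey HSD (TukeyHSD as independent oracle)
  set.seed(52)
  y2 <- rnorm(24)
  g2 <- factor(rep(c("a", "b", "c", "d"), each = 6))
  gt2 <- mnc_group_test(y2, design_spec(g2))
  hsd <- TukeyHSD(aov(y2 ~ g2))$g2
  key <- paste(gt2$tukey$group2, gt2$tukey$group1, sep = "-")
  expect_equal(gt2$tukey$p_adj, unname(hsd[key, "p adj"]),
               tolerance = 1e-8)
  expect_equal(-gt2$tukey$mean_diff, unname(hsd[key, "diff"]),
               tolerance = 1e-10)
  # k = 2 equal n: adjusted p equals the pooled two-sided t-test p
  set.seed(53)
  y3 <- rnorm(16); g3 <- rep(c("a", "b"), each = 8)
  gt3 <- mnc_group_test(y3, design_spec(g3))
  tt <- t.test(y3[g3 == "a"], y3[g3 == "b"], var.equal = TRUE)
  expect_equal(gt3$tukey$p_adj, tt$p.value, tolerance = 1e-8)
  expect_equal(gt3$tukey$q, sqrt(2) * abs(unname(tt$statistic)),
               tolerance = 1e-10)
  # zero within-group variance flags degeneracy
  expect_true(mnc_group_test(rep(c(0, 1), each = 3),
                             design_spec(rep(c("a", "b"),
                                             each = 3)))$degenerate)
})

test_that("directional subnetwork extraction respects alpha limits", {
  set.seed(54)
  cfg <- null_config(54, n_per_group = 8, n_regions = 10)
  sim <- simulate_fc_directly(cfg)
  des <- cohort_design(sim$cohort)
  parent <- list(edges = connstat:::edge_index(10)[1:20, ])
  full <- extract_subnetwork(sim$bundle, "theta", parent, des,
                             c("female_PD", "male_PD"), alpha = 1)
  expect_equal(sum(vapply(full, function(s) nrow(s$edges), 0L)), 20)
  none <- extract_subnetwork(sim$bundle, "theta", parent, des,
                             c("female_PD", "male_PD"), alpha = 1e-12)
  expect_equal(length(none), 0L)
  expect_error(extract_subnetwork(sim$bundle, "theta", parent, des,
                                  c("female_PD", "nope")), "contrast")
})

test_that("planted group differences are recovered with direction", {
  planted <- planted_star_edges()
  extra <- rbind(c(12, 14), c(13, 15), c(14, 16), c(15, 17), c(16, 18),
                 c(17, 19), c(18, 20), c(12, 20), c(13, 19), c(12, 16))
  parent <- list(edges = connstat:::edge_index(20)[
    connstat:::edge_positions(rbind(planted, extra), 20), ])
  hits <- vapply(1:20, function(s) {
    cfg <- null_config(700 + s, n_per_group = 20)
    eff <- planted_effect("theta", planted, c(female_PD = 0.2))
    sim <- simulate_fc_directly(cfg, eff)
    des <- cohort_design(sim$cohort)
    subs <- extract_subnetwork(sim$bundle, "theta", parent, des,
                               c("female_PD", "male_PD"), alpha = 0.05)
    up <- Filter(function(x) x$direction == "female_PD > male_PD", subs)
    if (!length(up)) return(FALSE)
    edge_jaccard(up[[1]]$edges, planted) >= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("subnetwork summaries count, percentage and lateralize correctly", {
  atlas <- load_atlas()
  e68 <- connstat:::edge_index(68)
  parent <- list(edges = e68[1:84, ])
  self_sum <- summarize_subnetwork(parent, parent, atlas)
  expect_equal(self_sum$pct_of_parent_links, 100.0)
  expect_equal(sum(self_sum$degree$degree), 2 * self_sum$n_links)
  empty <- summarize_subnetwork(matrix(0, 0, 2), parent, atlas)
  expect_equal(empty$n_links, 0L)
  expect_equal(empty$pct_of_parent_links, 0.0)
  expect_equal(nrow(empty$degree), 0L)
  # lateralization variants: an all-left edge set is 100 % left
  left_edges <- cbind(1:5, 7:11)     # regions 1..34 are left hemisphere
  s <- summarize_subnetwork(left_edges, list(edges = left_edges), atlas)
  expect_equal(unname(s$lateralization_pct$node_share["left"]), 100)
  expect_equal(unname(s$lateralization_pct$link_share["left"]), 100)
  expect_equal(unname(s$lateralization_pct$degree_mass["left"]), 100)
  # a single cross-hemisphere link splits half-half in the link variant
  cross <- rbind(c(1, 35))
  s2 <- summarize_subnetwork(cross, list(edges = cross), atlas)
  expect_equal(unname(s2$lateralization_pct$link_share["left"]), 50)
  expect_equal(s2$n_nodes, 2L)
  expect_error(summarize_subnetwork(rbind(c(1, 70)),
                                    list(edges = rbind(c(1, 70))), atlas),
               "outside")
  # lobe composition sums to 100 and tracks atlas metadata
  expect_equal(sum(self_sum$lobe_composition), 100, tolerance = 0.3)
})
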