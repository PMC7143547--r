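test_that("min-max standardization maps benefit and cost columns correctly", {
  x <- cbind(b = c(2, 4, 6), c = c(2, 4, 6))
  z <- minmax_standardize(x, c("benefit", "cost"))
  expect_equal(unname(z[, "b"]), c(0, 0.5, 1))
  expect_equal(unname(z[, "c"]), c(1, 0.5, 0))
  expect_warning(
    zc <- minmax_standardize(cbind(k = c(3, 3, 3)), "benefit"),
    "constant")
  expect_equal(unname(zc[, 1]), c(0.5, 0.5, 0.5))
  expect_error(minmax_standardize(cbind(c(1, NA)), "benefit"), "missing")
})

test_that("entropy weights match hand-evaluated arithmetic and sum to 1", {
  z <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  w <- entropy_weights(z)
  # symmetric columns -> equal weights
  expect_equal(unname(w), c(0.5, 0.5), tolerance = 1e-12)

  # hand-evaluated oracle on an asymmetric block
  z2 <- rbind(c(1, 0.2), c(0, 0.3), c(0.5, 0.25))
  eps <- 1e-6
  p <- sweep(z2 + eps, 2, colSums(z2 + eps), "/")
  e <- -colSums(p * log(p)) / log(3)
  w_hand <- (1 - e) / sum(1 - e)
  expect_equal(unname(entropy_weights(z2)), unname(w_hand),
               tolerance = 1e-10)
  expect_equal(sum(entropy_weights(z2)), 1, tolerance = 1e-12)

  # a zero-information (constant) column gets ~zero weight
  z3 <- cbind(flat = rep(0.5, 4), varies = c(0, 1, 0.2, 0.9))
  w3 <- entropy_weights(z3)
  expect_lt(w3[["flat"]], 1e-6)
  expect_gt(w3[["varies"]], 1 - 1e-6)

  expect_warning(entropy_weights(matrix(0.5, 3, 2)), "uniform")
  expect_error(entropy_weights(rbind(c(2, 0), c(0, 1))), "\\[0, 1\\]")
})

test_that("composite index is the weighted sum, bounded in [0, 1]", {
  expect_equal(composite_index(c(1, 1, 1), rep(1 / 3, 3)), 1)
  expect_equal(composite_index(c(0, 0), c(0.4, 0.6)), 0)
  expect_equal(composite_index(c(0.2, 0.8), c(0.25, 0.75)), 0.65)
  expect_error(composite_index(c(0.2, 0.8), c(1, 1, 1)), "dimension|sum")
})

test_that("coupling index obeys AM-GM with equality iff balanced", {
  expect_equal(coupling_index(0.5, 0.5), 1)
  expect_equal(coupling_index(0.8, 0.2), 0.64)
  expect_equal(coupling_index(0.2, 0.8), coupling_index(0.8, 0.2))
  expect_warning(expect_equal(coupling_index(0, 0), 0), "0")
  set.seed(99)
  fx <- runif(500); fy <- runif(500)
  C <- suppressWarnings(coupling_index(fx, fy))
  expect_true(all(C <= 1 & C >= 0))
  expect_true(all((C == 1) == (fx == fy)))
})

test_that("development level is the stated convex combination", {
  expect_equal(development_level(0.4, 0.4), 0.4)
  expect_equal(development_level(1, 0), 0.5)
  expect_equal(development_level(0.6, 0.2, alpha = 0.7, beta = 0.3), 0.48)
  expect_error(development_level(0.5, 0.5, alpha = 0.7, beta = 0.5), "sum")
})

test_that("coordination degree supports both variants", {
  expect_equal(coordination_degree(1, 1), 1)
  expect_equal(coordination_degree(1, 1, variant = "product"), 1)
  expect_equal(coordination_degree(0.64, 0.5, variant = "product"), 0.32)
  expect_equal(coordination_degree(0.64, 0.5, variant = "sqrt"),
               sqrt(0.32), tolerance = 1e-10)
  expect_equal(coordination_degree(0, 0.9), 0)
})

test_that("the product variant is infeasible for a stable vegetation-leading
           site while the sqrt variant is not", {
  # back-solving an observed (D = 0.90, ratio = 1.34) stable site
  prod <- stability_backsolve(0.90, 1.34, variant = "product")
  expect_gt(prod$f_x, 1)
  expect_false(prod$feasible)
  sq <- stability_backsolve(0.90, 1.34, variant = "sqrt")
  expect_lte(sq$f_x, 1)
  expect_true(sq$feasible)
  # round trip: the recovered composites reproduce (D, ratio)
  expect_equal(coordination_degree(coupling_index(sq$f_x, sq$f_y),
                                   development_level(sq$f_x, sq$f_y)),
               0.90, tolerance = 1e-10)
  expect_equal(sq$f_x / sq$f_y, 1.34, tolerance = 1e-10)
})

test_that("classification reproduces published (D, ratio) labels with the
           single known discrepancy flagged", {
  tab <- published_stability_table()
  got <- classify_stability(tab$D, tab$ratio)
  expect_identical(as.character(got$category), tab$category)
  mismatch <- which(got$sub_category != tab$sub_category)
  expect_length(mismatch, 1L)
  expect_identical(paste(tab$mine[mismatch], tab$site[mismatch]), "LLG RA14")
  # the discrepant row: ratio 1.17 sits inside the synchronous band
  expect_identical(got$sub_category[mismatch], "VSD")
})

test_that("classification is total and documented on band boundaries", {
  b <- classify_stability(c(0.2, 0.4, 0.6, 0.8, 1.0), rep(1, 5))
  expect_identical(as.character(b$category),
                   c("Extremely unstable", "Unstable", "Sub-stable",
                     "Nearly stable", "Stable"))
  r <- classify_stability(rep(0.5, 2), c(0.8, 1.2))
  expect_identical(r$sub_category, c("VSD", "VSD"))
  low <- classify_stability(rep(0.3, 2), c(0.8, 1.2))
  expect_identical(low$sub_category, c("VSL", "VSL"))
  edge <- classify_stability(c(0.5, 0.5), c(1.2000001, 0.7999999))
  expect_identical(edge$sub_category, c("VL", "SL"))
  expect_warning(z <- classify_stability(0, 1), "lowest")
  expect_identical(as.character(z$category), "Extremely unstable")
  inf <- classify_stability(0.5, Inf)
  expect_identical(inf$sub_category, "VL")
})

test_that("identical plant and soil blocks give perfect coupling", {
  set.seed(12)
  block <- matrix(runif(24, 1, 9), 6, 4,
                  dimnames = list(paste0("s", 1:6), paste0("i", 1:4)))
  res <- stability_assess(block, block, soil_polarity = "benefit")
  expect_equal(res$ratio, rep(1, 6))
  expect_equal(res$C, rep(1, 6))
  expect_equal(res$D, sqrt(res$T * 1), tolerance = 1e-12)
})

test_that("monotone indicator blocks yield D strictly increasing with age", {
  ages <- c(0.5, 1, 2, 3, 4, 6)
  rec <- recovery_curve(ages, 0.8, 2.5)
  plant <- outer(rec, c(1, 2, 0.5, 1.5))   # monotone benefit indicators
  soil <- outer(rec, c(3, 1, 2))
  rownames(plant) <- rownames(soil) <- sprintf("t%.1f", ages)
  # the youngest site sits at the scale minimum (both composites 0), which
  # legitimately warns; only monotonicity is under test here
  res <- suppressWarnings(
    stability_assess(plant, soil, soil_polarity = "benefit"))
  expect_true(all(diff(res$D) > 0))
  expect_true(all(res$D >= 0 & res$D <= 1))
})

test_that("raising a benefit indicator never lowers the composite", {
  set.seed(77)
  z <- matrix(runif(20), 5, 4)
  w <- entropy_weights(z)
  f0 <- composite_index(z, w)
  z2 <- z
  z2[2, 3] <- min(1, z[2, 3] + 0.2)
  f1 <- composite_index(z2, w)
  expect_gte(f1[2], f0[2])
  expect_equal(f1[-2], f0[-2])
})

test_that("stability_pipeline emits the full per-site report", {
  cfg <- simulation_config(n_mines = 2, seed = 8)
  ds <- simulate_chronosequence(cfg)
  st <- stability_pipeline(ds)
  expect_setequal(st$site_id, ds$sites$site_id)
  expect_true(all(st$D >= 0 & st$D <= 1))
  expect_true(all(st$f_x >= 0 & st$f_x <= 1))
  expect_true(all(st$f_y >= 0 & st$f_y <= 1))
  expect_true(all(c("category", "sub_category") %in% names(st)))
})
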