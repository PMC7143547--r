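make_xy <- function(n = 12, p = 3, m = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  B <- matrix(rnorm(p * m), p, m)
  list(X = X, Y = X %*% B)
}

test_that("an exact linear response is fully explained", {
  d <- make_xy(seed = 3)
  fit <- rda_fit(d$Y, d$X)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-10)
  expect_lte(sum(fit$eig), fit$total_variance + 1e-10)
})

test_that("a response orthogonalized against X is annihilated", {
  set.seed(8)
  X <- matrix(rnorm(12 * 3), 12, 3)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  Xc <- scale(X, scale = FALSE)
  R <- qr.resid(qr(Xc), scale(Y, scale = FALSE))
  fit <- rda_fit(R, X)
  expect_equal(fit$variance_explained, 0, tolerance = 1e-10)
})

test_that("variance explained matches the normal-equations oracle", {
  for (s in 1:25) {
    set.seed(s)
    Y <- matrix(rnorm(12 * 6), 12, 6)
    X <- matrix(rnorm(12 * 5), 12, 5)
    fit <- rda_fit(Y, X)
    expect_equal(fit$variance_explained, oracle_rda_ve(Y, X),
                 tolerance = 1e-10)
  }
})

test_that("eigenvalues and variance explained agree with vegan", {
  set.seed(21)
  Y <- matrix(rnorm(15 * 6), 15, 6)
  X <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  fit <- rda_fit(Y, X)
  vfit <- vegan::rda(scale(Y) ~ ., data = as.data.frame(X))
  expect_equal(unname(fit$eig), unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$variance_explained,
               vfit$CCA$tot.chi / vfit$tot.chi, tolerance = 1e-10)
})

test_that("rank-deficient predictors fail with the collinear column named", {
  set.seed(2)
  X <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(X, dup = X[, "a"] * 2)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  expect_error(rda_fit(Y, X), "dup")
  expect_error(rda_fit(Y[1:3, ], X[1:3, 1:2]), "rows")
  expect_error(rda_fit(Y[, 1, drop = FALSE], X[, 1:2]), "2 columns")
})

test_that("variance explained is invariant to predictor rescaling and
           monotone in added predictors", {
  set.seed(13)
  Y <- matrix(rnorm(14 * 5), 14, 5)
  X <- matrix(rnorm(14 * 3), 14, 3)
  ve <- rda_fit(Y, X)$variance_explained
  X2 <- X
  X2[, 1] <- 100 * X2[, 1] - 7
  expect_equal(rda_fit(Y, X2)$variance_explained, ve, tolerance = 1e-10)
  X3 <- cbind(X, noise = rnorm(14))
  expect_gte(rda_fit(Y, X3)$variance_explained, ve - 1e-12)
})

test_that("permutation test hits the 1/(n+1) floor for a perfect response", {
  d <- make_xy(seed = 5)
  pt <- permutation_test(d$Y, d$X, n_permutations = 499, seed = 42)
  expect_equal(pt$p, 1 / 500)
  expect_gte(pt$p, 1 / (pt$n_permutations + 1))
})

test_that("the permutation test is deterministic under a fixed seed", {
  set.seed(30)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  X <- matrix(rnorm(12 * 3), 12, 3)
  p1 <- permutation_test(Y, X, n_permutations = 199, seed = 7)$p
  p2 <- permutation_test(Y, X, n_permutations = 199, seed = 7)$p
  expect_identical(p1, p2)
})

test_that("marginal effects isolate informative predictors and respect
           near-duplicates", {
  set.seed(9)
  x1 <- rnorm(20)
  X <- cbind(inf = x1, noise = rnorm(20, sd = 1))
  Y <- cbind(y1 = 3 * x1 + rnorm(20, sd = 1e-4),
             y2 = -x1 + rnorm(20, sd = 1e-4))
  me <- marginal_effects(Y, X, n_permutations = 99, seed = 1)
  expect_gt(me$share[me$variable == "inf"], 0.99)
  expect_lt(me$share[me$variable == "noise"], 0.2)
  expect_lt(me$p[me$variable == "inf"], 0.05)

  Xd <- cbind(a = x1, b = x1 + rnorm(20, sd = 1e-6))
  med <- marginal_effects(Y, Xd, n_permutations = 99, seed = 1)
  expect_equal(med$share[1], med$share[2], tolerance = 1e-3)

  # marginal shares match brute-force single-predictor regressions
  set.seed(11)
  Y2 <- matrix(rnorm(12 * 4), 12, 4)
  X2 <- matrix(rnorm(12 * 3), 12, 3,
               dimnames = list(NULL, c("u", "v", "w")))
  me2 <- marginal_effects(Y2, X2, n_permutations = 99, seed = 2)
  full <- oracle_rda_ve(Y2, X2)
  for (j in 1:3) {
    single <- oracle_rda_ve(Y2, X2[, j, drop = FALSE])
    expect_equal(me2$share[j], single / full, tolerance = 1e-10)
  }
  # sequential shares sum to 1 by construction
  seq_me <- marginal_effects(Y2, X2, n_permutations = 99, seed = 2,
                             type = "sequential")
  expect_equal(sum(seq_me$share), 1, tolerance = 1e-10)
})

test_that("reference distances shrink monotonically along a noiseless
           chronosequence and are rotation invariant", {
  sp <- default_soil_params()
  sp$noise_sd[] <- 0
  cfg <- simulation_config(n_mines = 1, soil_params = sp, seed = 6)
  ds <- simulate_chronosequence(cfg)
  soil_cols <- c("SMC", "OM", "TN", "AN")
  Y <- as.matrix(ds$soil[soil_cols])
  # plots within a site are identical at zero noise; jitter-free single
  # predictor keeps X full rank
  X <- as.matrix(ds$soil[, "TN", drop = FALSE])
  fit <- rda_fit(Y, X)
  ref <- ds$sites$site_id[ds$sites$is_reference]
  d <- reference_distance(fit, ds$soil$site_id, ref)
  ra <- ds$sites[!ds$sites$is_reference, ]
  dd <- d[ra$site_id[order(ra$age)]]
  expect_true(all(diff(dd) < 0))
  expect_equal(unname(d[ref]), 0)

  # rigid rotation of the score space leaves distances unchanged
  set.seed(3)
  Y2 <- matrix(rnorm(12 * 4), 12, 4)
  X2 <- matrix(rnorm(12 * 2), 12, 2)
  f2 <- rda_fit(Y2, X2)
  g <- rep(c("a", "b", "c", "refg"), each = 3)
  d0 <- reference_distance(f2, g, "refg")
  th <- pi / 5
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  f2r <- f2
  f2r$site_scores <- f2$site_scores[, 1:2] %*% rot
  d1 <- reference_distance(f2r, g, "refg")
  expect_equal(d0, d1, tolerance = 1e-10)
  expect_error(reference_distance(f2, g, "missing"), "not present")
})
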