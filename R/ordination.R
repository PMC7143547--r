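#' Redundancy analysis of community characteristics on soil properties
#'
#' Constrained ordination computed from first principles: the response
#' matrix (plant community characteristics) is z-scored column-wise because
#' its columns are on incommensurate scales (counts vs unit-interval
#' indices); the predictor matrix (soil properties) is centered; fitted
#' values come from the multivariate least-squares regression of Y on X, and
#' the constrained axes from the SVD of those fitted values. Scores use
#' distance-preserving (type 1) scaling, so Euclidean distances between site
#' scores are meaningful.
#'
#' @param Y numeric response matrix/data.frame (rows = plots or sites,
#'   columns = community characteristics; >= 2 columns, no missing cells).
#' @param X numeric predictor matrix/data.frame, rows aligned with `Y`.
#' @param standardize_response z-score the columns of `Y` first (default
#'   TRUE).
#' @return object of class `"rda_fit"`: `eig` (constrained eigenvalues),
#'   `total_variance`, `constrained_variance`, `variance_explained`,
#'   `site_scores`, `response_scores`, `biplot_scores`, `rank`, `n`, `q`,
#'   and internal matrices reused by the permutation test.
#' @export
rda_fit <- function(Y, X, standardize_response = TRUE) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same rows", call. = FALSE)
  if (anyNA(Y) || anyNA(X)) stop("missing cells are not allowed", call. = FALSE)
  if (ncol(Y) < 2L) stop("Y needs >= 2 columns", call. = FALSE)
  n <- nrow(Y)
  if (n < ncol(X) + 2L)
    stop("need at least ncol(X) + 2 rows", call. = FALSE)
  if (standardize_response) {
    sds <- apply(Y, 2, stats::sd)
    if (any(sds == 0))
      stop("constant response column(s): ",
           paste(colnames(Y)[sds == 0], collapse = ", "), call. = FALSE)
    Ys <- scale(Y)
  } else {
    Ys <- scale(Y, scale = FALSE)
  }
  Xc <- scale(X, scale = FALSE)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xc))]]
    stop("predictor matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  Yhat <- qr.fitted(qrX, Ys)
  sv <- svd(Yhat)
  tol <- max(sv$d) * 1e-10
  r <- sum(sv$d > tol)
  r <- max(r, 1L)
  eig <- (sv$d[seq_len(r)]^2) / (n - 1)
  total <- sum(Ys^2) / (n - 1)
  constrained <- sum(Yhat^2) / (n - 1)

  site_scores <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r) / sqrt(n - 1)
  rownames(site_scores) <- rownames(Y)
  response_scores <- sv$v[, seq_len(r), drop = FALSE]
  rownames(response_scores) <- colnames(Y)
  biplot_scores <- suppressWarnings(stats::cor(Xc, site_scores))
  colnames(site_scores) <- colnames(response_scores) <-
    paste0("RDA", seq_len(r))
  structure(list(
    eig = stats::setNames(eig, paste0("RDA", seq_len(r))),
    total_variance = total,
    constrained_variance = constrained,
    variance_explained = constrained / total,
    site_scores = site_scores,
    response_scores = response_scores,
    biplot_scores = biplot_scores,
    rank = r, n = n, q = qrX$rank,
    Ys = Ys, qrX = qrX), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Redundancy analysis:", x$n, "rows,", x$q, "predictors\n")
  cat(sprintf("Variance explained: %.1f%% (constrained %.4g of total %.4g)\n",
              100 * x$variance_explained, x$constrained_variance,
              x$total_variance))
  invisible(x)
}

# pseudo-F for a response matrix given a fixed predictor QR decomposition
pseudo_f <- function(Ys, qrX, q, n) {
  Yh <- qr.fitted(qrX, Ys)
  css <- sum(Yh^2)
  rss <- sum(Ys^2) - css
  (css / q) / (rss / (n - q - 1))
}

#' Monte Carlo permutation test for an RDA
#'
#' Tests the null hypothesis that the community matrix is unrelated to the
#' environmental variables by unrestricted permutation of the response rows.
#' The observed pseudo-F is
#' \eqn{F = (V_c / q) / (V_r / (n - q - 1))} where \eqn{V_c} and \eqn{V_r}
#' are constrained and residual variance and q the number of predictors; the
#' p-value is \eqn{(\#\{F_{perm} \ge F_{obs}\} + 1) / (n_{perm} + 1)}, so
#' with the conventional 499 permutations the attainable floor is 0.002.
#'
#' @inheritParams rda_fit
#' @param n_permutations number of random permutations (default 499).
#' @param seed integer seed for reproducibility (optional).
#' @return list with `F`, `p`, `n_permutations`, `F_perm`.
#' @export
permutation_test <- function(Y, X, n_permutations = 499, seed = NULL,
                             standardize_response = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  fit <- rda_fit(Y, X, standardize_response = standardize_response)
  f_obs <- pseudo_f(fit$Ys, fit$qrX, fit$q, fit$n)
  f_perm <- vapply(seq_len(n_permutations), function(b) {
    pseudo_f(fit$Ys[sample.int(fit$n), , drop = FALSE],
             fit$qrX, fit$q, fit$n)
  }, 0)
  list(F = f_obs,
       p = (sum(f_perm >= f_obs) + 1) / (n_permutations + 1),
       n_permutations = n_permutations, F_perm = f_perm)
}

#' Per-variable effects of each soil property
#'
#' For every predictor, fits the single-predictor RDA and reports the share
#' of the full model's constrained variance that the predictor explains on
#' its own (`type = "marginal"`, default), or the incremental share when
#' predictors are added in column order (`type = "sequential"`), each with
#' its own permutation test.
#'
#' @inheritParams permutation_test
#' @param type `"marginal"` or `"sequential"`.
#' @return data.frame: `variable`, `variance`, `share` (of the full-model
#'   constrained variance), `F`, `p`.
#' @export
marginal_effects <- function(Y, X, n_permutations = 499, seed = NULL,
                             type = c("marginal", "sequential"),
                             standardize_response = TRUE) {
  type <- match.arg(type)
  X <- as.matrix(X)
  full <- rda_fit(Y, X, standardize_response = standardize_response)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("X", seq_len(ncol(X)))
  if (!is.null(seed)) set.seed(seed)
  prev <- 0
  rows <- lapply(seq_len(ncol(X)), function(j) {
    cols <- if (type == "marginal") j else seq_len(j)
    fj <- rda_fit(Y, X[, cols, drop = FALSE],
                  standardize_response = standardize_response)
    pt <- permutation_test(Y, X[, cols, drop = FALSE],
                           n_permutations = n_permutations,
                           standardize_response = standardize_response)
    v <- fj$constrained_variance - if (type == "sequential") prev else 0
    prev <<- fj$constrained_variance
    data.frame(variable = vars[j], variance = v,
               share = v / full$constrained_variance,
               F = pt$F, p = pt$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Euclidean distance of each site to the natural-reference centroid
#'
#' Distances are computed in the space of all constrained axes between each
#' site's centroid of row scores and the reference group's centroid; under
#' the distance-preserving scaling used by [rda_fit()] these distances track
#' how far each restoration stage still is from the reference state.
#'
#' @param fit an `"rda_fit"`.
#' @param groups site/group label per row of the fitted matrices.
#' @param reference the label of the natural-reference group.
#' @return named numeric vector of distances (reference itself at 0).
#' @export
reference_distance <- function(fit, groups, reference) {
  stopifnot(inherits(fit, "rda_fit"))
  groups <- as.character(groups)
  if (length(groups) != fit$n)
    stop("groups must have one label per row", call. = FALSE)
  if (!reference %in% groups)
    stop("reference group '", reference, "' not present", call. = FALSE)
  cen <- rowsum(fit$site_scores, groups) / as.vector(table(groups)[sort(unique(groups))])
  ref <- cen[reference, ]
  d <- sqrt(rowSums(sweep(cen, 2, ref)^2))
  d[order(names(d))]
}
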