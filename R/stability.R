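#' Extreme-value (min-max) standardization of an indicator block
#'
#' Linearly rescales every indicator to \[0, 1\] across the sites of one
#' mine — including the natural reference, which must share the scale for
#' the reference to be comparable. Benefit indicators map min -> 0,
#' max -> 1; cost indicators (e.g. soil pH and bulk density, which are
#' higher on disturbed dumps) are reversed. A constant column carries no
#' ranking information; it is set to 0.5 everywhere with a warning.
#'
#' @param x numeric matrix/data.frame (rows = sites, columns = indicators).
#' @param polarity character vector per column: `"benefit"` or `"cost"`.
#' @return numeric matrix in \[0, 1\], same dimnames as `x`.
#' @export
minmax_standardize <- function(x, polarity) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) stop("need >= 2 rows (sites)", call. = FALSE)
  if (anyNA(x)) stop("missing cells are not allowed", call. = FALSE)
  polarity <- match.arg(polarity, c("benefit", "cost"), several.ok = TRUE)
  if (length(polarity) == 1L) polarity <- rep(polarity, ncol(x))
  if (length(polarity) != ncol(x))
    stop("polarity must have one entry per column", call. = FALSE)
  z <- x
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j])
    if (rng[1] == rng[2]) {
      warning("constant indicator column ",
              if (!is.null(colnames(x))) colnames(x)[j] else j,
              "; standardized to 0.5", call. = FALSE)
      z[, j] <- 0.5
    } else if (polarity[j] == "benefit") {
      z[, j] <- (x[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      z[, j] <- (rng[2] - x[, j]) / (rng[2] - rng[1])
    }
  }
  z
}

#' Entropy weights for a standardized indicator block
#'
#' Objective weighting: indicators whose standardized values are more
#' dispersed across sites (lower Shannon entropy of their normalized
#' distribution) receive larger weights. With standardized values
#' \eqn{z_{ij}}, \eqn{p_{ij} = (z_{ij}+\epsilon)/\sum_i (z_{ij}+\epsilon)},
#' \eqn{e_j = -\frac{1}{\ln n}\sum_i p_{ij}\ln p_{ij}}, and
#' \eqn{w_j = (1-e_j)/\sum_k (1-e_k)}. The small \eqn{\epsilon} keeps
#' standardized zeros inside the log's domain.
#'
#' @param z standardized matrix in \[0, 1\] (rows = sites).
#' @param eps smoothing constant added before the log (default 1e-6).
#' @return numeric weight vector summing to 1, named by column.
#' @export
entropy_weights <- function(z, eps = 1e-6) {
  z <- as.matrix(z)
  if (anyNA(z) || any(z < 0) || any(z > 1))
    stop("z must be standardized to [0, 1]", call. = FALSE)
  n <- nrow(z)
  if (n < 2L) stop("need >= 2 rows", call. = FALSE)
  p <- sweep(z + eps, 2, colSums(z + eps), "/")
  e <- -colSums(p * log(p)) / log(n)
  d <- 1 - e
  if (all(abs(d) < 1e-12)) {
    warning("all indicators maximally uniform; equal weights used",
            call. = FALSE)
    w <- rep(1 / ncol(z), ncol(z))
  } else {
    d <- pmax(d, 0)
    w <- d / sum(d)
  }
  stats::setNames(w, colnames(z))
}

#' Composite quality index of one subsystem
#'
#' Weighted sum \eqn{f = \sum_k w_k z_k} of a site's standardized indicator
#' values; with weights summing to 1 and values in \[0, 1\] the composite is
#' guaranteed in \[0, 1\]. Applied to the plant block this is f(x), to the
#' soil block f(y).
#'
#' @param z standardized matrix (rows = sites) or a single row vector.
#' @param w weight vector (non-negative, summing to 1).
#' @return numeric vector, one composite per row.
#' @export
composite_index <- function(z, w) {
  z <- rbind(z)  # promotes a bare vector to one row
  if (ncol(z) != length(w))
    stop("dimension mismatch between z and weights", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  as.vector(z %*% w)
}

#' Coupling index of the plant and soil subsystems
#'
#' \eqn{C = f_x f_y / ((f_x + f_y)/2)^2 = 4 f_x f_y / (f_x + f_y)^2}: a
#' symmetric measure of how balanced the two composites are, equal to 1 iff
#' \eqn{f_x = f_y} (AM-GM equality) and approaching 0 as one subsystem
#' dominates. `C = 0` is returned with a warning when both composites are 0.
#'
#' @param f_x,f_y plant and soil composite indices (vectorised, >= 0).
#' @return C in \[0, 1\].
#' @export
coupling_index <- function(f_x, f_y) {
  if (any(f_x < 0) || any(f_y < 0))
    stop("composites must be non-negative", call. = FALSE)
  both0 <- f_x + f_y == 0
  if (any(both0))
    warning("f_x = f_y = 0; coupling defined as 0", call. = FALSE)
  out <- ifelse(both0, 0, 4 * f_x * f_y / (f_x + f_y)^2)
  pmin(out, 1)  # guards rounding at f_x == f_y
}

#' Overall development level of the coupled system
#'
#' Convex combination \eqn{T = \alpha f_x + \beta f_y}. Vegetation and soil
#' restoration are treated as equally important, so both contribution rates
#' default to 0.5.
#'
#' @inheritParams coupling_index
#' @param alpha,beta contribution rates; must be non-negative and sum to 1.
#' @return T in \[min(f_x, f_y), max(f_x, f_y)\].
#' @export
development_level <- function(f_x, f_y, alpha = 0.5, beta = 0.5) {
  if (alpha < 0 || beta < 0 || abs(alpha + beta - 1) > 1e-12)
    stop("alpha and beta must be non-negative and sum to 1", call. = FALSE)
  alpha * f_x + beta * f_y
}

#' Coupling coordination degree (the ecological-stability score)
#'
#' Combines coupling and development into the stability score D. The
#' default is the standard coordination degree \eqn{D = \sqrt{C T}}; the
#' plain product \eqn{D = C T} is kept behind `variant = "product"` but is
#' arithmetically inconsistent with observed stable/vegetation-leading sites
#' (see [stability_backsolve()]), which is why the square root is the
#' default.
#'
#' @param C coupling index in \[0, 1\].
#' @param T_ development level in \[0, 1\].
#' @param variant `"sqrt"` (default) or `"product"`.
#' @return D in \[0, 1\].
#' @export
coordination_degree <- function(C, T_, variant = c("sqrt", "product")) {
  variant <- match.arg(variant)
  if (any(C < 0 | C > 1) || any(T_ < 0 | T_ > 1))
    stop("C and T must lie in [0, 1]", call. = FALSE)
  if (variant == "sqrt") sqrt(C * T_) else C * T_
}

#' Back-solve the subsystem composites from (D, ratio)
#'
#' Given a stability score D and a development ratio \eqn{k = f_x/f_y},
#' inverts the coupling-coordination model to recover the composites:
#' \eqn{C = 4k/(1+k)^2} depends on the ratio alone, \eqn{T} follows from the
#' variant (\eqn{T = D^2/C} for sqrt, \eqn{T = D/C} for product), and with
#' \eqn{\alpha = \beta = 0.5}, \eqn{f_x + f_y = 2T}. A returned composite
#' above 1 proves the (D, ratio, variant) combination infeasible for
#' convex combinations of \[0, 1\]-standardized indicators — the check that
#' motivates the sqrt default.
#'
#' @param D stability score in (0, 1\].
#' @param ratio development ratio f_x/f_y (> 0).
#' @param variant `"sqrt"` or `"product"`.
#' @return list with `f_x`, `f_y`, `C`, `T`, and `feasible` (both
#'   composites in \[0, 1\]).
#' @export
stability_backsolve <- function(D, ratio, variant = c("sqrt", "product")) {
  variant <- match.arg(variant)
  stopifnot(D > 0, ratio > 0)
  C <- 4 * ratio / (1 + ratio)^2
  T_ <- if (variant == "sqrt") D^2 / C else D / C
  f_y <- 2 * T_ / (1 + ratio)
  f_x <- ratio * f_y
  list(f_x = f_x, f_y = f_y, C = C, T = T_,
       feasible = f_x <= 1 + 1e-12 && f_y <= 1 + 1e-12)
}

.es_categories <- c("Extremely unstable", "Unstable", "Sub-stable",
                    "Nearly stable", "Stable")

#' Classify ecological stability and vegetation/soil development
#'
#' Applies the five-band stability classification and the development
#' sub-bands. D bands (upper bounds inclusive): (0, 0.2\] extremely
#' unstable, (0.2, 0.4\] unstable, (0.4, 0.6\] sub-stable, (0.6, 0.8\]
#' nearly stable, (0.8, 1\] stable. Sub-categories from the ratio
#' \eqn{f_x/f_y}: > 1.2 vegetation-lagging (VL), < 0.8 soil-lagging (SL),
#' and within \[0.8, 1.2\] synchronous — lagging (VSL) in the two lowest
#' stability bands, development (VSD) in the top three. D = 0 falls outside
#' the open-at-zero bands and is assigned to the lowest band with a warning.
#'
#' @param D stability score(s) in \[0, 1\].
#' @param ratio development ratio(s) f_x/f_y (may be `Inf` when f_y = 0).
#' @return data.frame with `D`, `ratio`, `category` (ordered factor),
#'   `sub_category`.
#' @export
classify_stability <- function(D, ratio) {
  stopifnot(length(D) == length(ratio), all(D >= 0), all(D <= 1),
            all(ratio >= 0))
  if (any(D == 0))
    warning("D = 0 lies outside the (0, 1] bands; assigned to the lowest",
            call. = FALSE)
  # upper-inclusive bands: (0, 0.2], (0.2, 0.4], ...
  band <- findInterval(D, c(0.2, 0.4, 0.6, 0.8), left.open = TRUE) + 1L
  category <- factor(.es_categories[band], levels = .es_categories,
                     ordered = TRUE)
  sub <- ifelse(ratio > 1.2, "VL",
         ifelse(ratio < 0.8, "SL",
                ifelse(band <= 2L, "VSL", "VSD")))
  data.frame(D = D, ratio = ratio, category = category, sub_category = sub)
}

#' Entropy-weighted coupling-coordination stability assessment
#'
#' Full assessment for the sites of one mine: min-max standardization of
#' the plant and soil indicator blocks (across all sites including the
#' natural reference), entropy weights per block, composite indices f(x)
#' and f(y), coupling C, development level T, stability score D and the
#' category/sub-category labels.
#'
#' @param plant numeric matrix/data.frame of plant community
#'   characteristics, rows = sites (shared rownames with `soil`).
#' @param soil numeric matrix/data.frame of soil properties, same rows.
#' @param plant_polarity,soil_polarity per-column polarity
#'   (`"benefit"`/`"cost"`); plant characteristics default to all-benefit,
#'   soil to benefit except `pH` and `BD` (cost).
#' @param variant coordination-degree variant, see [coordination_degree()].
#' @param alpha,beta contribution rates of vegetation and soil.
#' @param eps entropy smoothing constant.
#' @return data.frame (one row per site): `site_id`, `f_x`, `f_y`, `ratio`,
#'   `C`, `T`, `D`, `category`, `sub_category`; entropy weights attached as
#'   attributes `plant_weights` and `soil_weights`.
#' @export
stability_assess <- function(plant, soil,
                             plant_polarity = "benefit",
                             soil_polarity = NULL,
                             variant = c("sqrt", "product"),
                             alpha = 0.5, beta = 0.5, eps = 1e-6) {
  variant <- match.arg(variant)
  plant <- as.matrix(plant); soil <- as.matrix(soil)
  if (nrow(plant) != nrow(soil))
    stop("plant and soil blocks must share the same site rows", call. = FALSE)
  if (!is.null(rownames(plant)) && !is.null(rownames(soil)) &&
      !identical(rownames(plant), rownames(soil)))
    stop("plant and soil blocks must share the same site rows", call. = FALSE)
  if (is.null(soil_polarity)) {
    soil_polarity <- ifelse(colnames(soil) %in% c("pH", "BD"),
                            "cost", "benefit")
  }
  zp <- minmax_standardize(plant, plant_polarity)
  zs <- minmax_standardize(soil, soil_polarity)
  wp <- entropy_weights(zp, eps = eps)
  ws <- entropy_weights(zs, eps = eps)
  f_x <- composite_index(zp, wp)
  f_y <- composite_index(zs, ws)
  C <- coupling_index(f_x, f_y)
  T_ <- development_level(f_x, f_y, alpha = alpha, beta = beta)
  D <- coordination_degree(C, T_, variant = variant)
  cls <- classify_stability(D, ifelse(f_y == 0, Inf, f_x / f_y))
  out <- data.frame(
    site_id = if (!is.null(rownames(plant))) rownames(plant)
              else paste0("site", seq_along(f_x)),
    f_x = f_x, f_y = f_y, ratio = cls$ratio, C = C, T = T_, D = D,
    category = cls$category, sub_category = cls$sub_category,
    row.names = NULL)
  attr(out, "plant_weights") <- wp
  attr(out, "soil_weights") <- ws
  attr(out, "variant") <- variant
  out
}

#' Stability pipeline over a whole chronosequence dataset
#'
#' Builds the site-level indicator blocks (plant community characteristics
#' from per-plot diversity averaged per site; soil properties as plot means
#' per site), runs [stability_assess()] separately per mine (each mine's
#' sites, including its natural reference, share one standardization scale),
#' and returns the combined report with restoration ages attached.
#'
#' @param dataset a `"chronosequence"` object, or a list with `sites`,
#'   `vegetation`, `soil` tables of the same shape.
#' @param ... passed to [stability_assess()] (variant, polarities, alpha,
#'   beta, eps).
#' @return data.frame with `mine_id`, `site_id`, `age`, `is_reference`,
#'   `f_x`, `f_y`, `ratio`, `C`, `T`, `D`, `category`, `sub_category`.
#' @export
stability_pipeline <- function(dataset, ...) {
  sites <- dataset$sites
  divs <- diversity_table(dataset$vegetation, level = "site")
  soil_cols <- setdiff(names(dataset$soil), c("plot_id", "site_id"))
  soil_site <- aggregate(dataset$soil[soil_cols],
                         by = list(site_id = dataset$soil$site_id), mean)
  out <- lapply(split(sites, sites$mine_id), function(s) {
    ids <- sort(s$site_id)
    plant <- as.matrix(divs[match(ids, divs$site_id),
                            c("SP", "NP", "shannon", "simpson",
                              "pielou", "margalef")])
    soil <- as.matrix(soil_site[match(ids, soil_site$site_id), soil_cols])
    rownames(plant) <- rownames(soil) <- ids
    res <- stability_assess(plant, soil, ...)
    cbind(s[match(ids, s$site_id), c("mine_id", "site_id", "age",
                                     "is_reference")], res[-1])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
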