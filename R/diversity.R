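#' @keywords internal
check_counts <- function(counts) {
  if (length(counts) == 0L)
    stop("abundance vector is empty", call. = FALSE)
  if (anyNA(counts))
    stop("abundance vector contains NA", call. = FALSE)
  if (any(counts < 0))
    stop("abundances must be non-negative", call. = FALSE)
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    stop("abundance vector is all zero", call. = FALSE)
  counts
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H' = -\sum p_i \log p_i} with \eqn{p_i = n_i / N}. Zero counts are
#' dropped; the index is bounded by \eqn{0 \le H' \le \log S}.
#'
#' @param counts numeric vector of species abundances (counts, zeros allowed
#'   and ignored).
#' @param base logarithm base; natural log (nats) by default.
#' @return Shannon diversity, a non-negative scalar.
#' @examples
#' shannon_index(c(10, 10, 10, 10))  # log(4)
#' @export
shannon_index <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Simpson diversity index
#'
#' By default the Gini-Simpson complement \eqn{D = 1 - \sum p_i^2}, which
#' increases with diversity so its direction matches the other indices. The
#' raw dominance form \eqn{\sum p_i^2} is available via `variant`.
#'
#' @inheritParams shannon_index
#' @param variant `"gini"` (default, \eqn{1 - \sum p_i^2}) or `"dominance"`
#'   (\eqn{\sum p_i^2}).
#' @return value in \[0, 1\].
#' @export
simpson_index <- function(counts, variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  counts <- check_counts(counts)
  p <- counts / sum(counts)
  lambda <- sum(p^2)
  if (variant == "gini") 1 - lambda else lambda
}

#' Pielou evenness index
#'
#' \eqn{J = H' / \log S}. For a monoculture (\eqn{S = 1}) the ratio is 0/0;
#' the convention \eqn{J = 0} is adopted so site-level aggregation never
#' fails.
#'
#' @inheritParams shannon_index
#' @return value in \[0, 1\].
#' @export
pielou_index <- function(counts, base = exp(1)) {
  counts <- check_counts(counts)
  s <- length(counts)
  if (s < 2L) return(0)
  shannon_index(counts, base = base) / log(s, base = base)
}

#' Margalef richness index
#'
#' \eqn{Mg = (S - 1) / \log N}. Defined as 0 when \eqn{S = 1} (zero
#' numerator) and when \eqn{N = 1} (undefined denominator).
#'
#' @inheritParams shannon_index
#' @return non-negative scalar.
#' @export
margalef_index <- function(counts) {
  counts <- check_counts(counts)
  s <- length(counts)
  n <- sum(counts)
  if (s < 2L || n < 2) return(0)
  (s - 1) / log(n)
}

#' Summarise one plot census into its community characteristics
#'
#' Computes the six plant community characteristics used throughout the
#' assessment — species count (SP), total individuals (NP), Shannon-Wiener
#' H', Simpson D, Pielou J and Margalef Mg — from a single abundance vector,
#' so all indices are guaranteed to come from the same census.
#'
#' @inheritParams shannon_index
#' @inheritParams simpson_index
#' @return one-row `data.frame` with columns `SP`, `NP`, `shannon`,
#'   `simpson`, `pielou`, `margalef`.
#' @examples
#' diversity_profile(c(A = 10, B = 10, C = 10, D = 10))
#' @export
diversity_profile <- function(counts, base = exp(1),
                              variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  counts <- check_counts(counts)
  data.frame(
    SP = length(counts),
    NP = sum(counts),
    shannon = shannon_index(counts, base = base),
    simpson = simpson_index(counts, variant = variant),
    pielou = pielou_index(counts, base = base),
    margalef = margalef_index(counts)
  )
}

#' Diversity table for a long-format vegetation census
#'
#' Takes the long vegetation table (one row per plot x species, columns
#' `plot_id`, `site_id`, `species`, `count`) and returns the community
#' characteristics per plot, or aggregated per site. Site aggregation
#' defaults to the mean of per-plot indices (matching the mean +/- letter
#' presentation of grouped-bar figures); `site_method = "pool"` instead pools
#' abundances across a site's plots before computing indices.
#'
#' @param vegetation data.frame with columns `plot_id`, `site_id`, `species`,
#'   `count`.
#' @param level `"plot"` (default) or `"site"`.
#' @param site_method for `level = "site"`: `"mean"` of per-plot indices
#'   (default) or `"pool"` abundances then index.
#' @inheritParams diversity_profile
#' @return data.frame with id columns and the six characteristics.
#' @export
diversity_table <- function(vegetation, level = c("plot", "site"),
                            site_method = c("mean", "pool"),
                            base = exp(1), variant = c("gini", "dominance")) {
  level <- match.arg(level)
  site_method <- match.arg(site_method)
  variant <- match.arg(variant)
  need <- c("plot_id", "site_id", "species", "count")
  if (!all(need %in% names(vegetation)))
    stop("vegetation table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(vegetation$count <= 0))
    stop("vegetation counts must be positive", call. = FALSE)

  per_plot <- do.call(rbind, lapply(split(vegetation, vegetation$plot_id),
    function(d) {
      cbind(data.frame(plot_id = d$plot_id[1], site_id = d$site_id[1]),
            diversity_profile(d$count, base = base, variant = variant))
    }))
  rownames(per_plot) <- NULL
  if (level == "plot") return(per_plot[order(per_plot$plot_id), ])

  if (site_method == "mean") {
    idx <- c("SP", "NP", "shannon", "simpson", "pielou", "margalef")
    agg <- aggregate(per_plot[idx], by = list(site_id = per_plot$site_id), mean)
    return(agg[order(agg$site_id), ])
  }
  pooled <- aggregate(count ~ site_id + species, data = vegetation, sum)
  out <- do.call(rbind, lapply(split(pooled, pooled$site_id), function(d) {
    cbind(data.frame(site_id = d$site_id[1]),
          diversity_profile(d$count, base = base, variant = variant))
  }))
  rownames(out) <- NULL
  out[order(out$site_id), ]
}
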