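#' One-way ANOVA for a grouped measurement
#'
#' Standard between/within variance decomposition across restoration sites
#' (and the natural reference). Degenerate inputs — zero variance everywhere
#' with equal group means — yield an undefined F and are flagged rather than
#' erroring.
#'
#' @param values numeric replicate measurements.
#' @param groups group labels, same length as `values`.
#' @return list with `F`, `p`, `df` (c(between, within)), and `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 replicates", call. = FALSE)
  fit <- stats::lm(values ~ groups)
  # anova.lm warns on (near-)perfect fits; degeneracy is reported via the
  # `degenerate` flag instead
  tab <- suppressWarnings(stats::anova(fit))
  msb <- tab$`Mean Sq`[1]
  mse <- tab$`Mean Sq`[2]
  if (mse == 0 && msb == 0) {
    return(list(F = NaN, p = NaN, df = tab$Df, degenerate = TRUE))
  }
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1], df = tab$Df,
       degenerate = FALSE)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean comparisons with studentized-range adjusted p-values;
#' unequal group sizes use the Tukey-Kramer correction (the study design has
#' 2 or 3 plots per site).
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the `significant` flag.
#' @return list with `table` (data.frame: group1, group2, diff, p_adj,
#'   significant), `p_matrix` and `signif_matrix` (symmetric), `means`,
#'   `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 replicates", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  # rows follow the lower triangle column-major, i.e. combn() order with
  # the pair reversed ("lev_j-lev_i"); labels may contain '-', so rebuild
  # the pairs from the levels rather than splitting row names
  cmb <- utils::combn(levels(groups), 2L)
  tab <- data.frame(
    group1 = cmb[2L, ],
    group2 = cmb[1L, ],
    diff = th[, "diff"], p_adj = th[, "p adj"],
    significant = th[, "p adj"] < alpha, row.names = NULL)
  lev <- levels(groups)
  pm <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (r in seq_len(nrow(tab))) {
    pm[tab$group1[r], tab$group2[r]] <- tab$p_adj[r]
    pm[tab$group2[r], tab$group1[r]] <- tab$p_adj[r]
  }
  diag(pm) <- 1
  list(table = tab, p_matrix = pm, signif_matrix = pm < alpha,
       means = tapply(values, groups, mean), alpha = alpha)
}

#' Compact letter display by insert-and-absorb
#'
#' Summarises a symmetric pairwise-significance matrix as letter sets so
#' that two groups share at least one letter if and only if they are not
#' significantly different. Letters are ordered `a`, `b`, `c`, ... by
#' descending group mean; ties in means break by label order, so output is
#' deterministic.
#'
#' @param signif_matrix symmetric logical matrix (TRUE = significantly
#'   different) with group labels as dimnames.
#' @param means named vector of group means (orders the letters).
#' @return data.frame with `group`, `mean`, `letters`, sorted by descending
#'   mean.
#' @export
compact_letter_display <- function(signif_matrix, means) {
  stopifnot(is.matrix(signif_matrix),
            nrow(signif_matrix) == ncol(signif_matrix))
  labs <- rownames(signif_matrix)
  stopifnot(!is.null(labs), all(labs %in% names(means)))
  ord <- order(-means[labs], labs)
  labs <- labs[ord]
  m <- signif_matrix[labs, labs, drop = FALSE]
  n <- length(labs)

  # columns = letter groups, start with one containing everybody
  cols <- list(rep(TRUE, n))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!isTRUE(m[i, j])) next
    k <- 1L
    while (k <= length(cols)) {
      col <- cols[[k]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[k]] <- c1
        cols[[length(cols) + 1L]] <- c2
        # absorb: drop any column whose members are a subset of another's
        drop <- rep(FALSE, length(cols))
        for (a in seq_along(cols)) for (b in seq_along(cols)) {
          if (a != b && !drop[a] && !drop[b] &&
              all(cols[[b]][cols[[a]]])) {
            if (all(cols[[a]][cols[[b]]]) && a < b) next  # equal: keep first
            drop[a] <- TRUE
          }
        }
        cols <- cols[!drop]
        k <- 0L
      }
      k <- k + 1L
    }
  }
  # order columns by first member so letter 'a' goes to the top mean
  first <- vapply(cols, function(cl) which(cl)[1], 1L)
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(n), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, "")
  data.frame(group = labs, mean = unname(means[labs]),
             letters = letters_out, row.names = NULL)
}

#' Mean, SD and significance letters per group
#'
#' Convenience wrapper reproducing the "mean +/- sd with letters"
#' presentation: one-way ANOVA, Tukey HSD and the compact letter display in
#' one call.
#'
#' @inheritParams tukey_hsd
#' @return data.frame with `group`, `mean`, `sd`, `letters`, plus the ANOVA
#'   `F` and `p` as attributes.
#' @export
group_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  av <- one_way_anova(values, groups)
  th <- tukey_hsd(values, groups, alpha = alpha)
  sm <- th$signif_matrix
  if (av$degenerate) sm[] <- FALSE
  cld <- compact_letter_display(sm, th$means)
  cld$sd <- as.vector(tapply(values, groups, stats::sd)[cld$group])
  cld <- cld[c("group", "mean", "sd", "letters")]
  attr(cld, "anova") <- av
  attr(cld, "alpha") <- alpha
  cld
}
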