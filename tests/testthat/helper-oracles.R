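# Independent brute-force oracles used across the suite.

# direct-summation diversity oracle (kept deliberately naive)
oracle_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  s <- length(counts)
  p <- counts / n
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  list(shannon = h,
       simpson = 1 - sum(p^2),
       pielou = if (s < 2) 0 else h / log(s),
       margalef = if (s < 2 || n < 2) 0 else (s - 1) / log(n))
}

random_counts <- function(max_s = 12, max_n = 50) {
  s <- sample(1:max_s, 1)
  sample(1:max_n, s, replace = TRUE)
}

# explicit normal-equations RDA oracle: fraction of variance of the
# z-scored response captured by its regression on the centered predictors
oracle_rda_ve <- function(Y, X) {
  Ys <- scale(Y)
  Xc <- scale(X, scale = FALSE)
  B <- solve(t(Xc) %*% Xc, t(Xc) %*% Ys)
  Yhat <- Xc %*% B
  sum(Yhat * Yhat) / sum(Ys * Ys)
}

# hand-rolled Tukey-Kramer adjusted p for one pair
oracle_tukey_p <- function(values, groups, g1, g2) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- table(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  sse <- sum((values - gm[groups])^2)
  mse <- sse / (n - k)
  se <- sqrt(mse / 2 * (1 / ni[[g1]] + 1 / ni[[g2]]))
  q <- abs(gm[[g1]] - gm[[g2]]) / se
  ptukey(q, nmeans = k, df = n - k, lower.tail = FALSE)
}

# check both defining invariants of a compact letter display
cld_invariants_hold <- function(cld, signif_matrix) {
  labs <- cld$group
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    shared <- length(intersect(strsplit(cld$letters[i], "")[[1]],
                               strsplit(cld$letters[j], "")[[1]])) > 0
    sig <- isTRUE(signif_matrix[labs[i], labs[j]])
    if (sig && shared) return(FALSE)
    if (!sig && !shared) return(FALSE)
  }
  TRUE
}

# the published 18-row stability classification (D, development ratio, and
# the printed category / sub-category labels), used as replay input
published_stability_table <- function() {
  tab <- read.csv(text = '
mine,site,D,ratio,category,sub_category
WLHD,RA14,0.51,0.93,Sub-stable,VSD
WLHD,RA15,0.49,0.64,Sub-stable,SL
WLHD,RA16,0.47,0.57,Sub-stable,SL
WLHD,RA17,0.22,0.67,Unstable,SL
WLHD,RA18,0.13,0.21,Extremely unstable,SL
WLHD,NA,0.63,0.95,Nearly stable,VSD
LLG,RA14,0.75,1.17,Nearly stable,VL
LLG,RA15,0.67,1.49,Nearly stable,VL
LLG,RA16,0.44,2.48,Sub-stable,VL
LLG,RA17,0.37,0.25,Unstable,SL
LLG,RA18,0.33,0.11,Unstable,SL
LLG,NA,0.90,1.34,Stable,VL
JZT,RA12,0.85,1.02,Stable,VSD
JZT,RA13,0.82,0.98,Stable,VSD
JZT,RA16,0.40,3.60,Unstable,VL
JZT,RA17,0.28,3.92,Unstable,VL
JZT,RA18,0.17,0.14,Extremely unstable,SL
JZT,NA,0.81,2.22,Stable,VL
', stringsAsFactors = FALSE)
  tab
}
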