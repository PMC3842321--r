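#' Mann-Whitney U test
#'
#' Two-sided nonparametric comparison of two independent samples. The U
#' statistic is computed from rank sums with average ranks for ties
#' (`U = R1 - m(m+1)/2` for the first sample). Exact mode enumerates the
#' null distribution: by the standard counting recursion when the pooled
#' data are tie-free, otherwise by full enumeration of all
#' `choose(m+n, m)` labelings when `m + n <= 14` (falling back to the
#' asymptotic approximation beyond that). Asymptotic mode uses the normal
#' approximation with tie correction and continuity correction. `auto`
#' selects exact when `m + n <= 25` and the pooled data are tie-free,
#' enumeration when tied and small, else asymptotic. The two-sided exact p
#' is `min(1, 2 x` the smaller one-sided tail including the observed U`)`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_max_n Largest tie-free pooled size for exact mode in `auto`.
#' @param tie_enum_max_n Largest pooled size for tie enumeration.
#' @return List with `U` (first-sample U), `p` (two-sided), and `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         exact_max_n = 25L, tie_enum_max_n = 14L) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  u1 <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  method <- mode
  if (mode == "auto") {
    method <- if (!has_ties && N <= exact_max_n) "exact"
    else if (has_ties && N <= tie_enum_max_n) "exact"
    else "asymptotic"
  }
  if (method == "exact") {
    if (!has_ties) {
      p <- mwu_exact_tiefree(u1, m, n)
      return(list(U = u1, p = p, method = "exact"))
    }
    if (N <= tie_enum_max_n) {
      p <- mwu_exact_enum(r, m, u1)
      return(list(U = u1, p = p, method = "exact_enumeration"))
    }
    if (mode == "exact")
      warning("ties with m+n > tie_enum_max_n: falling back to asymptotic")
  }
  p <- mwu_asymptotic(u1, r, m, n)
  list(U = u1, p = p, method = "asymptotic")
}

# Exact tie-free null distribution of U via the standard recursion
# N(m, n, u) = N(m-1, n, u-n) + N(m, n-1, u), returned as frequencies over
# u = 0..mn.
mwu_null_counts <- function(m, n) {
  # f[[mm + 1]] holds the count vector over u = 0..mm*nn for first-sample
  # size mm at the current second-sample size nn (starting at nn = 0).
  f <- rep(list(1), m + 1)
  for (nn in seq_len(n)) {
    g <- vector("list", m + 1)
    g[[1]] <- 1
    for (mm in seq_len(m)) {
      a <- numeric(mm * nn + 1)
      prev_same <- f[[mm + 1]]  # (mm, nn-1): largest pooled obs is a y
      a[seq_along(prev_same)] <- prev_same
      less <- g[[mm]]           # (mm-1, nn): largest pooled obs is an x
      idx <- nn + seq_along(less)
      a[idx] <- a[idx] + less
      g[[mm + 1]] <- a
    }
    f <- g
  }
  f[[m + 1]]
}

mwu_exact_tiefree <- function(u1, m, n) {
  counts <- mwu_null_counts(m, n)
  total <- sum(counts)
  u_vals <- 0:(m * n)
  lo <- sum(counts[u_vals <= u1 + 1e-9]) / total
  hi <- sum(counts[u_vals >= u1 - 1e-9]) / total
  min(1, 2 * min(lo, hi))
}

# Exact p with ties: enumerate all subsets of pooled ranks of size m.
mwu_exact_enum <- function(r, m, u1) {
  N <- length(r)
  subsets <- utils::combn(N, m)
  offset <- m * (m + 1) / 2
  us <- colSums(matrix(r[subsets], nrow = m)) - offset
  lo <- mean(us <= u1 + 1e-9)
  hi <- mean(us >= u1 - 1e-9)
  min(1, 2 * min(lo, hi))
}

mwu_asymptotic <- function(u1, r, m, n) {
  N <- m + n
  mu <- m * n / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  d <- u1 - mu
  cc <- if (d == 0) 0 else sign(d) * 0.5  # continuity correction toward mean
  z <- (d - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average ranks of both variables.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("spearman needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(rank(x), rank(y))
}

#' Pairwise Spearman correlations over the metabolite panel
#'
#' @param quant Quantification data frame (as from [quantify_cohort()]).
#' @param metabolites Columns to correlate (default: the 4-metabolite panel).
#' @param absolute Render unsigned magnitudes (the signed value is always
#'   computed and stored; the published table prints unsigned values).
#' @return Data frame with feature pair, signed `r`, rendered `r_rendered`,
#'   and `n`.
#' @export
metabolite_correlations <- function(quant,
                                    metabolites = panel_defaults()$feature_order,
                                    absolute = FALSE) {
  prs <- utils::combn(metabolites, 2)
  out <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    r <- spearman_cor(quant[[a]], quant[[b]])
    data.frame(feature_a = a, feature_b = b, spearman_r = r,
               r_rendered = if (absolute) abs(r) else r,
               n = sum(is.finite(quant[[a]]) & is.finite(quant[[b]])))
  })
  do.call(rbind, out)
}

#' Group-wise univariate comparison table
#'
#' For each metabolite: per-group median and range, plus pairwise two-sided
#' Mann-Whitney p-values for every group pairing -- the layout of the
#' published concentration table (sporadic vs SDHx, sporadic vs VHL, SDHx vs
#' VHL for the default three groups).
#'
#' @param quant Quantification data frame with a `group` column.
#' @param metabolites Metabolite columns to compare.
#' @param mode Mann-Whitney mode, see [mann_whitney()].
#' @return Data frame: one row per metabolite, median/range per group and a
#'   p-value column per group pair (no p columns with a single group).
#' @export
group_table <- function(quant, metabolites = panel_defaults()$feature_order,
                        mode = "auto") {
  groups <- unique(quant$group)
  counts <- table(quant$group)
  empty <- setdiff(groups, names(counts)[counts > 0])
  if (length(empty)) {
    warning(sprintf("skipping empty group(s): %s", paste(empty, collapse = ", ")))
    groups <- setdiff(groups, empty)
  }
  if (length(groups) < 1) stopf("no non-empty groups")
  rows <- lapply(metabolites, function(met) {
    row <- list(metabolite = met)
    for (g in groups) {
      v <- quant[[met]][quant$group == g]
      row[[paste0("median_", g)]] <- stats::median(v)
      row[[paste0("min_", g)]] <- min(v)
      row[[paste0("max_", g)]] <- max(v)
    }
    if (length(groups) >= 2) {
      prs <- utils::combn(groups, 2)
      for (i in seq_len(ncol(prs))) {
        a <- prs[1, i]; b <- prs[2, i]
        mw <- mann_whitney(quant[[met]][quant$group == a],
                           quant[[met]][quant$group == b], mode)
        row[[paste0("p_", a, "_vs_", b)]] <- mw$p
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
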