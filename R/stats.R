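# Statistical gate shared by the fractionation and drought analyses:
# Tukey outlier screening, Shapiro-Wilk normality gating into Welch t or
# Wilcoxon rank-sum (exact by enumeration for small samples), and a
# Jonckheere-style permutation trend test for ordered density designs.

#' Tukey fence outlier screen
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` (default `k = 1.5`).
#'
#' @param x Numeric vector.
#' @param k Fence multiplier.
#' @return Logical vector, `TRUE` for outliers.
#' @export
tukey_outliers <- function(x, k = 1.5) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(N, n_a) group assignments of the (mid)ranks. Handles ties through
# midranks; two-sided p doubles the smaller tail (capped at 1), which is
# exact for the symmetric tie-free null and the conventional choice
# otherwise.
ranksum_exact <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); N <- length(r)
  W <- sum(r[seq_len(na)])
  combos <- combn(N, na)
  Wperm <- colSums(matrix(r[combos], nrow = na))
  eps <- 1e-9
  p_le <- mean(Wperm <= W + eps)
  p_ge <- mean(Wperm >= W - eps)
  list(statistic = W - na * (na + 1) / 2,  # Mann-Whitney U
       p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Two-sample comparison with a normality gate
#'
#' The statistical procedure applied to every two-group contrast: gross
#' outliers are removed per group (Tukey fences at `outlier_k` times the
#' IQR beyond the quartiles; removed ids are logged in the result), each
#' group is tested for normality (Shapiro-Wilk at `alpha`), and then
#' either a Welch two-sample t-test (both groups normal) or a Wilcoxon
#' rank-sum test is applied, two-sided. The rank-sum p-value is computed
#' by exact enumeration of all group assignments when the pooled sample
#' has at most `exact_n_max` observations, and by the tie-corrected
#' normal approximation otherwise.
#'
#' The default fences are Tukey's "far out" fences (`outlier_k = 3`),
#' which screen recording and transcription errors while flagging clean
#' normally distributed samples only rarely; the conventional 1.5 x IQR
#' fences trim the tails of small normal samples so often that the
#' downstream t-test loses its nominal size (about 0.09 instead of 0.05
#' at n = 10 per group), so they are not used as the default here.
#'
#' @param a,b Numeric samples (each n >= 3 after outlier removal).
#' @param alpha Significance level of the Shapiro-Wilk gate (default
#'   0.05).
#' @param method `"auto"` (the gate), or force `"t"` / `"wilcoxon"`.
#' @param remove_outliers Apply the Tukey screen first (default `TRUE`).
#' @param outlier_k Fence multiplier for the screen (default 3, Tukey's
#'   far-out fences; 1.5 gives the conventional inner fences).
#' @param exact_n_max Largest pooled n for exact rank-sum enumeration
#'   (default 20).
#' @param ids_a,ids_b Optional observation ids used to report removed
#'   outliers.
#' @return An object of class `group_comparison`: `statistic_name`
#'   (`"t"` or `"wilcoxon_rank_sum"`), `statistic`, `p_value`,
#'   `normality_p` per group, `outliers_removed`, group sizes and means.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           method = c("auto", "t", "wilcoxon"),
                           remove_outliers = TRUE, outlier_k = 3,
                           exact_n_max = 20,
                           ids_a = NULL, ids_b = NULL) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  ids_a <- ids_a %||% paste0("a", seq_along(a))
  ids_b <- ids_b %||% paste0("b", seq_along(b))
  removed <- character(0)
  if (remove_outliers) {
    oa <- tukey_outliers(a, k = outlier_k); ob <- tukey_outliers(b, k = outlier_k)
    removed <- c(ids_a[oa], ids_b[ob])
    a <- a[!oa]; b <- b[!ob]
    ids_a <- ids_a[!oa]; ids_b <- ids_b[!ob]
  }
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs n >= 3 after outlier removal")
  sw_p <- function(x) {
    if (length(unique(x)) < 3L) return(0)  # degenerate: not plausibly normal
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  norm_p <- c(a = sw_p(a), b = sw_p(b))
  use_t <- switch(method,
    auto = all(norm_p > alpha),
    t = TRUE,
    wilcoxon = FALSE)
  if (use_t) {
    tt <- t.test(a, b)  # Welch, two-sided
    res <- list(statistic_name = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, exact = FALSE)
  } else if (length(a) + length(b) <= exact_n_max) {
    ex <- ranksum_exact(a, b)
    res <- list(statistic_name = "wilcoxon_rank_sum",
                statistic = ex$statistic, p_value = ex$p_value, exact = TRUE)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- list(statistic_name = "wilcoxon_rank_sum",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                exact = FALSE)
  }
  structure(
    c(res, list(normality_p = norm_p, outliers_removed = removed,
                n = c(a = length(a), b = length(b)),
                means = c(a = mean(a), b = mean(b)))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g%s\n",
              x$statistic_name, x$statistic, x$p_value,
              if (isTRUE(x$exact)) " (exact)" else ""))
  cat(sprintf("  n = %d/%d, means %.4g vs %.4g, Shapiro p = %.3g/%.3g\n",
              x$n[1], x$n[2], x$means[1], x$means[2],
              x$normality_p[1], x$normality_p[2]))
  if (length(x$outliers_removed))
    cat("  outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  invisible(x)
}

# Jonckheere-Terpstra statistic for ordered groups: sum over ordered group
# pairs (i < j) of Mann-Whitney counts #(x_i < x_j) + 0.5 #(x_i == x_j).
jt_statistic <- function(x, gidx, k) {
  s <- 0
  for (i in seq_len(k - 1)) {
    xi <- x[gidx == i]
    for (j in (i + 1):k) {
      xj <- x[gidx == j]
      s <- s + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
  }
  s
}

# Enumerate jt_statistic over all distinct assignments of x to ordered
# groups of the given sizes (recursive subset enumeration).
jt_enumerate <- function(x, sizes) {
  out <- numeric(0)
  recurse <- function(remaining_idx, gidx_acc) {
    g <- length(gidx_acc) + 1L
    if (g > length(sizes)) {
      gi <- integer(length(x))
      for (gg in seq_along(gidx_acc)) gi[gidx_acc[[gg]]] <- gg
      out[length(out) + 1L] <<- jt_statistic(x, gi, length(sizes))
      return(invisible(NULL))
    }
    if (g == length(sizes)) {
      recurse(integer(0), c(gidx_acc, list(remaining_idx)))
    } else {
      ch <- combn(remaining_idx, sizes[g])
      for (cc in seq_len(ncol(ch))) {
        recurse(setdiff(remaining_idx, ch[, cc]),
                c(gidx_acc, list(ch[, cc])))
      }
    }
  }
  recurse(seq_along(x), list())
  out
}

#' Jonckheere-style permutation trend test for ordered groups
#'
#' Tests for a monotone trend of a response across ordered groups (e.g.
#' water-loss rate across planting densities) using the
#' Jonckheere-Terpstra statistic with a permutation null. All distinct
#' group assignments are enumerated exactly when their number is at most
#' `exact_limit`; otherwise `n_perm` random permutations are drawn
#' (seeded). The permutation p-value includes the observed arrangement in
#' the Monte-Carlo case (the add-one rule), so it is never exactly zero.
#'
#' @param x Numeric response.
#' @param g Ordered grouping: a numeric vector (e.g. the density itself)
#'   or ordered factor, same length as `x`.
#' @param alternative `"increasing"` or `"decreasing"` trend of `x` with
#'   `g`.
#' @param n_perm Random permutations when exact enumeration is infeasible
#'   (default 999).
#' @param exact_limit Maximum number of distinct assignments for exact
#'   enumeration (default 20000).
#' @param seed Optional integer seed for the permutation draw.
#' @return List with `statistic` (observed JT), `p_value`, `exact`,
#'   `n_perm_used`, group sizes and levels.
#' @export
jonckheere_test <- function(x, g, alternative = c("increasing", "decreasing"),
                            n_perm = 999, exact_limit = 20000, seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(g)) stop("`x` and `g` must have the same length")
  lev <- sort(unique(g))
  if (length(lev) < 2L) stop("need at least 2 ordered groups")
  gidx <- match(g, lev)
  k <- length(lev)
  sizes <- tabulate(gidx, k)
  obs <- jt_statistic(x, gidx, k)
  n_arrange <- round(exp(lgamma(length(x) + 1) - sum(lgamma(sizes + 1))))
  eps <- 1e-9
  if (n_arrange <= exact_limit) {
    null_stats <- jt_enumerate(x, sizes)
    p <- if (alternative == "increasing") mean(null_stats >= obs - eps)
         else mean(null_stats <= obs + eps)
    exact <- TRUE; n_used <- length(null_stats)
  } else {
    perm_stats <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      jt_statistic(sample(x), gidx, k)
    }, numeric(1)))
    extreme <- if (alternative == "increasing") sum(perm_stats >= obs - eps)
               else sum(perm_stats <= obs + eps)
    p <- (extreme + 1) / (n_perm + 1)
    exact <- FALSE; n_used <- n_perm
  }
  list(statistic = obs, p_value = p, exact = exact, n_perm_used = n_used,
       alternative = alternative, sizes = sizes, levels = lev)
}
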