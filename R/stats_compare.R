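#' Replicate summary (mean and standard deviation)
#'
#' Aggregates one metric over replicate breath tests as mean and sample
#' standard deviation (n - 1 denominator), the form in which fingerprint
#' metrics are reported per model (typically n = 5 replicates).
#'
#' @param values Numeric vector of per-replicate metric values (n >= 2).
#' @return Named list with `mean`, `sd` and `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3))  # mean 2, sd 1
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stopf("need at least 2 replicates for an SD")
  if (!all(is.finite(values))) stopf("non-finite replicate values")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

# exact permutation distribution of the Kruskal-Wallis statistic: enumerate
# all partitions of the pooled ranks into the observed group sizes
kw_stat <- function(rank_sums, sizes, N, tie_div) {
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  h / tie_div
}

kw_exact_p <- function(values, groups) {
  r <- rank(values)
  sizes <- as.integer(table(groups))
  N <- length(r)
  ties <- table(r)
  tie_div <- 1 - sum(ties^3 - ties) / (N^3 - N)
  obs_sums <- tapply(r, groups, sum)
  h_obs <- kw_stat(obs_sums, sizes, N, tie_div)
  count <- 0; total <- 0
  recurse <- function(avail, k, sums) {
    if (k == length(sizes)) {
      sums <- c(sums, sum(avail))
      h <- kw_stat(sums, sizes, N, tie_div)
      count <<- count + (h >= h_obs - 1e-12)
      total <<- total + 1
      return(invisible())
    }
    cmb <- utils::combn(length(avail), sizes[k])
    for (j in seq_len(ncol(cmb))) {
      pick <- cmb[, j]
      recurse(avail[-pick], k + 1L, c(sums, sum(avail[pick])))
    }
    invisible()
  }
  recurse(r, 1L, numeric(0))
  list(p = count / total, n_partitions = total, H = h_obs)
}

#' Kruskal-Wallis comparison of fingerprint metrics across models
#'
#' Rank-based one-way comparison of a metric across airway models, with
#' average ranks and the standard tie-correction divisor. The H statistic
#' and the chi-squared p value (df = k - 1) come from
#' [stats::kruskal.test()]; for small samples (total N <= 12) an exact
#' permutation p value is additionally computed by enumerating all
#' partitions of the pooled ranks into the observed group sizes, and is the
#' one used for significance stars ("*" for p < 0.05, "**" for p < 0.01).
#'
#' @param values Numeric vector of metric values, or a list of per-group
#'   numeric vectors (in which case `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @return An object of class `kw_result` with fields `H`, `p_chisq`,
#'   `p_exact` (NA when N > 12), `p` (exact when available), `df`,
#'   `group_sizes`, `tie_correction_applied` and `stars`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))$H
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) stopf("every group needs n >= 2")
  if (stats::var(values) == 0) {
    res <- list(H = 0, p_chisq = 1, p_exact = 1, p = 1,
                df = nlevels(groups) - 1L,
                group_sizes = as.integer(table(groups)),
                tie_correction_applied = TRUE, stars = "")
    class(res) <- "kw_result"
    return(res)
  }
  kt <- stats::kruskal.test(values, groups)
  N <- length(values)
  exact <- if (N <= 12L) kw_exact_p(values, groups) else NULL
  p <- if (!is.null(exact)) exact$p else kt$p.value
  res <- list(H = unname(kt$statistic), p_chisq = kt$p.value,
              p_exact = if (is.null(exact)) NA_real_ else exact$p,
              p = p, df = unname(kt$parameter),
              group_sizes = as.integer(table(groups)),
              tie_correction_applied = TRUE,
              stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  class(res) <- "kw_result"
  res
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g%s%s\n",
              x$H, x$df, x$p,
              if (!is.na(x$p_exact)) " (exact permutation)" else " (chi-squared)",
              if (nzchar(x$stars)) paste0(" ", x$stars) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
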