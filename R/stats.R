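# Nonparametric comparison of morphometry distributions.

kw_statistic <- function(ranks, sizes) {
  n <- sum(sizes)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  rs <- vapply(seq_along(sizes),
               function(g) sum(ranks[starts[g]:ends[g]]), numeric(1L))
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  # tie correction
  t <- table(ranks)
  corr <- 1 - sum(t^3 - t) / (n^3 - n)
  if (corr == 0) return(list(h = 0, corr = corr))
  list(h = h / corr, corr = corr)
}

#' Kruskal-Wallis rank test for equal distributions
#'
#' Computes the tie-corrected Kruskal-Wallis statistic
#' `H = [12 / (N(N+1))] * sum(R_g^2 / n_g) - 3(N+1)` (mid-ranks for ties,
#' standard tie-correction divisor). The p-value uses the chi-squared
#' approximation with `k - 1` degrees of freedom (appropriate for the
#' thousands of tubules a morphometry run yields), or the exact permutation
#' null (all assignments of the pooled mid-ranks to groups enumerated) for
#' small samples.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @param p_method `"chisq"` (default) or `"exact"` (total n <= 10).
#' @return A `kw_result`: `statistic` (H), `df`, `p_value`, `n` (group
#'   sizes), `tie_correction`, `p_method`.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2L)
    stop_field("groups", "must be a list of at least two samples")
  if (any(lengths(groups) == 0L))
    stop_field("groups", "all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop_field("groups", "values must be finite")
  sizes <- lengths(groups)
  g <- factor(rep(seq_along(groups), sizes))
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, df = df, p_value = 1, n = as.integer(sizes),
                tie_correction = 0, p_method = p_method)
    class(res) <- "kw_result"
    return(res)
  }
  kt <- stats::kruskal.test(x, g)
  h <- unname(kt$statistic)
  corr <- kw_statistic(rank(x), sizes)$corr
  p <- if (p_method == "chisq") {
    unname(kt$p.value)
  } else {
    if (length(x) > 10L)
      stop("exact permutation p-value supported for total n <= 10",
           call. = FALSE)
    kw_exact_p(rank(x), sizes, h)
  }
  res <- list(statistic = h, df = df, p_value = p, n = as.integer(sizes),
              tie_correction = corr, p_method = p_method)
  class(res) <- "kw_result"
  res
}

# Exact permutation null: enumerate all distinct assignments of the pooled
# rank multiset to groups of the given sizes and count H >= observed.
kw_exact_p <- function(ranks, sizes, h_obs) {
  n <- length(ranks)
  idx <- seq_len(n)
  total <- 0
  extreme <- 0
  assign_rec <- function(avail, g, acc) {
    if (g == length(sizes)) {
      perm_ranks <- ranks[c(unlist(acc), avail)]
      h <- kw_statistic(perm_ranks, sizes)$h
      total <<- total + 1
      if (h >= h_obs - 1e-9) extreme <<- extreme + 1
      return(invisible())
    }
    cmb <- utils::combn(avail, sizes[g], simplify = FALSE)
    for (pick in cmb)
      assign_rec(setdiff(avail, pick), g + 1L, c(acc, list(pick)))
  }
  assign_rec(idx, 1L, list())
  extreme / total
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (%s; n = %s)\n",
              x$statistic, x$df, x$p_value, x$p_method,
              paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Per-condition width (or intensity) histograms
#'
#' Half-open bins `[e_k, e_{k+1})`, last bin closed; values beyond the last
#' edge are counted in an overflow bin and reported. Probabilities sum to 1
#' per condition.
#'
#' @param records a `tubule_records` data frame (needs `condition` and the
#'   chosen `value` column).
#' @param bin_edges strictly increasing numeric vector; default 20 nm steps
#'   covering the data (matching a 20 nm reconstruction pixel).
#' @param value column to histogram, default `"width_nm"`.
#' @return A `distribution_summary`: list with `bin_edges`, per-condition
#'   `probability` matrix (conditions x bins, last column = overflow), and
#'   `n` per condition.
#' @export
width_distribution <- function(records, bin_edges = NULL, value = "width_nm") {
  if (nrow(records) == 0L) stop("records is empty", call. = FALSE)
  if (!value %in% names(records)) stop_field("value", "not a record column")
  v <- records[[value]]
  if (is.null(bin_edges))
    bin_edges <- seq(0, (floor(max(v) / 20) + 1) * 20, by = 20)
  if (any(diff(bin_edges) <= 0))
    stop_field("bin_edges", "must be strictly increasing")
  conds <- unique(as.character(records$condition))
  nb <- length(bin_edges) - 1L
  prob <- matrix(0, length(conds), nb + 1L,
                 dimnames = list(conds, c(paste0("[", head(bin_edges, -1L), ",",
                                                 bin_edges[-1L], ")"),
                                          "overflow")))
  n <- integer(length(conds))
  for (i in seq_along(conds)) {
    vi <- v[records$condition == conds[i]]
    n[i] <- length(vi)
    k <- findInterval(vi, bin_edges, rightmost.closed = TRUE)
    # k = 0 (below first edge) counted with overflow; k = nb+1 is overflow
    counts <- tabulate(ifelse(k == 0L, nb + 1L, k), nbins = nb + 1L)
    prob[i, ] <- counts / length(vi)
  }
  structure(list(bin_edges = bin_edges, probability = prob, n = n,
                 conditions = conds, value = value),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("distribution_summary of %s: %d bins, conditions: %s\n",
              x$value, length(x$bin_edges) - 1L,
              paste(sprintf("%s (n=%d)", x$conditions, x$n), collapse = ", ")))
  invisible(x)
}
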