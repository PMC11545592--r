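# Group-level statistics: per-sample prey-group summaries, the Mann-Whitney
# U test (exact enumeration for small tie-free samples, tie-corrected normal
# approximation otherwise) and hypergeometric rarefaction.

#' Per-sample prey-group summaries
#'
#' For every sample and prey group: the group's share of the sample's prey
#' reads (`rel_abundance_share`) and the number of the group's items with at
#' least one read (`richness`). Shares of the two groups sum to 1 within
#' each sample.
#'
#' @param prey a `prey_table`.
#' @return data frame: `sample_id`, `group`, `rel_abundance_share`,
#'   `richness`.
#' @export
summarise_groups <- function(prey) {
  stopifnot(inherits(prey, "prey_table"))
  totals <- rowSums(prey$counts)
  groups <- intersect(PREY_GROUPS, unique(prey$items$prey_group))
  out <- do.call(rbind, lapply(groups, function(g) {
    cols <- prey$items$prey_group == g
    sub <- prey$counts[, cols, drop = FALSE]
    data.frame(
      sample_id = prey$sample_ids,
      group = g,
      rel_abundance_share = rowSums(sub) / totals,
      richness = as.integer(rowSums(sub > 0)),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }))
  rownames(out) <- NULL
  out
}

# Exact null pmf of the Mann-Whitney U statistic for group sizes m and n,
# by counting rank subsets with the classic recurrence
#   c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1).
exact_u_pmf <- function(m, n) {
  memo <- new.env(parent = emptyenv())
  cnt <- function(u, m, n) {
    if (u < 0) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    key <- paste(u, m, n)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- cnt(u - n, m - 1, n) + cnt(u, m, n - 1)
    assign(key, v, envir = memo)
    v
  }
  u <- 0:(m * n)
  counts <- vapply(u, cnt, numeric(1L), m = m, n = n)
  counts / choose(m + n, m)
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums for `x` (so `U(x, y) + U(y, x) = n1 n2`).
#' For tie-free data with `min(n1, n2) <= 8` the two-sided p-value is exact,
#' from the full null distribution of U over all rank assignments; otherwise
#' a normal approximation with tie correction and continuity correction is
#' used. Requesting `mode = "exact"` on tied data is an error, since the
#' rank-permutation null is no longer distribution-free under ties.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return list of class `mwu_result`: `U`, `n1`, `n2`, `p_two_sided`,
#'   `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("x and y must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  n1 <- length(x)
  n2 <- length(y)
  z <- c(x, y)
  rk <- rank(z)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(z) > 0L

  if (mode == "exact" && ties) {
    stop("exact Mann-Whitney p-value is unavailable with ties", call. = FALSE)
  }
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !ties && min(n1, n2) <= 8
  )

  mu <- n1 * n2 / 2
  if (use_exact) {
    pmf <- exact_u_pmf(n1, n2)
    u_vals <- 0:(n1 * n2)
    p <- sum(pmf[abs(u_vals - mu) >= abs(U - mu) - 1e-9])
    method <- "exact"
  } else {
    n <- n1 + n2
    tab <- table(z)
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      num <- max(abs(U - mu) - 0.5, 0) # continuity correction
      p <- min(1, 2 * stats::pnorm(-num / sqrt(sigma2)))
    }
    method <- "normal_approx"
  }
  structure(
    list(U = U, n1 = n1, n2 = n2, p_two_sided = p, method = method),
    class = "mwu_result"
  )
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(
    sprintf(
      "Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
      x$U, x$n1, x$n2, x$p_two_sided, x$method
    )
  )
  invisible(x)
}

#' Compare the two prey groups across samples
#'
#' Runs [mann_whitney_u()] on the per-sample group read shares and on the
#' per-sample group richness (fish vs benthic invertebrates), the two panels
#' of the standard box-plot comparison.
#'
#' @param prey a `prey_table` containing both prey groups.
#' @param mode passed to [mann_whitney_u()].
#' @return data frame: `statistic`, `n1`, `n2`, `U`, `p_two_sided`,
#'   `method`.
#' @export
compare_prey_groups <- function(prey, mode = "auto") {
  s <- summarise_groups(prey)
  if (length(unique(s$group)) < 2L) {
    stop("both prey groups are required for a comparison", call. = FALSE)
  }
  fish <- s[s$group == "fish", ]
  inv <- s[s$group == "benthic_invertebrate", ]
  rows <- lapply(
    c(rel_abundance_share = "rel_abundance_share", richness = "richness"),
    function(col) {
      res <- mann_whitney_u(fish[[col]], inv[[col]], mode = mode)
      data.frame(
        statistic = col, n1 = res$n1, n2 = res$n2, U = res$U,
        p_two_sided = res$p_two_sided, method = res$method,
        stringsAsFactors = FALSE
      )
    }
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual-based rarefaction
#'
#' Expected richness when drawing `m` reads without replacement from the
#' pooled counts: `E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))`, the exact
#' hypergeometric form. Computed with log binomial coefficients for
#' numerical stability.
#'
#' @param counts non-negative integer read counts per item.
#' @param m number of reads drawn, `0 <= m <= sum(counts)`.
#' @return expected number of items represented.
#' @export
rarefy_individual <- function(counts, m) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts) | counts < 0 | counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  N <- sum(counts)
  if (length(m) != 1L || m != floor(m) || m < 0 || m > N) {
    stop(sprintf("m must be an integer in [0, %d]", N), call. = FALSE)
  }
  if (m == 0) return(0)
  counts <- counts[counts > 0]
  sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
}

#' Sample-based rarefaction
#'
#' Expected richness when drawing `s` of the `S` samples without
#' replacement: `E[S(s)] = sum_i (1 - C(S - F_i, s) / C(S, s))` where `F_i`
#' is item i's occurrence count.
#'
#' @param prey a `prey_table`.
#' @param s number of samples drawn, `1 <= s <= S`.
#' @return expected number of items detected.
#' @export
rarefy_samples <- function(prey, s) {
  stopifnot(inherits(prey, "prey_table"))
  S <- prey$n_samples
  if (length(s) != 1L || s != floor(s) || s < 1 || s > S) {
    stop(sprintf("s must be an integer in [1, %d]", S), call. = FALSE)
  }
  F_i <- colSums(prey$counts > 0)
  F_i <- F_i[F_i > 0]
  sum(1 - exp(lchoose(S - F_i, s) - lchoose(S, s)))
}

#' Rarefaction curve
#'
#' @param prey a `prey_table`.
#' @param mode `"sample_based"` (effort = number of samples, default) or
#'   `"individual_based"` (effort = number of reads pooled over samples).
#' @param efforts integer efforts; defaults to `1:S` for sample-based and to
#'   20 points spanning `[1, N]` for individual-based curves.
#' @return data frame: `mode`, `effort`, `expected_richness`; the final
#'   point at maximal effort equals the observed richness.
#' @export
rarefaction_curve <- function(prey,
                              mode = c("sample_based", "individual_based"),
                              efforts = NULL) {
  mode <- match.arg(mode)
  if (mode == "sample_based") {
    if (is.null(efforts)) efforts <- seq_len(prey$n_samples)
    val <- vapply(efforts, function(s) rarefy_samples(prey, s), numeric(1L))
  } else {
    pooled <- colSums(prey$counts)
    N <- sum(pooled)
    if (is.null(efforts)) {
      efforts <- unique(round(seq(1, N, length.out = 20)))
    }
    val <- vapply(efforts, function(m) rarefy_individual(pooled, m), numeric(1L))
  }
  data.frame(
    mode = mode, effort = as.integer(efforts), expected_richness = val,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
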