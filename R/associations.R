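# Nonparametric association screen: Spearman rank correlation and
# Mann-Whitney U, with exhaustive-permutation p-values for small samples
# and large-sample approximations otherwise. Ties take average (mid)
# ranks throughout.

#' Spearman rank correlation with permutation p-value
#'
#' rho is the Pearson correlation of mid-ranks. For `n <= exact_n` the
#' two-sided p-value is computed from the exhaustive permutation null
#' (all n! orderings of y); for larger n the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom is used.
#'
#' @param x,y Paired numeric vectors, >= 3 complete pairs.
#' @param exact_n Largest n for the exhaustive permutation null
#'   (default 8; 8! = 40320 permutations).
#' @return A one-row tibble: `rho`, `p`, `n`, `method`. A constant
#'   variable makes rho undefined: `rho = NA`, `p = NA`.
#' @export
#' @examples
#' spearman_screen(1:4, c(2, 1, 4, 3))
spearman_screen <- function(x, y, exact_n = 8) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined (constant variable)"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- pracma::perms(ry)
    rho_null <- as.vector(
      stats::cor(rx, t(perms))
    )
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p = p, n = n, method = method)
}

# Mann-Whitney U from mid-ranks: U for group 1.
mwu_statistic <- function(ranks1, n1, n2) {
  sum(ranks1) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test with permutation p-value
#'
#' U is computed from mid-ranks of the pooled sample (U for `x`; the
#' complementary statistic is `n1*n2 - U`). For pooled n up to
#' `exact_n_total` the two-sided p-value enumerates all
#' choose(n1+n2, n1) group assignments; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact_n_total Largest pooled n for exhaustive enumeration
#'   (default 12).
#' @return A one-row tibble: `u` (for `x`), `p`, `n1`, `n2`, `method`.
#' @export
#' @examples
#' mann_whitney_screen(c(1, 5, 7), c(2, 3))
mann_whitney_screen <- function(x, y, exact_n_total = 12) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty",
                             call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- mwu_statistic(r[seq_len(n1)], n1, n2)
  if (n1 + n2 <= exact_n_total) {
    idx <- utils::combn(n1 + n2, n1)
    u_null <- apply(idx, 2, function(i) mwu_statistic(r[i], n1, n2))
    # two-sided: deviation of U from its null mean n1*n2/2
    dev <- abs(u_null - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-12)
    method <- "exact permutation"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) /
                              (nt * (nt - 1)))
    z <- (u - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(u = u, p = p, n1 = n1, n2 = n2, method = method)
}

#' Association screen across variable pairs
#'
#' Runs [spearman_screen()] for each requested pair of columns of a table,
#' the screen used to relate diazotroph abundances, rates and
#' environmental variables.
#'
#' @param data Data frame of variables.
#' @param pairs Data frame (or 2-column matrix) with columns `var1`,
#'   `var2` naming the pairs to test; defaults to all distinct column
#'   pairs of numeric variables.
#' @param exact_n Passed to [spearman_screen()].
#' @return Tibble with `var1`, `var2`, `rho`, `p`, `n`, `method`.
#' @export
association_screen <- function(data, pairs = NULL, exact_n = 8) {
  data <- tibble::as_tibble(data)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (is.null(pairs)) {
    if (length(num) < 2) stop("need >= 2 numeric variables",
                              call. = FALSE)
    cmb <- utils::combn(num, 2)
    pairs <- tibble::tibble(var1 = cmb[1, ], var2 = cmb[2, ])
  } else {
    pairs <- tibble::as_tibble(as.data.frame(pairs,
                                             stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("var1", "var2")
  }
  miss <- setdiff(unique(c(pairs$var1, pairs$var2)), names(data))
  if (length(miss)) {
    stop("unknown variables: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::bind_cols(
    pairs,
    dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      spearman_screen(data[[pairs$var1[i]]], data[[pairs$var2[i]]],
                      exact_n = exact_n)
    }))
  )
}
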