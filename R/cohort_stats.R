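#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by enumeration of the hypergeometric distribution with the
#' observed margins: the two-sided p sums the probabilities of every table
#' whose point probability does not exceed that of the observed table (the
#' minimum-likelihood rule used by mainstream scientific software). The
#' conditional maximum-likelihood odds ratio is reported alongside.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param odds_ratio Also compute the conditional MLE odds ratio (default
#'   `TRUE`; skip for bulk p-value computation).
#' @return List with `p.value`, `odds_ratio`, `method`.
#' @export
fisher_exact_2x2 <- function(table, odds_ratio = TRUE) {
  x <- as.matrix(table)
  if (!all(dim(x) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warning("degenerate margin: p = 1")
    return(list(p.value = 1, odds_ratio = NA_real_,
                method = "degenerate margin"))
  }
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); N <- sum(x)
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(x[1, 1], c1, N - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (odds_ratio) unname(stats::fisher.test(x)$estimate) else NA_real_
  list(p.value = p, odds_ratio = or, method = "exact hypergeometric")
}

# log multivariate hypergeometric probability of a table given its margins
log_table_prob <- function(x) {
  sum(lfactorial(rowSums(x))) + sum(lfactorial(colSums(x))) -
    lfactorial(sum(x)) - sum(lfactorial(x))
}

# recursively enumerate all r x c tables with the given margins, calling
# fun(table) on each
enumerate_margin_tables <- function(row_sums, col_sums, fun) {
  r <- length(row_sums); cc <- length(col_sums)
  tab <- matrix(0L, r, cc)
  fill_row <- function(i, col_rem) {
    if (i == r) {
      tab[r, ] <<- col_rem
      if (all(col_rem >= 0)) fun(tab)
      return(invisible())
    }
    fill_cell <- function(j, remaining) {
      if (j == cc) {
        if (remaining <= col_rem[cc]) {
          tab[i, cc] <<- remaining
          fill_row(i + 1L, col_rem - tab[i, ])
        }
        return(invisible())
      }
      for (v in 0:min(remaining, col_rem[j])) {
        tab[i, j] <<- v
        fill_cell(j + 1L, remaining - v)
      }
    }
    fill_cell(1L, row_sums[i])
    invisible()
  }
  fill_row(1L, col_sums)
  invisible()
}

#' Two-sided exact test for an r x c table (Freeman-Halton)
#'
#' Generalizes the 2x2 exact test to larger contingency tables. When the
#' margin class is small enough, the p-value is computed by exhaustive
#' enumeration of every table with the observed margins (minimum-likelihood
#' rule); otherwise a Monte-Carlo estimate over random tables with the same
#' margins is returned, with its standard error.
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @param max_tables Enumeration bound (upper estimate of the number of
#'   tables); above it the Monte-Carlo path is taken.
#' @param mc_samples Monte-Carlo sample size.
#' @param seed Seed for the Monte-Carlo path.
#' @return List with `p.value`, `method`, and for Monte-Carlo also
#'   `std_error`.
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e7, mc_samples = 1e5,
                             seed = 1L) {
  x <- as.matrix(table)
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warning("degenerate margin: p = 1")
    return(list(p.value = 1, method = "degenerate margin"))
  }
  rs <- rowSums(x); cs <- colSums(x)
  lp_obs <- log_table_prob(x)
  # upper bound on the number of tables: compositions of each row over c cells
  est <- prod(vapply(rs[-length(rs)], function(ri)
    choose(ri + length(cs) - 1, length(cs) - 1), 1))
  if (is.finite(est) && est <= max_tables) {
    p <- 0
    enumerate_margin_tables(as.integer(rs), as.integer(cs), function(tab) {
      lp <- log_table_prob(tab)
      if (lp <= lp_obs + 1e-7) p <<- p + exp(lp)
    })
    list(p.value = min(1, p), method = "exhaustive enumeration")
  } else {
    set.seed(seed)
    sims <- stats::r2dtable(mc_samples, as.integer(rs), as.integer(cs))
    hits <- vapply(sims, function(tab) log_table_prob(tab) <= lp_obs + 1e-7,
                   NA)
    p <- mean(hits)
    list(p.value = p, method = "Monte Carlo",
         std_error = sqrt(p * (1 - p) / mc_samples))
  }
}

#' Mann-Whitney U test
#'
#' U statistic with midrank tie handling, reported for the first sample. The
#' two-sided p-value is exact — by enumeration of all assignments of the
#' pooled values to the two groups — when the pooled size is at most
#' `exact_max`, and otherwise uses the normal approximation with tie
#' correction (no continuity correction).
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param exact_max Pooled-size bound for the exact path (default 12).
#' @return List with `U`, `p.value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L)
    return(list(U = na * nb / 2, p.value = 1, method = "all values tied"))
  ranks <- rank(pooled)
  U <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (N <= exact_max) {
    combos <- utils::combn(N, na)
    obs_dev <- abs(U - mu)
    devs <- apply(combos, 2, function(idx)
      abs(sum(ranks[idx]) - na * (na + 1) / 2 - mu))
    p <- mean(devs >= obs_dev - 1e-9)
    return(list(U = U, p.value = p, method = "exact enumeration"))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- na * nb / 12 * (N + 1 - tie_term)
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation with tie correction")
}

#' Format a p-value for the baseline table
#'
#' Two decimals, three below 0.01, and `"<0.001"` below 0.001.
#' @param p Numeric p-value.
#' @return Character.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "<0.001"
    else if (pi < 0.01) sprintf("%.3f", pi)
    else sprintf("%.2f", pi)
  }, "")
}
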