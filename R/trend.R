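# Trend analysis of ordered survey categories (e.g. self-reported confidence
# bands) before vs after an intervention.

#' Build a 2 x k trend table
#'
#' Two rows of counts (pre and post) over at least two ordered categories
#' with integer scores. Used to test whether responses shift along the
#' category ordering between the two survey waves.
#'
#' @param pre,post Non-negative integer count vectors of equal length >= 2.
#' @param scores Integer scores encoding the category order; defaults to
#'   `0, 1, ..., k-1`.
#' @param categories Optional category labels.
#' @return A `trend_table`.
#' @export
#' @examples
#' trend_table(pre = c(10, 5, 5), post = c(5, 5, 10))
trend_table <- function(pre, post, scores = seq_along(pre) - 1,
                        categories = NULL) {
  if (length(pre) < 2) stop("trend is undefined for fewer than 2 categories",
                            call. = FALSE)
  if (length(post) != length(pre) || length(scores) != length(pre)) {
    stop("pre, post and scores must have equal length", call. = FALSE)
  }
  if (any(pre < 0) || any(post < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (sum(pre) + sum(post) == 0) stop("total count must be positive",
                                      call. = FALSE)
  structure(list(pre = as.numeric(pre), post = as.numeric(post),
                 scores = as.numeric(scores),
                 categories = categories %||%
                   paste0("category_", seq_along(pre))),
            class = "trend_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal pieces shared by the asymptotic test and the permutation oracle:
# the linear-trend statistic is T = sum(scores * post counts); under the
# null that the post row is a random draw of its size from the pooled
# column margins, T has the hypergeometric mean/variance below.
.trend_moments <- function(tab) {
  n_i <- tab$pre + tab$post
  N <- sum(n_i)
  R2 <- sum(tab$post)
  R1 <- N - R2
  s <- tab$scores
  T_obs <- sum(s * tab$post)
  E <- R2 * sum(s * n_i) / N
  V <- R1 * R2 / (N^2 * (N - 1)) * (N * sum(s^2 * n_i) - sum(s * n_i)^2)
  list(T_obs = T_obs, E = E, V = V, N = N, R2 = R2, n_i = n_i)
}

#' Cochran-Armitage test for trend on a 2 x k table
#'
#' Tests for a linear trend in the proportion of post-row counts across
#' ordered categories. The statistic is the score-weighted post-row total
#' `T = sum(s_i * post_i)`, standardised by its exact conditional
#' (hypergeometric) mean and variance given the margins. The two-sided p
#' comes from the normal approximation, without continuity correction.
#'
#' Sign convention: positive Z means counts shift toward *higher*-score
#' categories in the post row relative to pre. Identical pre and post rows
#' give Z = 0, p = 1; reversing the category order flips the sign of Z
#' exactly.
#'
#' @param table A [trend_table()].
#' @return A list with `Z` (the standardised trend statistic), `p.value`
#'   (two-sided, normal approximation), and `statistic` (the raw
#'   score-weighted total `T`).
#' @seealso [ca_trend_permutation()], the permutation-null cross-check used
#'   as ground truth in the test suite.
#' @export
#' @examples
#' cochran_armitage_trend(trend_table(pre = c(10, 5, 5), post = c(5, 5, 10)))
cochran_armitage_trend <- function(table) {
  stopifnot(inherits(table, "trend_table"))
  m <- .trend_moments(table)
  if (m$V <= 0) {
    stop("trend statistic has zero variance (all mass in one category or constant scores)",
         call. = FALSE)
  }
  Z <- (m$T_obs - m$E) / sqrt(m$V)
  p <- min(1, 2 * stats::pnorm(-abs(Z)))
  list(Z = Z, p.value = p, statistic = m$T_obs)
}

#' Permutation-null cross-check for the trend test
#'
#' Monte-Carlo permutation version of the Cochran-Armitage test: the pooled
#' category scores are permuted and `R2` of them redrawn as the "post" row,
#' holding both margins fixed, which samples the exact conditional null the
#' asymptotic test approximates. Deliberately shares no code with
#' [cochran_armitage_trend()]'s standardisation: it is the independent
#' ground truth the test suite checks the normal approximation against.
#'
#' The permutation null is *discrete*: the trend statistic lives on a
#' lattice, and the probability mass sitting exactly at the observed
#' deviation can be several percent. A continuous approximation such as the
#' normal one can therefore only be expected to land inside that atom, so
#' the oracle reports the two-sided tail under all three conventions:
#' `p.inclusive` counts resamples with deviation `>=` the observed one,
#' `p.exclusive` counts `>` only, and `p.mid` splits the atom (the mid-p).
#' Agreement of the asymptotic p means lying in
#' `[p.exclusive, p.inclusive]` up to Monte-Carlo error.
#'
#' @param table A [trend_table()].
#' @param n_perm Number of resamples.
#' @param seed Integer seed for reproducibility.
#' @return A list with `p.value` (alias of `p.inclusive`, the conservative
#'   Monte-Carlo p with the +1 correction), `p.inclusive`, `p.exclusive`,
#'   `p.mid`, `Z` (observed deviation standardised by the permutation
#'   standard deviation), and `mc_se` (the Monte-Carlo standard error of a
#'   tail estimate).
#' @export
ca_trend_permutation <- function(table, n_perm = 10000, seed = 1) {
  stopifnot(inherits(table, "trend_table"))
  n_i <- table$pre + table$post
  R2 <- sum(table$post)
  pooled <- rep(table$scores, times = round(n_i))
  T_obs <- sum(table$scores * table$post)
  E <- R2 * mean(pooled)
  dev_obs <- abs(T_obs - E)
  T_star <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(sample(pooled, R2)), numeric(1))
  })
  dev <- abs(T_star - E)
  n_over <- sum(dev > dev_obs + 1e-9)
  n_at <- sum(abs(dev - dev_obs) <= 1e-9)
  p_incl <- (n_over + n_at + 1) / (n_perm + 1)
  p_excl <- n_over / n_perm
  list(p.value = p_incl,
       p.inclusive = p_incl,
       p.exclusive = p_excl,
       p.mid = (n_over + 0.5 * n_at) / n_perm,
       Z = (T_obs - E) / stats::sd(T_star),
       mc_se = sqrt(p_incl * (1 - p_incl) / n_perm))
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the Mersenne-Twister generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded helpers never perturb user
#' code. Mersenne-Twister is a named, portable algorithm: the same seed
#' yields the same sequence on every platform.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}
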