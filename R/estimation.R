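#' Paired mean difference
#'
#' Arithmetic mean of the pairwise differences `y[i] - x[i]`, the point
#' estimate reported with Gardner-Altman estimation plots.
#'
#' @param x,y Numeric vectors of equal length (`>= 2`).
#' @return Mean difference (numeric scalar).
#' @export
paired_mean_difference <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least two pairs", call. = FALSE)
  mean(y - x)
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' BCa interval for the mean of `x`: the bias correction `z0` is the normal
#' quantile of the fraction of bootstrap means below the point estimate, the
#' acceleration `a` comes from the jackknife skewness, and the interval
#' endpoints are the bootstrap distribution's quantiles at the adjusted
#' levels.  Deterministic given `seed`.
#'
#' @param x Numeric vector (`length >= 2`), typically per-dendrite
#'   differences.
#' @param n_resamples Bootstrap resamples (default 5000).
#' @param alpha Two-sided miscoverage (default 0.05 for a 95% CI).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param boot_stats Optional pre-computed bootstrap means (overrides
#'   resampling; used for cross-validation against reference
#'   implementations).
#' @return Named numeric `c(ci_low, ci_high)` with attributes `z0` and
#'   `acceleration`.  When every value of `x` is identical the degenerate
#'   interval `[d, d]` is returned.
#' @export
bca_bootstrap_ci <- function(x, n_resamples = 5000, alpha = 0.05,
                             seed = NULL, boot_stats = NULL) {
  m <- length(x)
  if (m < 2) stop("need at least two values", call. = FALSE)
  if (diff(range(x)) == 0) {
    out <- c(ci_low = x[1], ci_high = x[1])
    attr(out, "z0") <- 0; attr(out, "acceleration") <- 0
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  theta <- mean(x)
  if (is.null(boot_stats)) {
    idx <- sample.int(m, m * n_resamples, replace = TRUE)
    boot_stats <- rowMeans(matrix(x[idx], nrow = n_resamples))
  }
  B <- length(boot_stats)
  p0 <- sum(boot_stats < theta) / B
  p0 <- min(max(p0, 1 / (B + 1)), B / (B + 1))  # keep z0 finite
  z0 <- stats::qnorm(p0)
  # jackknife acceleration
  jack <- (sum(x) - x) / (m - 1)
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(boot_stats, probs = adj, names = FALSE, type = 7)
  out <- c(ci_low = ci[1], ci_high = ci[2])
  attr(out, "z0") <- z0
  attr(out, "acceleration") <- a
  out
}

#' Two-sided permutation t-test
#'
#' Permutation test on the t statistic.  For the paired and one-group
#' designs the null distribution is generated by sign-flipping the
#' (paired) differences; for the unpaired design, by permuting group
#' labels, with the Welch t statistic.  When the number of distinct
#' permutations is at most `max_exhaustive` they are enumerated
#' exhaustively; otherwise `n_resamples` Monte-Carlo permutations are drawn
#' and the observed arrangement is included in both numerator and
#' denominator (so `p > 0` always).
#'
#' @param x Numeric vector: the first sample (one-group: the values tested
#'   against `mu`).
#' @param y Optional second sample (paired: same length as `x`; the test is
#'   on `y - x`).
#' @param design `"one_group"`, `"paired"` or `"unpaired"`.
#' @param mu Null value for the one-group design (default 0).
#' @param n_resamples Monte-Carlo permutations when exhaustive enumeration
#'   is infeasible (default 10000).
#' @param max_exhaustive Largest permutation count enumerated exhaustively
#'   (default 2^20).
#' @param seed Integer seed for Monte-Carlo sampling.
#' @return A list with `p_value`, `t_obs`, `n_permutations` and `exhaustive`.
#'   Degenerate zero-variance data yield `p_value = 1`.
#' @examples
#' permutation_t_test(c(1, 2, 3, 4, 5), design = "one_group")$p_value  # 2/32
#' @export
permutation_t_test <- function(x, y = NULL,
                               design = c("one_group", "paired", "unpaired"),
                               mu = 0, n_resamples = 10000,
                               max_exhaustive = 2^20, seed = NULL) {
  design <- match.arg(design)
  if (!is.null(seed)) set.seed(seed)

  if (design != "unpaired") {
    d <- switch(design,
                one_group = x - mu,
                paired = {
                  if (is.null(y) || length(y) != length(x)) {
                    stop("paired design needs `y` of the same length",
                         call. = FALSE)
                  }
                  y - x
                })
    m <- length(d)
    if (m < 2) stop("need at least two observations", call. = FALSE)
    if (all(d == 0)) {
      return(list(p_value = 1, t_obs = 0, n_permutations = 1L,
                  exhaustive = TRUE))
    }
    ssq <- sum(d^2)
    t_of_sum <- function(s) {
      # for sign-flipped data the sum of squares is invariant
      mean_ <- s / m
      v <- (ssq - s^2 / m) / (m - 1)
      ifelse(v > 0, mean_ / sqrt(v / m), sign(mean_) * Inf)
    }
    t_obs <- t_of_sum(sum(d))
    n_flips <- 2^m
    if (n_flips <= max_exhaustive) {
      sums <- d[1] * c(1, -1)
      for (j in 2:m) sums <- c(sums + d[j], sums - d[j])
      t_perm <- t_of_sum(sums)
      p <- mean(abs(t_perm) >= abs(t_obs) - 1e-10)
      return(list(p_value = p, t_obs = t_obs,
                  n_permutations = as.integer(n_flips), exhaustive = TRUE))
    }
    signs <- matrix(sample(c(-1, 1), m * n_resamples, replace = TRUE),
                    nrow = n_resamples)
    t_perm <- t_of_sum(as.numeric(signs %*% d))
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-10)) / (n_resamples + 1)
    return(list(p_value = p, t_obs = t_obs,
                n_permutations = as.integer(n_resamples), exhaustive = FALSE))
  }

  # unpaired: label permutations with the Welch t statistic
  if (is.null(y)) stop("unpaired design needs `y`", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least two per group", call. = FALSE)
  pool <- c(x, y)
  if (diff(range(pool)) == 0) {
    return(list(p_value = 1, t_obs = 0, n_permutations = 1L,
                exhaustive = TRUE))
  }
  welch_t <- function(idx1) {
    a <- pool[idx1]; b <- pool[-idx1]
    se <- sqrt(stats::var(a) / n1 + stats::var(b) / n2)
    if (se == 0) return(sign(mean(a) - mean(b)) * Inf)
    (mean(a) - mean(b)) / se
  }
  t_obs <- welch_t(seq_len(n1))
  n_comb <- choose(n1 + n2, n1)
  if (n_comb <= max_exhaustive) {
    combs <- utils::combn(n1 + n2, n1)
    t_perm <- apply(combs, 2, welch_t)
    p <- mean(abs(t_perm) >= abs(t_obs) - 1e-10)
    return(list(p_value = p, t_obs = t_obs,
                n_permutations = as.integer(n_comb), exhaustive = TRUE))
  }
  t_perm <- vapply(seq_len(n_resamples), function(i) {
    welch_t(sample.int(n1 + n2, n1))
  }, numeric(1))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-10)) / (n_resamples + 1)
  list(p_value = p, t_obs = t_obs, n_permutations = as.integer(n_resamples),
       exhaustive = FALSE)
}

#' Pearson or Spearman correlation
#'
#' Thin wrapper over [stats::cor()] adding the domain's error conventions:
#' series must have at least three points and non-zero variance.  Spearman
#' uses average ranks for ties.
#'
#' @param series_a,series_b Numeric vectors of equal length (>= 3).
#' @param kind `"pearson"` or `"spearman"`.
#' @return Correlation coefficient.
#' @export
correlations <- function(series_a, series_b,
                         kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  if (length(series_a) != length(series_b) || length(series_a) < 3) {
    stop("series must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  stats::cor(series_a, series_b, method = kind)
}

#' Estimation-statistics group summary
#'
#' Per-group (or per-contrast) mean difference with BCa bootstrap 95%
#' confidence interval and two-sided permutation t-test p-value, the
#' numbers reported alongside slopegraphs and Gardner-Altman plots.  Three
#' designs are supported: each group's mean tested against zero
#' (`"one_group_vs_zero"`, used for nonlinearity-vs-0 contrasts), paired
#' differences between two conditions sharing a unit id (`"paired"`, used
#' for before/after drug wash-in), and unpaired two-group contrasts.
#'
#' @param data A data frame of per-dendrite results.
#' @param value Column (tidy-eval) holding the measured value.
#' @param group Optional column identifying groups/conditions.
#' @param pair_id Column identifying the experimental unit for the paired
#'   design.
#' @param design `"one_group_vs_zero"`, `"paired"` or `"unpaired"`.
#' @param n_resamples Bootstrap resamples (default 5000).
#' @param perm_resamples Monte-Carlo permutations when exhaustive
#'   enumeration is infeasible (default 10000).
#' @param alpha Miscoverage for the CI (default 0.05).
#' @param seed Integer seed (default 1).
#' @return A tibble with one row per group or contrast: `contrast`,
#'   `design`, `estimate`, `ci_low`, `ci_high`, `p_value`, `n`,
#'   `n_resamples`, `seed`.  Groups with fewer than two units are dropped
#'   with a warning.
#' @export
group_summary <- function(data, value, group = NULL, pair_id = NULL,
                          design = c("one_group_vs_zero", "paired",
                                     "unpaired"),
                          n_resamples = 5000, perm_resamples = 10000,
                          alpha = 0.05, seed = 1L) {
  design <- match.arg(design)
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  pair_id <- rlang::enquo(pair_id)
  has_group <- !rlang::quo_is_null(group)

  summarize_one <- function(vals, label) {
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2) {
      warning(sprintf("group '%s' has fewer than two units; skipped", label),
              call. = FALSE)
      return(NULL)
    }
    ci <- bca_bootstrap_ci(vals, n_resamples, alpha, seed = seed)
    pt <- permutation_t_test(vals, design = "one_group",
                             n_resamples = perm_resamples, seed = seed)
    tibble::tibble(contrast = label, design = design,
                   estimate = mean(vals), ci_low = ci[["ci_low"]],
                   ci_high = ci[["ci_high"]], p_value = pt$p_value,
                   n = length(vals), n_resamples = n_resamples,
                   seed = as.integer(seed))
  }

  if (design == "one_group_vs_zero") {
    groups <- if (has_group) {
      split(dplyr::pull(data, !!value), dplyr::pull(data, !!group))
    } else {
      list(`vs 0` = dplyr::pull(data, !!value))
    }
    rows <- purrr::imap(groups, function(v, nm) {
      summarize_one(v, paste(nm, "vs 0"))
    })
    return(dplyr::bind_rows(purrr::compact(rows)))
  }

  if (!has_group) stop("`group` is required for this design", call. = FALSE)
  g <- as.factor(dplyr::pull(data, !!group))
  if (nlevels(g) != 2) {
    stop("paired/unpaired designs need exactly two groups", call. = FALSE)
  }
  v <- dplyr::pull(data, !!value)
  lv <- levels(g)
  label <- paste(lv[2], "minus", lv[1])

  if (design == "paired") {
    if (rlang::quo_is_null(pair_id)) {
      stop("`pair_id` is required for the paired design", call. = FALSE)
    }
    id <- dplyr::pull(data, !!pair_id)
    wide <- split(stats::setNames(v, id), g)
    common <- intersect(names(wide[[1]]), names(wide[[2]]))
    if (length(common) < 2) {
      warning("fewer than two complete pairs; skipped", call. = FALSE)
      return(tibble::tibble())
    }
    d <- wide[[lv[2]]][common] - wide[[lv[1]]][common]
    out <- summarize_one(as.numeric(d), label)
    if (!is.null(out)) out$design <- "paired"
    return(out %||% tibble::tibble())
  }

  # unpaired: BCa on the two-sample mean difference (stratified resampling;
  # acceleration from the combined leave-one-out jackknife)
  x <- v[g == lv[1]]; y <- v[g == lv[2]]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    warning("fewer than two units in a group; skipped", call. = FALSE)
    return(tibble::tibble())
  }
  set.seed(seed)
  boots <- vapply(seq_len(n_resamples), function(i) {
    mean(sample(y, replace = TRUE)) - mean(sample(x, replace = TRUE))
  }, numeric(1))
  est <- mean(y) - mean(x)
  jack <- c(vapply(seq_along(x), function(i) mean(y) - mean(x[-i]), numeric(1)),
            vapply(seq_along(y), function(i) mean(y[-i]) - mean(x), numeric(1)))
  u <- mean(jack) - jack
  denom <- sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  p0 <- sum(boots < est) / n_resamples
  p0 <- min(max(p0, 1 / (n_resamples + 1)), n_resamples / (n_resamples + 1))
  z0 <- stats::qnorm(p0)
  zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- stats::quantile(boots, adj, names = FALSE, type = 7)
  pt <- permutation_t_test(x, y, design = "unpaired",
                           n_resamples = perm_resamples, seed = seed)
  tibble::tibble(contrast = label, design = "unpaired", estimate = est,
                 ci_low = ci[1], ci_high = ci[2], p_value = pt$p_value,
                 n = length(x) + length(y), n_resamples = n_resamples,
                 seed = as.integer(seed))
}
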