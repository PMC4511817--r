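#' Grouped sample of a per-feature metric
#'
#' One numeric vector of metric values per benthic class, with a record of
#' any transformation applied.
#'
#' @param values numeric vector of metric values (one per feature).
#' @param groups class label per value (factor or character).
#' @return A `grouped_sample`: named list of numeric vectors with attribute
#'   `transform_applied` (`"none"` or `"log"`).
#' @export
grouped_sample <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  sp <- split(as.numeric(values[keep]), as.character(groups[keep]))
  if (any(lengths(sp) == 0)) stop("every group must be nonempty")
  structure(sp, class = "grouped_sample", transform_applied = "none")
}

# pooled skewness of within-group residuals (biased moment estimator)
.pooled_skewness <- function(sample) {
  res <- unlist(lapply(sample, function(v) v - mean(v)), use.names = FALSE)
  m2 <- mean(res^2)
  if (m2 == 0) return(0)
  mean(res^3) / m2^1.5
}

#' Screen residual skewness and log-transform if needed
#'
#' Applies the natural log when the pooled within-group residual skewness
#' exceeds `threshold` in absolute value (default 1), or when `force` is
#' `TRUE`; the decision is recorded in the `transform_applied` attribute.
#' Transforming non-positive values is an error naming the offending group.
#'
#' @param sample a [grouped_sample()].
#' @param threshold absolute skewness above which the log is applied.
#' @param force `TRUE`/`FALSE` to override the screen; `NULL` (default) to
#'   let the screen decide.
#' @return The (possibly transformed) `grouped_sample`.
#' @export
screen_and_transform <- function(sample, threshold = 1, force = NULL) {
  skew <- .pooled_skewness(sample)
  do_log <- if (!is.null(force)) isTRUE(force) else abs(skew) > threshold
  if (!do_log) {
    attr(sample, "transform_applied") <- "none"
    attr(sample, "skewness") <- skew
    return(sample)
  }
  for (g in names(sample)) {
    bad <- sample[[g]] <= 0
    if (any(bad))
      stop("log transform triggered but group ", sQuote(g),
           " contains non-positive value ", sample[[g]][bad][1])
  }
  out <- lapply(sample, log)
  structure(out, class = "grouped_sample", transform_applied = "log",
            skewness = skew)
}

.sample_to_df <- function(sample) {
  data.frame(
    value = unlist(sample, use.names = FALSE),
    group = factor(rep(names(sample), lengths(sample)),
                   levels = names(sample)))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition (fitted via [stats::lm()]):
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom.
#'
#' @param sample a [grouped_sample()] with at least two groups.
#' @return An `anova_result`: list with `F`, `df_between`, `df_within`,
#'   `p`, `group_means`, `ms_within`.
#' @export
one_way_anova <- function(sample) {
  k <- length(sample)
  if (k < 2) stop("ANOVA needs at least 2 groups")
  df <- .sample_to_df(sample)
  if (nrow(df) <= k) stop("total N must exceed the number of groups")
  if (stats::var(df$value) == 0)
    stop("degenerate sample: no variation within or between groups")
  fit <- stats::lm(value ~ group, data = df)
  an <- stats::anova(fit)
  structure(
    list(F = an$`F value`[1],
         df_between = an$Df[1], df_within = an$Df[2],
         p = an$`Pr(>F)`[1],
         group_means = vapply(sample, mean, 0),
         ms_within = an$`Mean Sq`[2]),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Tukey's HSD pairwise comparisons
#'
#' For each pair of groups the studentized range statistic
#' `q = |mean_i - mean_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))`
#' (the Tukey-Kramer form for unequal n) with the adjusted p-value from the
#' studentized-range distribution on `(k, df_within)`.
#'
#' @param sample a [grouped_sample()] with at least two groups.
#' @param alpha family-wise significance level, default 0.01.
#' @return A `tibble`: `group_1`, `group_2`, `diff` (mean_2 - mean_1), `q`,
#'   `p_adj`, `significant`.
#' @export
tukey_hsd <- function(sample, alpha = 0.01) {
  if (length(sample) < 2) stop("Tukey's HSD needs at least 2 groups")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  an <- one_way_anova(sample)
  k <- length(sample)
  means <- vapply(sample, mean, 0)
  ns <- lengths(sample)
  pairs <- utils::combn(names(sample), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- means[[j]] - means[[i]]
    se <- sqrt(an$ms_within / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    tibble::tibble(group_1 = i, group_2 = j, diff = d, q = q, p_adj = p,
                   significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' MANOVA via Wilks' lambda with Rao's F approximation
#'
#' Computes the within- (`W`) and between-group (`B`) cross-product
#' matrices of the response matrix, `lambda = det(W) / det(W + B)`, and
#' Rao's approximate F. With a single response this reduces exactly to the
#' one-way ANOVA F.
#'
#' @param responses numeric matrix or data frame, one column per response
#'   metric, one row per feature.
#' @param groups class label per row.
#' @return A `manova_result`: list with `lambda`, `F`, `df1`, `df2`, `p`.
#' @export
wilks_manova <- function(responses, groups) {
  Y <- as.matrix(responses)
  storage.mode(Y) <- "double"
  groups <- factor(groups)
  stopifnot(nrow(Y) == length(groups))
  N <- nrow(Y); p <- ncol(Y); k <- nlevels(groups)
  if (k < 2) stop("MANOVA needs at least 2 groups")
  if (N <= k + 1) stop("MANOVA needs N > k + 1")
  grand <- colMeans(Y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (g in levels(groups)) {
    Yg <- Y[groups == g, , drop = FALSE]
    mg <- colMeans(Yg)
    cg <- sweep(Yg, 2, mg)
    W <- W + crossprod(cg)
    B <- B + nrow(Yg) * tcrossprod(mg - grand)
  }
  detW <- det(W)
  if (!is.finite(detW) || detW <= 0 || rcond(W) < 1e-12)
    stop("deficient within-group variation: W is singular")
  lambda <- detW / det(W + B)
  nu_h <- k - 1; nu_e <- N - k
  t_den <- p^2 + nu_h^2 - 5
  t_fac <- if (t_den > 0) sqrt((p^2 * nu_h^2 - 4) / t_den) else 1
  df1 <- p * nu_h
  wq <- nu_e + nu_h - (p + nu_h + 1) / 2
  df2 <- wq * t_fac - (p * nu_h - 2) / 2
  lam_t <- lambda^(1 / t_fac)
  Fstat <- (1 - lam_t) / lam_t * df2 / df1
  structure(
    list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
         p = stats::pf(Fstat, df1, df2, lower.tail = FALSE)),
    class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("<manova_result> Wilks' lambda = %.4g, F(%g, %.4g) = %.4g, p = %.4g\n",
              x$lambda, x$df1, x$df2, x$F, x$p))
  invisible(x)
}
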