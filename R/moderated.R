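# Shared two-group testing engine used by both the expression and the
# methylation modules. The moderated variant shrinks per-feature residual
# variances towards a common prior fitted by method of moments on
# log-variances (scaled-F model: s^2 ~ s0^2 * F(d, d0)).

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on a
#' transformed scale. Used when fitting the variance-prior degrees of
#' freedom from the spread of log residual variances.
#'
#' @param x Positive numeric vector.
#' @return `y` such that `trigamma(y) = x`; `Inf` maps to 0-adjacent
#'   input, very small `x` maps to large `y`.
#' @keywords internal
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, numeric(1))
}

#' Fit a scaled inverse-chi-square prior to residual variances
#'
#' Models observed residual variances as `s^2 ~ s0^2 * F(df, d0)` and
#' estimates the prior degrees of freedom `d0` and prior variance
#' `s0^2` by matching the mean and variance of `log(s^2)`
#' (digamma/trigamma moment equations). This is the standard
#' empirical-Bayes hyperparameter fit behind moderated t-statistics.
#'
#' @param s2 Vector of per-feature residual variances (must contain at
#'   least 2 positive values).
#' @param df Residual degrees of freedom of each `s2` (scalar).
#' @return List with `df_prior` (`d0`, possibly `Inf`) and `var_prior`
#'   (`s0^2`).
#' @export
fit_variance_prior <- function(s2, df) {
  if (df <= 0) stop("residual degrees of freedom must be positive")
  s2 <- s2[is.finite(s2)]
  s2 <- pmax(s2, 1e-12 * stats::median(s2[s2 > 0], na.rm = TRUE))
  if (length(s2) < 2) stop("need at least two finite residual variances")
  z <- log(s2)
  emean <- mean(z)
  evar <- stats::var(z)
  resid_var <- evar - trigamma(df / 2)
  if (is.finite(resid_var) && resid_var > 0) {
    d0 <- 2 * trigamma_inverse(resid_var)
    s0 <- exp(emean - digamma(df / 2) + log(df / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- exp(emean - digamma(df / 2) + log(df / 2))
  }
  list(df_prior = d0, var_prior = s0)
}

#' Moderated (or plain) two-group test per feature
#'
#' For each row of `x`, compares the two groups defined by `classes`
#' with a pooled-variance linear-model t-statistic. With
#' `moderated = TRUE` the per-feature variance is replaced by the
#' posterior `(d0*s0^2 + df*s^2) / (d0 + df)` with hyperparameters
#' fitted by [fit_variance_prior()] (or supplied), and the t-statistic
#' is referred to `df + d0` degrees of freedom. With
#' `moderated = FALSE` this is the classical equal-variance two-sample
#' t-test.
#'
#' @param x Numeric matrix, features x samples (rownames = feature ids).
#' @param classes Character/factor of length `ncol(x)` with exactly two
#'   levels; the reported difference is `mean(level1) - mean(level2)`
#'   where `level1` is the first factor level.
#' @param moderated Apply empirical-Bayes variance shrinkage?
#' @param d0,s0_sq Optional prior hyperparameter overrides (bypass the
#'   moment fit); `d0 = 0` reproduces the unmoderated test, `d0 = Inf`
#'   a pooled-prior z-like statistic.
#' @return data.frame with columns `feature`, `diff`, `t`, `p_value`,
#'   `df_total`, `s2`, `s2_post`, plus attributes `df_prior`,
#'   `var_prior`.
#' @export
two_group_test <- function(x, classes, moderated = TRUE, d0 = NULL, s0_sq = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (length(classes) != ncol(x)) {
    stop("length(classes) must equal ncol(x)")
  }
  f <- if (is.factor(classes)) droplevels(classes) else factor(classes)
  if (nlevels(f) != 2) stop("classes must have exactly two levels")
  g1 <- f == levels(f)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least 2 samples (got ", n1, " and ", n2, ")")
  }
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  rss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
    rowSums((x[, g2, drop = FALSE] - m2)^2)
  df_resid <- n1 + n2 - 2
  s2 <- rss / df_resid
  diff <- m1 - m2

  if (moderated) {
    if (is.null(d0) || is.null(s0_sq)) {
      prior <- fit_variance_prior(s2, df_resid)
      if (is.null(d0)) d0 <- prior$df_prior
      if (is.null(s0_sq)) s0_sq <- prior$var_prior
    }
    if (is.infinite(d0)) {
      s2_post <- rep(s0_sq, length(s2))
      df_total <- Inf
    } else {
      s2_post <- (d0 * s0_sq + df_resid * s2) / (d0 + df_resid)
      df_total <- df_resid + d0
    }
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_post <- s2
    df_total <- df_resid
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[is.infinite(tstat)] <- 0
  p[se == 0 & diff == 0] <- 1

  out <- data.frame(
    feature = if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x),
    diff = diff, t = tstat, p_value = p,
    df_total = df_total, s2 = s2, s2_post = s2_post,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s0_sq
  out
}
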