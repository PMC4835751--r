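#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (>= 3 values). A zero-variance
#'   input yields NA with a warning (undefined, not 0).
#' @return correlation in [-1, 1], or NA when undefined.
#' @examples
#' pearsonR(1:4, c(1, 3, 2, 5))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired values are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA: \code{F = MS_between / MS_within}
#' with \code{(k - 1, N - k)} degrees of freedom, p-value from the F
#' distribution. When both between- and within-group sums of squares vanish
#' (all values identical) F is 0 and p is 1.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return list: \code{f_statistic}, \code{df_between}, \code{df_within},
#'   \code{p_value}, \code{group_means}.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5 on (1, 4) df
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("at least 2 groups are required")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 values")
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  means <- vapply(groups, mean, 1)
  grand <- sum(ns * means) / N
  ssB <- sum(ns * (means - grand)^2)
  ssW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfB <- k - 1L
  dfW <- N - k
  if (ssW == 0 && ssB == 0) {
    f <- 0; p <- 1
  } else {
    f <- (ssB / dfB) / (ssW / dfW)
    p <- stats::pf(f, dfB, dfW, lower.tail = FALSE)
  }
  list(f_statistic = f, df_between = dfB, df_within = dfW, p_value = p,
       group_means = means)
}

#' Tukey-Kramer post hoc comparisons
#'
#' All pairwise comparisons after a one-way ANOVA, using the studentized
#' range statistic with the Kramer adjustment for unequal group sizes:
#' \code{q = |m_i - m_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))}, p-values
#' from the studentized range distribution (\code{ptukey}). With equal group
#' sizes the Kramer term reduces to the classic Tukey term.
#'
#' @param groups list of >= 2 numeric vectors (named or not), each >= 2
#'   values.
#' @param alpha significance level; default 0.05.
#' @return data.frame: \code{group_a}, \code{group_b}, \code{mean_diff},
#'   \code{q_statistic}, \code{p_value}, \code{significant}.
#' @export
tukeyKramer <- function(groups, alpha = 0.05) {
  aov1 <- oneWayAnova(groups)
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  means <- aov1$group_means
  dfW <- aov1$df_within
  msW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / dfW
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- vector("list", ncol(pairs))
  for (c2 in seq_len(ncol(pairs))) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    se <- sqrt(msW / 2 * (1 / ns[i] + 1 / ns[j]))
    diff <- means[j] - means[i]
    if (se == 0) {
      q <- if (diff == 0) 0 else Inf
      p <- if (diff == 0) 1 else 0
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = dfW, lower.tail = FALSE)
    }
    out[[c2]] <- data.frame(group_a = nms[i], group_b = nms[j],
                            mean_diff = diff, q_statistic = q,
                            p_value = p, significant = p < alpha,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Student t tests (two-sample pooled-variance, or one-sample)
#'
#' Two-sided throughout. The two-sample form is the pooled-variance Student
#' t (not Welch); the one-sample form tests against \code{mu0}. Inputs with
#' (essentially) zero variance yield NA statistics with an undefined flag.
#'
#' @param a numeric vector (>= 2 values).
#' @param b optional second sample for the two-sample form.
#' @param mu0 null mean for the one-sample form (required when \code{b} is
#'   missing).
#' @return list: \code{statistic}, \code{df}, \code{p_value}, \code{type}
#'   (\code{"two_sample"} or \code{"one_sample"}), \code{undefined}
#'   (logical).
#' @examples
#' tTests(c(1, 2, 3, 4), c(2, 3, 4, 5))  # t = -1.095 on 6 df
#' tTests(c(1, 2, 3), mu0 = 2)           # t = 0
#' @export
tTests <- function(a, b = NULL, mu0 = NULL) {
  if (length(a) < 2) stop("sample 'a' needs at least 2 values")
  if (is.null(b) && is.null(mu0))
    stop("provide either a second sample 'b' or a null mean 'mu0'")
  res <- tryCatch({
    if (!is.null(b)) {
      if (length(b) < 2) stop("sample 'b' needs at least 2 values")
      tt <- stats::t.test(a, b, var.equal = TRUE)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, type = "two_sample", undefined = FALSE)
    } else {
      tt <- stats::t.test(a, mu = mu0)
      list(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, type = "one_sample", undefined = FALSE)
    }
  }, error = function(e) {
    if (grepl("constant", conditionMessage(e))) {
      warning("zero variance: t statistic undefined")
      list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
           type = if (!is.null(b)) "two_sample" else "one_sample",
           undefined = TRUE)
    } else stop(e)
  })
  res
}
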