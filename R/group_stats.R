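#' Band centers of the central and peripheral eccentricity subsets
#'
#' Default dependent-variable subsets for the group comparisons: the central
#' 3 degrees (bands centered 0.5, 1.5, 2.5) and the peripheral 3-10 degrees
#' (bands centered 3.5 ... 9.5). When the surface-area-percent restriction to
#' 1-10 degrees is active, the central subset drops the 0.5-degree band.
#'
#' @param restricted drop the 0.5-degree band from the central subset.
#' @return numeric band centers.
#' @export
central_bands <- function(restricted = FALSE) {
  if (restricted) c(1.5, 2.5) else c(0.5, 1.5, 2.5)
}

#' @rdname central_bands
#' @export
peripheral_bands <- function() seq(3.5, 9.5, by = 1)

new_group_comparison <- function(test, statistic, df, p_value,
                                 band_subset = NULL, map = NULL,
                                 extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value, band_subset = band_subset, map = map),
              extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  dfs <- paste(round(x$df, 1), collapse = ", ")
  lab <- switch(x$test, manova = "Wilks MANOVA, exact F",
                anova = "one-way ANOVA F", ttest = "two-sample pooled t")
  cat(sprintf("%s%s: %s(%s) = %.3f, p = %.4g\n",
              if (!is.null(x$map)) paste0(x$map, ": ") else "", lab,
              if (x$test == "ttest") "t" else "F", dfs, x$statistic,
              x$p_value))
  if (!is.null(x$band_subset))
    cat("  bands:", paste(x$band_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Two-group MANOVA over eccentricity-band values
#'
#' One-way multivariate analysis of variance comparing two subject groups on
#' a set of band values (e.g., surface-area percent in the central-3-degree
#' bands). For two groups, Wilks' lambda has an exact F transform (the
#' Hotelling T^2 case): F = ((N - p - 1)/p) (1 - Lambda)/Lambda on
#' (p, N - p - 1) degrees of freedom, where p is the number of dependent
#' variables and N the total number of subjects. Degrees of freedom are
#' always reported as (df-effect, df-error) in that order.
#'
#' @param group1,group2 subjects x bands numeric matrices (or data.frames),
#'   one row per subject, columns in the same band order.
#' @param band_subset optional column indices or names selecting the
#'   dependent variables (default: all columns).
#' @param map optional map label carried into the result.
#' @return a `group_comparison` with the F statistic, Wilks' lambda, df and
#'   p-value.
#' @examples
#' g1 <- matrix(rnorm(15), 5, 3); g2 <- matrix(rnorm(12, 1), 4, 3)
#' manova_bands(g1, g2)   # df = (3, 5) for 9 subjects, 3 bands
#' @export
manova_bands <- function(group1, group2, band_subset = NULL, map = NULL) {
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  if (!is.null(band_subset)) {
    g1 <- g1[, band_subset, drop = FALSE]
    g2 <- g2[, band_subset, drop = FALSE]
  }
  if (ncol(g1) != ncol(g2))
    stop("groups must share the same dependent variables", call. = FALSE)
  p <- ncol(g1)
  n1 <- nrow(g1); n2 <- nrow(g2); n <- n1 + n2
  if (p >= n - 1)
    stop("need more subjects than dependent variables (p = ", p,
         ", N = ", n, ")", call. = FALSE)
  m1 <- colMeans(g1); m2 <- colMeans(g2); mg <- (n1 * m1 + n2 * m2) / n
  e <- crossprod(sweep(g1, 2, m1)) + crossprod(sweep(g2, 2, m2))
  h <- n1 * tcrossprod(m1 - mg) + n2 * tcrossprod(m2 - mg)
  if (qr(e)$rank < p) {
    v <- diag(e)
    bad <- which(v <= max(v) * 1e-12)
    stop("singular within-group covariance; deficient dimension(s): ",
         paste(if (length(bad)) colnames(e)[bad] %||% bad else "collinear set",
               collapse = ", "), call. = FALSE)
  }
  lambda <- det(e) / det(e + h)
  df1 <- p; df2 <- n - p - 1
  f <- (df2 / df1) * (1 - lambda) / lambda
  pval <- stats::pf(f, df1, df2, lower.tail = FALSE)
  new_group_comparison("manova", f, c(df1, df2), pval,
                       band_subset = colnames(g1) %||% band_subset, map = map,
                       extra = list(wilks_lambda = lambda, n = c(n1, n2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way ANOVA on total map surface area
#'
#' Compares total visual-field-map surface area between subject groups with a
#' standard one-way F test on (k - 1, N - k) degrees of freedom (reported as
#' (df-effect, df-error)).
#'
#' @param groups named list of numeric vectors, one value per subject.
#' @param map optional map label carried into the result.
#' @return a `group_comparison`.
#' @export
anova_total_area <- function(groups, map = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  fit <- stats::aov(value ~ grp)
  tab <- summary(fit)[[1]]
  f <- tab$`F value`[1]
  if (!is.finite(f))
    return(new_group_comparison("anova", NA_real_, c(tab$Df[1], tab$Df[2]),
                                NA_real_, map = map,
                                extra = list(flag = "zero residual variance")))
  new_group_comparison("anova", f, c(tab$Df[1], tab$Df[2]),
                       tab$`Pr(>F)`[1], map = map)
}

#' Two-sample pooled-variance t-test
#'
#' Two-tailed independent-samples t-test with pooled variance on
#' n1 + n2 - 2 degrees of freedom, either from raw samples
#' (`ttest_two_sample`, a thin wrapper around [stats::t.test()] with
#' `var.equal = TRUE`) or from summary statistics (`ttest_from_summary`),
#' e.g. when only group means and SDs are published.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return a `group_comparison`.
#' @export
ttest_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(c(a - mean(a), b - mean(b))) < 1e-24)
    stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = TRUE)
  new_group_comparison("ttest", unname(tt$statistic), unname(tt$parameter),
                       tt$p.value)
}

#' @rdname ttest_two_sample
#' @param mean1,sd1,n1,mean2,sd2,n2 group summary statistics.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  new_group_comparison("ttest", t, df,
                       2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
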