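#' Median and quartiles
#'
#' The reporting convention used throughout: median with 25th and 75th
#' percentiles (linear interpolation, `type = 7`).
#'
#' @param values Numeric vector, length >= 1.
#' @return Named numeric vector `median`, `q25`, `q75`.
#' @export
summarize_mq <- function(values) {
  if (length(values) == 0) stop("cannot summarize an empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

# Dunn's z-based pairwise comparisons on pooled ranks with tie correction
.dunn_test <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  k <- length(lev)
  z <- p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    zij <- (rbar[i] - rbar[j]) / se
    z[i, j] <- z[j, i] <- zij
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zij))
  }
  list(z = z, p = p)
}

#' Compare groups with rank-based statistics
#'
#' Per-group Shapiro-Wilk normality tests, the Kruskal-Wallis omnibus test
#' (one-way ANOVA on ranks) and Dunn's z-based pairwise comparisons with tie
#' correction. The pairwise multiple-testing adjustment is configurable
#' (`"none"` for Dunn's plain z comparisons, or `"bonferroni"`).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 3
#'   values).
#' @param alpha_level Significance level, default 0.05.
#' @param p_adjust `"none"` or `"bonferroni"` for the pairwise p-values.
#' @return A `group_comparison`: list with `summary` (per-group median/q25/
#'   q75/n and Shapiro-Wilk p), `kruskal` (statistic, df, p), `dunn` (z and p
#'   matrices), `significant` (logical pairwise matrix at `alpha_level`),
#'   `testable` (FALSE when all pooled values are identical).
#' @export
compare_groups <- function(groups, alpha_level = 0.05,
                           p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 3))
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  gl <- factor(rep(names(groups), lengths(groups)), levels = names(groups))

  summ <- do.call(rbind, lapply(names(groups), function(nm) {
    v <- groups[[nm]]
    sw <- if (length(unique(v)) > 2 && length(v) >= 3 && length(v) <= 5000)
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(group = nm, n = length(v), median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)), shapiro_p = sw)
  }))

  if (length(unique(values)) == 1) {
    return(structure(list(summary = summ, kruskal = NULL, dunn = NULL,
                          significant = NULL, testable = FALSE,
                          alpha_level = alpha_level, p_adjust = p_adjust),
                     class = "group_comparison"))
  }

  kw <- stats::kruskal.test(values, gl)
  dunn <- .dunn_test(values, gl)
  p <- dunn$p
  if (p_adjust == "bonferroni") {
    m <- length(groups) * (length(groups) - 1) / 2
    p <- pmin(p * m, 1)
  }
  structure(list(summary = summ,
                 kruskal = list(statistic = unname(kw$statistic),
                                df = unname(kw$parameter),
                                p = kw$p.value),
                 dunn = list(z = dunn$z, p = p),
                 significant = p < alpha_level, testable = TRUE,
                 alpha_level = alpha_level, p_adjust = p_adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (median (25th-75th percentile)):\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %s: %.4g (%.4g-%.4g), n = %d\n",
                s$group, s$median, s$q25, s$q75, s$n))
  }
  if (!x$testable) {
    cat("  all values identical: not testable\n")
  } else {
    cat(sprintf("  Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
                x$kruskal$statistic, x$kruskal$df, x$kruskal$p))
  }
  invisible(x)
}
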