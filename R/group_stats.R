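# Group-comparison layer: per-group normality screening (reported, never
# gating), tie-corrected Kruskal-Wallis omnibus, and Dunn's pairwise rank
# comparisons with multiplicity adjustment. Statistical units are vessels.

# D'Agostino & Pearson omnibus K^2 normality test: combines the standardized
# skewness and kurtosis statistics; K^2 ~ chi-square(2) under normality.
# Requires n >= 8 for the kurtosis approximation.
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) return(list(statistic = NA_real_, p.value = NA_real_))
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(list(statistic = NA_real_, p.value = NA_real_))
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zg1 <- delta * asinh(y / alpha)
  # kurtosis: Anscombe & Glynn (1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  b2s <- g2 + 3
  xx <- (b2s - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  inner <- (1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4)))
  zg2 <- ((1 - 2 / (9 * a)) - sign(inner) * abs(inner)^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- zg1^2 + zg2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

# run the four normality tests on one sample; returns a data frame row set
normality_screen <- function(x, group) {
  safe <- function(f) {
    tryCatch(f(), error = function(e) list(statistic = NA_real_,
                                           p.value = NA_real_))
  }
  tests <- list(
    dagostino_pearson = safe(function() dagostino_pearson(x)),
    anderson_darling = safe(function() nortest::ad.test(x)),
    shapiro_wilk = safe(function() stats::shapiro.test(x)),
    kolmogorov_smirnov = safe(function() nortest::lillie.test(x))
  )
  do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(group = group, test = nm,
               statistic = unname(as.numeric(t$statistic[1L])),
               p_value = unname(as.numeric(t$p.value[1L])))
  }))
}

# Kruskal-Wallis with the all-tied degenerate case defined as H = 0, p = 1
kruskal_safe <- function(values, groups) {
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p.value = 1,
                parameter = length(unique(groups)) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       parameter = unname(kt$parameter))
}

# Dunn's pairwise z-tests on the pooled ranks, with tie correction
dunn_pairwise <- function(values, groups, method = "holm") {
  g <- factor(groups)
  r <- rank(values)
  n <- length(values)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    se2 <- (n * (n + 1) / 12 - tie_term / (12 * (n - 1))) *
      (1 / ni[[a]] + 1 / ni[[b]])
    z[k] <- if (se2 > 0) (rbar[[a]] - rbar[[b]]) / sqrt(se2) else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
             z = z, p_value = p,
             p_adjusted = stats::p.adjust(p, method = method))
}

#' Compare a metric across groups
#'
#' Runs four normality tests per group (D'Agostino-Pearson, Anderson-Darling,
#' Shapiro-Wilk, Lilliefors/Kolmogorov-Smirnov; reported for transparency,
#' never used to switch the test), the tie-corrected Kruskal-Wallis omnibus
#' test, and Dunn's pairwise comparisons with Holm adjustment. Groups with
#' fewer than 3 values are excluded with a warning.
#'
#' @param samples Named list: group label -> numeric vector of per-vessel
#'   values.
#' @param alpha Significance threshold (default 0.05).
#' @param metric_name Label carried into the result.
#' @param p_adjust_method Multiplicity adjustment for the pairwise p-values
#'   (any [stats::p.adjust()] method; default "holm").
#' @param run_normality Run the normality screen (default TRUE; disable in
#'   simulation loops where only the omnibus result is consumed).
#' @return Object of class `group_comparison`: list with `metric_name`,
#'   `groups` (the usable samples), `normality` (data frame), `omnibus_stat`
#'   (Kruskal-Wallis H), `omnibus_df`, `omnibus_p`, `significant`, `pairwise`
#'   (data frame), `alpha`.
#' @export
compare_groups <- function(samples, alpha = 0.05, metric_name = "metric",
                           p_adjust_method = "holm", run_normality = TRUE) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  samples <- lapply(samples, function(x) x[is.finite(x)])
  small <- names(samples)[vapply(samples, length, integer(1L)) < 3L]
  if (length(small)) {
    warning("excluding group(s) with fewer than 3 values: ",
            paste(small, collapse = ", "))
    samples <- samples[!names(samples) %in% small]
  }
  if (length(samples) < 2L) stop("need at least 2 usable groups")
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(names(samples), vapply(samples, length, integer(1L))))
  norm <- if (run_normality) {
    do.call(rbind, lapply(names(samples), function(g) {
      normality_screen(samples[[g]], g)
    }))
  } else {
    NULL
  }
  kw <- kruskal_safe(values, groups)
  structure(list(metric_name = metric_name,
                 groups = samples,
                 normality = norm,
                 omnibus_stat = kw$statistic,
                 omnibus_df = kw$parameter,
                 omnibus_p = kw$p.value,
                 significant = kw$p.value < alpha,
                 pairwise = dunn_pairwise(values, groups,
                                          method = p_adjust_method),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis H = %.4g (df = %d), p = %.4g%s\n",
              x$metric_name, x$omnibus_stat, x$omnibus_df, x$omnibus_p,
              if (isTRUE(x$significant)) " *" else ""))
  cat("  groups:", paste(sprintf("%s (n=%d)", names(x$groups),
                                 lengths(x$groups)), collapse = ", "), "\n")
  sig <- x$pairwise[x$pairwise$p_adjusted < x$alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s vs %s: adjusted p = %.4g\n", sig$group_a[i],
                  sig$group_b[i], sig$p_adjusted[i]))
    }
  } else {
    cat("  no pairwise difference at alpha =", x$alpha, "\n")
  }
  invisible(x)
}
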