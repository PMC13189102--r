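#' @importFrom stats aov anova shapiro.test kruskal.test wilcox.test t.test
#'   fisher.test p.adjust TukeyHSD pnorm quantile sd var median rnorm runif
#'   rpois rbinom complete.cases setNames aggregate terms
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normality-gated choice between parametric and nonparametric branches
#'
#' Applies a Shapiro-Wilk test to every group and routes the analysis to the
#' nonparametric branch as soon as any single group departs from normality at
#' the chosen alpha. Groups that are too small (n < 3) or degenerate
#' (zero variance) cannot be assessed and conservatively force the
#' nonparametric branch with a warning.
#'
#' @param groups list of numeric vectors, one per group.
#' @param alpha significance level for the Shapiro-Wilk gate (default 0.05).
#' @return A list with `branch` ("parametric" or "nonparametric") and the
#'   per-group Shapiro-Wilk p-values (`NA` where not assessable).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1)
  pvals <- vapply(groups, function(g) {
    g <- g[is.finite(g)]
    if (length(g) < 3) return(NA_real_)
    if (stats::sd(g) == 0) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  if (anyNA(pvals)) {
    warning("group with n < 3 or degenerate variance: nonparametric branch forced")
    branch <- "nonparametric"
  } else {
    branch <- if (any(pvals < alpha)) "nonparametric" else "parametric"
  }
  list(branch = branch, shapiro_p = pvals, alpha = alpha)
}

#' One-way analysis of variance with eta-squared effect size
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `cq_stat` list with the F statistic, degrees of freedom, p-value
#'   and eta squared (SS_between / SS_total).
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs n >= 2 for one-way ANOVA")
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(y) == 0) {
    warning("zero total variance: F undefined")
    return(structure(list(test = "oneway_anova", statistic = NA_real_,
                          df = c(length(groups) - 1L, length(y) - length(groups)),
                          p = NA_real_, eta2 = NA_real_), class = "cq_stat"))
  }
  tab <- stats::anova(stats::aov(y ~ f))
  structure(list(
    test = "oneway_anova",
    statistic = unname(tab$`F value`[1]),
    df = c(unname(tab$Df[1]), unname(tab$Df[2])),
    p = unname(tab$`Pr(>F)`[1]),
    eta2 = unname(tab$`Sum Sq`[1] / sum(tab$`Sum Sq`))
  ), class = "cq_stat")
}

#' Main-effects ANOVA for multi-factor designs
#'
#' Sequential (Type-I) decomposition on a balanced or near-balanced design,
#' reporting F, p and eta squared for each factor's main effect. With a single
#' factor this reduces exactly to [oneway_anova()].
#'
#' @param response numeric response vector.
#' @param factors data.frame of factors (one column per factor).
#' @return data.frame with one row per factor: statistic, df1, df2, p, eta2.
#' @export
multiway_anova_main_effects <- function(response, factors) {
  factors <- as.data.frame(factors)
  stopifnot(nrow(factors) == length(response), ncol(factors) >= 1)
  factors[] <- lapply(factors, factor)
  if (any(vapply(factors, nlevels, 1L) < 2)) stop("each factor needs >= 2 levels")
  dat <- cbind(.y = response, factors)
  form <- stats::as.formula(paste(".y ~", paste(names(factors), collapse = " + ")))
  fit <- stats::aov(form, data = dat)
  tab <- stats::anova(fit)
  ss_total <- sum(tab$`Sum Sq`)
  k <- nrow(tab) - 1L  # last row is residuals
  data.frame(
    factor = rownames(tab)[seq_len(k)],
    statistic = tab$`F value`[seq_len(k)],
    df1 = tab$Df[seq_len(k)],
    df2 = tab$Df[nrow(tab)],
    p = tab$`Pr(>F)`[seq_len(k)],
    eta2 = tab$`Sum Sq`[seq_len(k)] / ss_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Tukey honestly-significant-difference post hoc comparisons
#'
#' @param groups list of numeric vectors; names are used as group labels.
#' @return data.frame with pairwise mean differences and Tukey-adjusted
#'   p-values (studentized-range family correction).
#' @export
tukey_hsd <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  labs <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- labs
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(labs, vapply(groups, length, 1L)), levels = labs)
  tk <- stats::TukeyHSD(stats::aov(y ~ f))$f
  data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"],
    lwr = tk[, "lwr"],
    upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis rank-sum test with H-based eta squared
#'
#' H is tie-corrected and reported on the chi-squared scale with k - 1
#' degrees of freedom. The effect size uses the H-based analogue
#' eta2_H = (H - k + 1) / (n - k).
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return A `cq_stat` list with statistic (H), df, p and eta2.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups); n <- length(y)
  if (length(unique(y)) == 1L) {
    return(structure(list(test = "kruskal_wallis", statistic = 0,
                          df = k - 1L, p = 1,
                          eta2 = (0 - k + 1) / (n - k)), class = "cq_stat"))
  }
  kt <- stats::kruskal.test(y, f)
  H <- unname(kt$statistic)
  structure(list(test = "kruskal_wallis", statistic = H, df = k - 1L,
                 p = kt$p.value, eta2 = (H - k + 1) / (n - k)),
            class = "cq_stat")
}

#' Dunn's post hoc z tests with Holm step-down adjustment
#'
#' Pairwise comparisons of mean ranks following a Kruskal-Wallis test, with
#' the usual tie correction of the rank variance, and Holm-adjusted p-values.
#'
#' @param groups list of numeric vectors; names are used as group labels.
#' @return data.frame with z, raw p and Holm-adjusted p per pair.
#' @export
dunn_holm <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  labs <- names(groups) %||% as.character(seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(y)
  r <- rank(y)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(y)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) return(0)
    (rbar[i] - rbar[j]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(
    comparison = apply(pairs, 2, function(ij) paste(labs[ij[1]], labs[ij[2]], sep = "-")),
    z = as.numeric(z),
    p = as.numeric(p_raw),
    p_adj = stats::p.adjust(p_raw, method = "holm"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 table \{a = overlap, b = |A| - a, c = |B| - a,
#' d = N - |A| - |B| + a\} against a stated background of size N and reports
#' the sample odds ratio ad/bc together with the two-sided exact
#' (hypergeometric) p-value.
#'
#' @param size_a,size_b sizes of the two sets.
#' @param overlap number of elements in both sets.
#' @param background total number of elements the sets are drawn from.
#' @return list with `odds_ratio`, `p` and the 2x2 `table`.
#' @export
fisher_overlap <- function(size_a, size_b, overlap, background) {
  if (overlap > min(size_a, size_b) || max(size_a, size_b) > background ||
      background - size_a - size_b + overlap < 0)
    stop("inconsistent set sizes for overlap test")
  a <- overlap
  b <- size_a - overlap
  c_ <- size_b - overlap
  d <- background - size_a - size_b + overlap
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  or <- if (b == 0 || c_ == 0) {
    if (a == 0) 0 else Inf
  } else a * d / (b * c_)
  if (a == 0) or <- 0
  list(odds_ratio = or,
       p = stats::fisher.test(tab)$p.value,
       table = tab)
}

#' Bootstrap estimation of a two-group mean difference
#'
#' Resamples within each group with replacement and reports the observed mean
#' difference (A minus B) with a percentile confidence interval. Deterministic
#' under a fixed seed.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param n_boot number of bootstrap resamples (default 5000).
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level for the percentile interval (default 0.95).
#' @return list with `mean_diff`, `ci` (lower, upper), `boot` (resampled
#'   differences) and the settings used.
#' @export
bootstrap_mean_diff <- function(group_a, group_b, n_boot = 5000, seed = 1,
                                conf = 0.95) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(sample(group_a, replace = TRUE)) - mean(sample(group_b, replace = TRUE))
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  list(mean_diff = mean(group_a) - mean(group_b),
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       boot = boot, n_boot = n_boot, conf = conf, seed = seed)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' @export
print.cq_stat <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 5),
      ", df = ", paste(x$df, collapse = ","),
      ", p = ", signif(x$p, 4), sep = "")
  if (!is.null(x$eta2) && !is.na(x$eta2))
    cat(", eta2 = ", signif(x$eta2, 4), sep = "")
  cat("\n")
  invisible(x)
}
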