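# Univariate association screen: rank/ANOVA/chi-squared tests with effect
# sizes and post-hoc Monte-Carlo power, mirroring the feature-screening
# tables of the analysis.

# Mann-Whitney U statistic for group1 (x) vs group2 (y): number of (x, y)
# pairs with x < y plus half-ties — the classical U of the first group.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# two-sided p by complete enumeration of all label assignments (exact
# permutation null); used for small samples
u_exact_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_statistic(pooled[ii], pooled[-ii]))
  u <- u_statistic(x, y)
  p_lo <- mean(us <= u); p_hi <- mean(us >= u)
  min(1, 2 * min(p_lo, p_hi))
}

# tie-corrected normal approximation with continuity correction
u_normal_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference (group1 - group2) with the pooled-variance
#' denominator.  Under the screening convention the symptomatic group is
#' passed second, so an elevated marker in that group yields a negative d.
#'
#' @param x,y Numeric samples for group 1 and group 2.
#' @return d; 0 when the pooled variance is 0 and the means are equal.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) return(if (dm == 0) 0 else sign(dm) * Inf)
  dm / sqrt(sp2)
}

# post-hoc Monte-Carlo power of the two-group U test at the observed |d| and
# group sizes: normal populations shifted by d, tested at alpha
mc_power_u <- function(d, n1, n2, B = 2000, alpha = 0.05, seed = 1L) {
  if (!is.finite(d)) d <- 3
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    x <- stats::rnorm(n1, abs(d)); y <- stats::rnorm(n2, 0)
    if (u_normal_p(x, y) < alpha) hits <- hits + 1L
  }
  hits / B
}

mc_power_anova <- function(eta2, ns, B = 2000, alpha = 0.05, seed = 1L) {
  eta2 <- min(max(eta2, 0), 0.99)
  f2 <- eta2 / (1 - eta2)
  k <- length(ns)
  # group means spread to achieve the observed eta-squared (centered contrast)
  spread <- sqrt(f2 * k / max(1, k - 1))
  mus <- scale(seq_len(k))[, 1] * spread
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  hits <- 0L
  g <- factor(rep(seq_len(k), ns))
  for (b in seq_len(B)) {
    v <- stats::rnorm(sum(ns), rep(mus, ns))
    p <- stats::anova(stats::lm(v ~ g))[1, "Pr(>F)"]
    if (p < alpha) hits <- hits + 1L
  }
  hits / B
}

mc_power_chi2 <- function(tab, B = 2000, alpha = 0.05, seed = 1L) {
  probs <- tab / sum(tab)
  n <- sum(tab)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    sim <- matrix(stats::rmultinom(1, n, as.vector(probs)), nrow = nrow(tab))
    p <- suppressWarnings(stats::chisq.test(
      sim, correct = all(dim(sim) == 2)))$p.value
    if (!is.na(p) && p < alpha) hits <- hits + 1L
  }
  hits / B
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

assoc_result <- function(feature, test, statistic, p, es, power, groups) {
  out <- list(feature = feature, test = test, statistic = statistic,
              p_value = p, effect_size = es, power = power, groups = groups)
  class(out) <- "lf_assoc_result"
  out
}

#' Two-group Mann-Whitney association
#'
#' Two-sided Mann-Whitney U test: exact p by complete enumeration of label
#' assignments when n1 + n2 <= 12, tie-corrected normal approximation with
#' continuity correction otherwise.  Effect size is pooled-sd Cohen's d with
#' the group1 - group2 sign convention (pass the symptomatic group second so
#' elevated markers give negative d).  Power is post-hoc Monte-Carlo at the
#' observed |d| and group sizes.
#'
#' @param values Numeric vector.
#' @param labels Two-level factor/vector aligned with `values`; the first
#'   level is group 1.
#' @param feature Feature name carried into the result.
#' @param B Monte-Carlo replicates for power (default 2000).
#' @param power_seed Seed for the power simulation.
#' @param exact_max Largest n1+n2 for exact enumeration (default 12).
#' @return `lf_assoc_result`: feature, test, statistic (U), p_value,
#'   effect_size, power, group summaries.
#' @export
mann_whitney_assoc <- function(values, labels, feature = "value", B = 2000,
                               power_seed = 1L, exact_max = 12L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2L) stop("mann_whitney_assoc needs exactly 2 groups")
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations")
  p <- if (length(x) + length(y) <= exact_max) u_exact_p(x, y) else u_normal_p(x, y)
  d <- cohens_d(x, y)
  pow <- mc_power_u(d, length(x), length(y), B = B, seed = power_seed)
  groups <- data.frame(group = levels(labels), n = c(length(x), length(y)),
                       mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)))
  assoc_result(feature, "mann_whitney", u_statistic(x, y), p, d, pow, groups)
}

#' Three-or-more-group one-way ANOVA association
#'
#' One-way analysis of variance F test with eta-squared effect size
#' (between-group sum of squares over total) and post-hoc Monte-Carlo power
#' at the observed eta-squared and group sizes.  With zero variance
#' everywhere the result is degenerate: p = 1 when all group means are
#' equal, p = 0 (flagged) otherwise.
#'
#' @inheritParams mann_whitney_assoc
#' @param labels Factor with >= 3 levels (>= 2 observations per level).
#' @return `lf_assoc_result` with test `"anova"`.
#' @export
anova_assoc <- function(values, labels, feature = "value", B = 2000,
                        power_seed = 1L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 3L)
    stop("anova_assoc needs at least 3 groups (use mann_whitney_assoc for 2)")
  ns <- table(labels)
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  groups <- data.frame(group = levels(labels), n = as.integer(ns),
                       mean = tapply(values, labels, mean),
                       sd = tapply(values, labels, stats::sd))
  if (all(groups$sd == 0 | is.na(groups$sd))) {
    equal <- length(unique(groups$mean)) == 1L
    res <- assoc_result(feature, "anova", if (equal) 0 else Inf,
                        if (equal) 1 else 0, if (equal) 0 else 1,
                        if (equal) 0 else 1, groups)
    res$degenerate <- TRUE
    return(res)
  }
  fit <- stats::anova(stats::lm(values ~ labels))
  Fstat <- fit[1, "F value"]; p <- fit[1, "Pr(>F)"]
  eta2 <- fit[1, "Sum Sq"] / sum(fit[, "Sum Sq"])
  pow <- mc_power_anova(eta2, as.integer(ns), B = B, seed = power_seed)
  assoc_result(feature, "anova", Fstat, p, eta2, pow, groups)
}

#' Chi-squared contingency association
#'
#' Pearson chi-squared test of independence with Yates continuity correction
#' for 2x2 tables (only), Cramer's V effect size, and Monte-Carlo power
#' simulated from the observed cell proportions.
#'
#' @param table Contingency matrix of nonnegative integer counts (>= 2x2).
#' @inheritParams mann_whitney_assoc
#' @return `lf_assoc_result` with test `"chi2"`.
#' @export
chi2_assoc <- function(table, feature = "value", B = 2000, power_seed = 1L) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = all(dim(tab) == 2)))
  n <- sum(tab)
  v <- sqrt(as.numeric(ct$statistic) / (n * (min(dim(tab)) - 1)))
  # with continuity correction the statistic can be 0 on independent tables
  pow <- mc_power_chi2(tab, B = B, seed = power_seed)
  groups <- data.frame(group = colnames(tab) %||% paste0("g", seq_len(ncol(tab))),
                       n = colSums(tab))
  assoc_result(feature, "chi2", as.numeric(ct$statistic), ct$p.value, v, pow,
               groups)
}

#' Feature-by-feature association screen
#'
#' Runs the appropriate test per feature column against the label: the
#' Mann-Whitney U test for two groups, one-way ANOVA for three.  Results are
#' ordered by registry group then p-value, with a significance flag at
#' `alpha` (raw p-values by default; Benjamini-Hochberg adjustment by
#' option).
#'
#' @param features Feature table (`lf_features` or data.frame with doc_id).
#' @param labels Named vector or factor aligned to `features$doc_id` (names
#'   used for alignment when present).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default, raw p-values) or `"BH"`.
#' @param B Monte-Carlo replicates for power per feature.
#' @param power_seed Base seed for power simulations.
#' @param registry Registry for group ordering.
#' @return data.frame of class `lf_assoc`: feature, group, test, statistic,
#'   p_value, effect_size, power, significant.
#' @export
association_table <- function(features, labels, alpha = 0.05,
                              adjust = c("none", "BH"), B = 2000,
                              power_seed = 1L, registry = lf_registry()) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(features), "doc_id" %in% names(features))
  if (!is.null(names(labels))) {
    if (!all(features$doc_id %in% names(labels)))
      stop("labels are missing for some doc_ids")
    labels <- labels[features$doc_id]
  } else if (length(labels) != nrow(features)) {
    stop("labels length does not match feature table")
  }
  labels <- droplevels(factor(labels))
  feat_cols <- setdiff(names(features), "doc_id")
  if (!length(feat_cols))
    return(structure(data.frame(feature = character(), group = character(),
                                test = character(), statistic = numeric(),
                                p_value = numeric(), effect_size = numeric(),
                                power = numeric(), significant = logical()),
                     class = c("lf_assoc", "data.frame")))
  two <- nlevels(labels) == 2L
  rows <- lapply(seq_along(feat_cols), function(k) {
    f <- feat_cols[k]
    r <- if (two)
      mann_whitney_assoc(features[[f]], labels, feature = f, B = B,
                         power_seed = power_seed + k)
    else
      anova_assoc(features[[f]], labels, feature = f, B = B,
                  power_seed = power_seed + k)
    grp <- registry$group[match(f, registry$name)]
    data.frame(feature = f, group = if (is.na(grp)) "other" else grp,
               test = r$test, statistic = r$statistic, p_value = r$p_value,
               effect_size = r$effect_size, power = r$power,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_used <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_used < alpha
  grp_order <- c(unique(registry$group), "other")
  out <- out[order(match(out$group, grp_order), out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lf_assoc", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' @export
print.lf_assoc <- function(x, ...) {
  needed <- c("feature", "group", "p_value", "effect_size", "power",
              "significant")
  if (!all(needed %in% names(x))) {   # column-subset view: plain print
    print(as.data.frame(x), ...)
    return(invisible(x))
  }
  cat("<lf_assoc> ", nrow(x), " features screened, ",
      sum(x$significant), " significant at alpha = ",
      attr(x, "alpha") %||% 0.05, "\n", sep = "")
  sig <- x[x$significant, c("feature", "group", "p_value", "effect_size", "power")]
  if (nrow(sig)) print(format(sig, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
print.lf_assoc_result <- function(x, ...) {
  cat("<", x$test, "> ", x$feature, ": p = ", signif(x$p_value, 3),
      ", effect size = ", signif(x$effect_size, 3),
      ", power = ", signif(x$power, 3), "\n", sep = "")
  invisible(x)
}
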