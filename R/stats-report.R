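# Group-comparison reporting: Shapiro-Wilk normality screening, one-way
# ANOVA gated Fisher's LSD with compact letter display, two-sample t-tests
# with asterisk coding, least-squares correlation, and the division-rate
# computation from cell densities.

#' Per-group Shapiro-Wilk normality check
#'
#' Groups with fewer than 3 observations are skipped with a note; a
#' constant sample raises an error (the statistic is undefined).
#'
#' @param values numeric vector
#' @param groups grouping vector of the same length
#' @return data.frame: group, n, W, p
#' @export
normality_check <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups, levels = unique(groups))
  out <- lapply(levels(g), function(lv) {
    x <- values[g == lv]
    if (length(x) < 3) {
      message("group '", lv, "' skipped: fewer than 3 observations")
      return(data.frame(group = lv, n = length(x), W = NA_real_,
                        p = NA_real_))
    }
    sw <- shapiro.test(x)
    data.frame(group = lv, n = length(x), W = unname(sw$statistic),
               p = sw$p.value)
  })
  do.call(rbind, out)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Letters are the maximal cliques of the non-significance graph (two
#' levels share a letter iff their pairwise p >= alpha), ordered so that
#' 'a' contains the highest mean.
#'
#' @param pmat symmetric matrix of pairwise p-values (dimnames = levels)
#' @param means named vector of group means
#' @param alpha significance level
#' @return named character vector of letter codes
#' @export
compact_letter_display <- function(pmat, means, alpha = 0.05) {
  lv <- rownames(pmat)
  stopifnot(!is.null(lv), all(lv %in% names(means)))
  adj <- (pmat >= alpha)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(x) lv[as.integer(x)])
  top <- vapply(cl, function(x) max(means[x]), 0)
  cl <- cl[order(-top)]
  codes <- setNames(rep("", length(lv)), lv)
  for (i in seq_along(cl)) {
    codes[cl[[i]]] <- paste0(codes[cl[[i]]], letters[i])
  }
  codes
}

#' One-way ANOVA with Fisher's LSD post-hoc and letter display
#'
#' Fits a one-way ANOVA; if the global test is significant at `alpha` (or
#' `gate = FALSE`), all pairwise Fisher LSD tests are computed using the
#' pooled within-group variance, and a compact letter display is assigned
#' ('a' = highest mean; levels sharing a letter are not significantly
#' different).
#'
#' @param values numeric response
#' @param groups grouping vector; level order follows first appearance
#' @param alpha significance level
#' @param gate require a significant global ANOVA before pairwise testing
#' @return list of class `anova_lsd`: `table` (level, n, mean, sd,
#'   letters), `F`, `p_anova`, `pairwise_p`, `mse`, `df_residual`, `alpha`
#' @export
anova_lsd <- function(values, groups, alpha = 0.05, gate = TRUE) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups, levels = unique(groups))
  cnt <- table(g)
  if (nlevels(g) < 2 || any(cnt < 2)) {
    stop("need at least 2 groups with at least 2 observations each")
  }
  fit <- aov(values ~ g)
  an <- summary(fit)[[1]]
  Fval <- an$`F value`[1]
  p_anova <- an$`Pr(>F)`[1]
  df_res <- an$Df[2]
  mse <- an$`Mean Sq`[2]
  if (!is.finite(mse) || mse <= 1e-12 * max(var(values), .Machine$double.eps)) {
    stop("zero within-group variance everywhere: LSD undefined")
  }
  lv <- levels(g)
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, sd)
  n <- as.numeric(cnt)
  pmat <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (i == j) {
        pmat[i, j] <- 1
        next
      }
      tstat <- (means[i] - means[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
      pmat[i, j] <- 2 * pt(-abs(tstat), df_res)
    }
  }
  if (gate && p_anova >= alpha) {
    letters_vec <- setNames(rep("a", nlevels(g)), lv)
  } else {
    letters_vec <- compact_letter_display(pmat, means, alpha)
  }
  structure(list(
    table = data.frame(level = lv, n = n, mean = as.numeric(means),
                       sd = as.numeric(sds),
                       letters = unname(letters_vec[lv])),
    F = Fval, p_anova = p_anova, pairwise_p = pmat, mse = mse,
    df_residual = df_res, alpha = alpha), class = "anova_lsd")
}

#' Asterisk code for a p-value
#'
#' `*` for 0.01 < p < 0.05, `**` for 0.001 < p < 0.01, `***` for
#' p < 0.001, `ns` otherwise. Values exactly on a band boundary map to the
#' weaker band (the published bands are open intervals).
#'
#' @param p p-value(s) in (0, 1]
#' @return character vector in {"ns", "*", "**", "***"}
#' @export
asterisk_code <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}

#' Two-sample t-test with asterisk coding
#'
#' @param x,y numeric samples (n >= 2 each)
#' @param var_equal pooled-variance t-test if TRUE (default), Welch
#'   otherwise
#' @return list of class `pair_test`: `t`, `p`, `code`, `var_equal`
#' @export
pair_test <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) + var(y) == 0) stop("zero combined variance")
  tt <- t.test(x, y, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 code = asterisk_code(tt$p.value), var_equal = var_equal),
            class = "pair_test")
}

#' Least-squares linear correlation
#'
#' @param x,y numeric vectors (n >= 3; x must vary)
#' @return list: `slope`, `intercept`, `r_squared`
#' @export
linear_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2)
}

#' Division rate from two cell densities
#'
#' `log2(density_t2 / density_t1) / dt_days`: doublings per day.
#'
#' @param density_t1,density_t2 cell densities (> 0)
#' @param dt_days elapsed time, days (> 0)
#' @return divisions per day; vectorised
#' @export
division_rate <- function(density_t1, density_t2, dt_days) {
  if (any(density_t1 <= 0) || any(density_t2 <= 0) || any(dt_days <= 0)) {
    stop("densities and time interval must be positive")
  }
  log2(density_t2 / density_t1) / dt_days
}
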