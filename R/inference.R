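## Heteroscedastic one-way models, Tukey-Kramer pairwise comparisons,
## trait-effect regressions and the unequal-variance t-test.
##
## The one-way fit allows a distinct residual variance per group
## (varIdent-type structure). Under a saturated one-way mean structure
## the REML variance estimates are available in closed form: the
## per-group sample variances with n_g - 1 denominators. The group
## effect is tested by a Wald F with containment denominator df
## (N_total - K).

#' Heteroscedastic one-way linear model
#'
#' Fits group means with either a common residual variance
#' (`equal_var = TRUE`, the textbook one-way ANOVA) or a separate
#' residual variance per group, estimated by restricted maximum
#' likelihood. The group effect is tested by a Wald F statistic
#' \eqn{F = \sum_g w_g (\bar y_g - \hat\mu_w)^2 / (K-1)} with
#' \eqn{w_g = n_g/\hat\sigma_g^2} and \eqn{\hat\mu_w} the
#' variance-weighted grand mean, on (K-1, N-K) degrees of freedom. With
#' `equal_var = TRUE` this reduces exactly to the classical ANOVA F; with
#' two groups and unequal variances it equals the squared Welch t
#' statistic.
#'
#' @param formula `response ~ group`.
#' @param data data.frame holding the variables.
#' @param equal_var Constrain a single residual variance (default FALSE).
#' @return Object of class `hetero_oneway`: group `means`, `variances`
#'   (REML), `n`, `F`, `df1`, `df2`, `p.value`, `logLik` (restricted).
#' @export
#' @examples
#' d <- data.frame(y = c(0, 1, 2, 10, 11, 12), g = rep(c("a", "b"), each = 3))
#' hetero_oneway(y ~ g, d, equal_var = TRUE)  # F = 150
hetero_oneway <- function(formula, data, equal_var = FALSE) {
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L) stop("formula must be of the form response ~ group")
  y <- mf[[1]]
  g <- droplevels(as.factor(mf[[2]]))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  n <- c(tapply(y, g, length))
  if (any(n < 2L)) {
    stop("data error: group(s) with fewer than 2 observations: ",
         paste(names(n)[n < 2L], collapse = ", "))
  }
  K <- nlevels(g)
  N <- length(y)
  means <- c(tapply(y, g, mean))
  ss <- c(tapply(y, g, function(v) sum((v - mean(v))^2)))
  if (equal_var) {
    s2 <- rep(sum(ss) / (N - K), K)  # pooled REML estimate
    names(s2) <- levels(g)
  } else {
    s2 <- ss / (n - 1)               # per-group REML estimates
  }

  w <- n / s2
  num <- if (all(is.finite(w))) {
    mu_w <- sum(w * means) / sum(w)
    sum(w * (means - mu_w)^2)
  } else NA_real_
  ssb <- sum(n * (means - mean(y))^2)
  Fstat <- if (ssb == 0) 0 else {
    if (!is.finite(num)) {
      stop("numerical error: zero within-group variance with unequal means")
    }
    num / (K - 1)
  }
  df1 <- K - 1
  df2 <- N - K   # containment df
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  logLik <- if (all(s2 > 0)) {
    -0.5 * ((N - K) * log(2 * pi) + sum(n * log(s2)) +
              sum(log(n / s2)) + sum(ss / s2))
  } else NA_real_

  structure(list(call = match.call(),
                 response = names(mf)[1], group = names(mf)[2],
                 levels = levels(g), n = n, means = means,
                 variances = s2, equal_var = equal_var,
                 F = Fstat, df1 = df1, df2 = df2, p.value = p,
                 logLik = logLik,
                 fitted = unname(means[g]),
                 residuals = y - unname(means[g])),
            class = "hetero_oneway")
}

#' @export
print.hetero_oneway <- function(x, digits = 4, ...) {
  cat(sprintf("Heteroscedastic one-way model: %s ~ %s (%s)\n",
              x$response, x$group,
              if (x$equal_var) "single variance"
              else "variance per group, REML"))
  cat(sprintf("  F = %.*g on (%d, %d) df, p = %.4g\n",
              digits, x$F, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' @export
summary.hetero_oneway <- function(object, ...) {
  tab <- data.frame(group = object$levels,
                    n = as.integer(object$n),
                    mean = as.numeric(object$means),
                    variance = as.numeric(object$variances),
                    sd = sqrt(as.numeric(object$variances)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(groups = tab, F = object$F, df1 = object$df1,
              df2 = object$df2, p.value = object$p.value,
              logLik = object$logLik, equal_var = object$equal_var,
              call = object$call)
  class(out) <- "summary.hetero_oneway"
  out
}

#' @export
print.summary.hetero_oneway <- function(x, digits = 4, ...) {
  cat("Heteroscedastic one-way model",
      if (x$equal_var) "(single variance)" else "(variance per group, REML)",
      "\n\n")
  print(x$groups, digits = digits)
  cat(sprintf("\nWald F = %.*g on (%d, %d) df, p = %.4g\n",
              digits, x$F, x$df1, x$df2, x$p.value))
  if (is.finite(x$logLik)) {
    cat(sprintf("Restricted log-likelihood: %.*g\n", digits, x$logLik))
  }
  invisible(x)
}

#' @export
coef.hetero_oneway <- function(object, ...) object$means

#' @export
fitted.hetero_oneway <- function(object, ...) object$fitted

#' @export
residuals.hetero_oneway <- function(object, ...) object$residuals

#' @export
logLik.hetero_oneway <- function(object, ...) {
  structure(object$logLik, df = length(object$levels) +
              if (object$equal_var) 1L else length(object$levels),
            class = "logLik")
}

#' Tukey-Kramer pairwise comparisons for a heteroscedastic fit
#'
#' All pairwise group contrasts with standard errors built from the
#' group-specific variances, per-pair Welch-Satterthwaite degrees of
#' freedom, and familywise adjustment by the Tukey-Kramer studentized
#' range. A compact letter display is attached: groups sharing no letter
#' differ significantly at level `alpha`.
#'
#' @param fit A [hetero_oneway()] fit.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Object of class `tukey_pairwise`: `$comparisons` (pair,
#'   estimate, se, df, t, p.raw, p.adj) and `$letters` (named by group).
#' @export
tukey_pairwise <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "hetero_oneway"))
  K <- length(fit$levels)
  if (K < 2L) stop("domain error: need at least 2 groups")
  v <- fit$variances / fit$n   # variances of group means
  pairs <- utils::combn(K, 2)
  comp <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    est <- fit$means[i] - fit$means[j]
    se2 <- v[i] + v[j]
    if (se2 == 0) {
      # both groups constant: no evidence of a difference unless means differ
      tstat <- if (est == 0) 0 else Inf
      df <- fit$n[i] + fit$n[j] - 2
    } else {
      tstat <- est / sqrt(se2)
      df <- se2^2 / (v[i]^2 / (fit$n[i] - 1) + v[j]^2 / (fit$n[j] - 1))
    }
    p_raw <- 2 * stats::pt(-abs(tstat), df)
    ## the studentized-range distribution is undefined below 2 df
    ## (possible with 2 observations per group); fall back to the more
    ## conservative Bonferroni adjustment there
    p_adj <- if (df >= 2) {
      stats::ptukey(sqrt(2) * abs(tstat), K, df, lower.tail = FALSE)
    } else {
      p_raw * K * (K - 1) / 2
    }
    data.frame(pair = paste(fit$levels[i], fit$levels[j], sep = " - "),
               group1 = fit$levels[i], group2 = fit$levels[j],
               estimate = unname(est), se = sqrt(se2), df = unname(df),
               t = unname(tstat), p.raw = unname(p_raw),
               p.adj = unname(min(1, p_adj)),
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  rownames(comp) <- NULL

  letters <- compact_letters(fit$levels, as.numeric(fit$means),
                             comp$group1, comp$group2,
                             comp$p.adj < alpha)
  structure(list(comparisons = comp, letters = letters, alpha = alpha,
                 means = fit$means),
            class = "tukey_pairwise")
}

#' @export
print.tukey_pairwise <- function(x, digits = 4, ...) {
  cat(sprintf("Tukey-Kramer pairwise comparisons (alpha = %g)\n", x$alpha))
  print(x$comparisons[, c("pair", "estimate", "se", "df", "t", "p.adj")],
        digits = digits)
  cat("\nLetters:", paste(names(x$letters), x$letters, sep = ": ",
                          collapse = "  "), "\n")
  invisible(x)
}

## Compact letter display: letters are the maximal cliques of the
## non-significance graph, ordered by the smallest group mean they
## contain; ties broken by label order. Exact for K small enough to
## enumerate (always the case for experimental treatment sets).
compact_letters <- function(groups, means, g1, g2, significant) {
  K <- length(groups)
  adj <- matrix(TRUE, K, K, dimnames = list(groups, groups))
  for (k in seq_along(g1)) {
    if (significant[k]) {
      adj[g1[k], g2[k]] <- adj[g2[k], g1[k]] <- FALSE
    }
  }
  diag(adj) <- TRUE
  if (K > 20L) stop("compact letter display supports at most 20 groups")
  ## enumerate maximal cliques by bitmask
  cliques <- list()
  for (mask in seq_len(2^K - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    if (all(adj[members, members])) {
      extendable <- any(vapply(setdiff(seq_len(K), members), function(m) {
        all(adj[m, members])
      }, logical(1)))
      if (!extendable) cliques[[length(cliques) + 1]] <- members
    }
  }
  ord <- order(vapply(cliques, function(m) min(means[m]), numeric(1)),
               vapply(cliques, function(m) min(m), numeric(1)))
  cliques <- cliques[ord]
  out <- stats::setNames(rep("", K), groups)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}

#' Regress a diversity effect on a mixture trait
#'
#' Ordinary least-squares regression of a per-mixture diversity effect
#' (net, complementarity or selection effect, or the FPOM net effect) on
#' a mixture-level predictor (a weighted trait mean or the trait
#' variability). By default both sides are log-transformed to meet the
#' linear-model assumptions; if any effect is non-positive (possible for
#' selection effects) the response is left untransformed with a warning.
#'
#' @param effects Numeric vector of per-replicate diversity effects.
#' @param predictor Numeric vector of the same length (> 0 when a log
#'   transform is requested).
#' @param log_transform Log-transform response and predictor (default
#'   TRUE).
#' @return Object of class `trait_regression`: `slope`, `intercept`,
#'   `F`, `p.value`, `r.squared`, the transformations applied, and the
#'   underlying `lm` fit.
#' @export
regress_effect_on_trait <- function(effects, predictor,
                                    log_transform = TRUE) {
  stopifnot(length(effects) == length(predictor))
  ok <- stats::complete.cases(effects, predictor)
  effects <- effects[ok]; predictor <- predictor[ok]
  if (length(effects) < 3L) stop("need at least 3 mixtures/replicates")
  transform_response <- transform_predictor <- FALSE
  if (log_transform) {
    bad <- which(predictor <= 0)
    if (length(bad)) {
      stop("transformation error: non-positive predictor value(s) at row(s) ",
           paste(bad, collapse = ", "))
    }
    predictor <- log(predictor)
    transform_predictor <- TRUE
    if (all(effects > 0)) {
      effects <- log(effects)
      transform_response <- TRUE
    } else {
      warning("non-positive effect values; response left untransformed")
    }
  }
  fit <- stats::lm(effects ~ predictor)
  an <- stats::anova(fit)
  informative <- stats::var(predictor) > 0 && stats::var(effects) > 0
  Fstat <- if (informative) an[1, "F value"] else 0
  p <- if (informative) an[1, "Pr(>F)"] else 1
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 F = unname(Fstat), p.value = unname(p),
                 r.squared = if (informative) summary(fit)$r.squared else 0,
                 n = length(effects),
                 transform_response = transform_response,
                 transform_predictor = transform_predictor,
                 model = fit),
            class = "trait_regression")
}

#' @export
print.trait_regression <- function(x, digits = 4, ...) {
  tr <- c(if (x$transform_response) "log(response)" else "response",
          if (x$transform_predictor) "log(predictor)" else "predictor")
  cat(sprintf("Trait-effect regression: %s ~ %s (n = %d)\n",
              tr[1], tr[2], x$n))
  cat(sprintf("  slope = %.*g, F = %.*g, p = %.4g, R^2 = %.*g\n",
              digits, x$slope, digits, x$F, x$p.value, digits, x$r.squared))
  invisible(x)
}

#' Unequal-variance (Welch) t-test from summary statistics
#'
#' Two-sample t-test on means and standard errors, with
#' Welch-Satterthwaite degrees of freedom. Useful for comparing a
#' measured group against published summary values.
#'
#' @param mean1,mean2 Group means.
#' @param se1,se2 Standard errors of the means (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return List with `t`, `df`, `p.value`.
#' @export
#' @examples
#' welch_t(1.58, 0.05, 5, 1.62, 0.13, 5)
welch_t <- function(mean1, se1, n1, mean2, se2, n2) {
  if (se1 <= 0 || se2 <= 0) stop("degenerate error: standard errors must be > 0")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group")
  t <- (mean1 - mean2) / sqrt(se1^2 + se2^2)
  df <- (se1^2 + se2^2)^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df))
}

#' Diversity-loss test within a mixture nest
#'
#' The analysis applied to each "nest" of the experimental design: the
#' top mixture (e.g. the 4-species mixture, or one 3-species mixture)
#' together with all its sub-compositions, grouped by richness level.
#' Fits [hetero_oneway()] of the response on richness and runs
#' [tukey_pairwise()].
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @param nest Composition string of the top mixture (e.g. "ACQI").
#' @param response Metrics column, e.g. `"norm_total_loss"`,
#'   `"fpom_norm"`, `"growth_pct"`.
#' @param detritivores Which arm to analyse.
#' @param equal_var Passed to [hetero_oneway()]; default FALSE
#'   (variance per richness level).
#' @param alpha Significance level for letters.
#' @return List with the `fit`, the `pairwise` comparisons and the
#'   analysed subset.
#' @export
diversity_loss_test <- function(metrics, nest, response = "norm_total_loss",
                                detritivores = TRUE, equal_var = FALSE,
                                alpha = 0.05) {
  nest_sp <- parse_composition(nest)
  rows <- metrics$detritivores_present == detritivores &
    vapply(metrics$composition,
           function(x) all(parse_composition(x) %in% nest_sp), logical(1))
  d <- metrics[rows, , drop = FALSE]
  if (nrow(d) == 0L) stop("no microcosms within nest ", nest)
  d$richness_level <- factor(d$richness)
  fit <- hetero_oneway(stats::reformulate("richness_level", response), d,
                       equal_var = equal_var)
  list(nest = nest, response = response, detritivores = detritivores,
       fit = fit, pairwise = tukey_pairwise(fit, alpha), data = d)
}
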