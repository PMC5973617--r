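## Additive partitioning of net diversity effects on decomposition into
## complementarity and selection effects (Loreau-Hector partition).
##
## For a mixture of N species with seeded proportions p_i, per-species
## observed responses Y_O,i and monoculture means M_i:
##   RY_E,i = p_i                (expected relative yield)
##   RY_O,i = Y_O,i / M_i        (observed relative yield)
##   dRY_i  = RY_O,i - p_i
##   net = sum(Y_O) - sum(p_i * M_i)
##   CE  = N * mean(dRY) * mean(M)           (complementarity effect)
##   SE  = N * cov_pop(dRY, M)               (selection effect)
## with cov_pop the population covariance (divide by N), which is exactly
## what makes net = CE + SE an identity.

#' Monoculture mean responses
#'
#' Mean response across monoculture replicates, per species, used as the
#' baseline M_i of the additive partition.
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @param response Column of `metrics` holding the response (default the
#'   detritivore-normalised total mass loss).
#' @param detritivores Use the detritivore-present arm (`TRUE`, default)
#'   or the detritivore-free arm (`FALSE`).
#' @param species Restrict to these species (default: all with
#'   monocultures).
#' @return data.frame with `species`, `M`, `n`, `sd`, of class
#'   `monoculture_summary`.
#' @export
monoculture_summary <- function(metrics, response = "norm_total_loss",
                                detritivores = TRUE, species = NULL) {
  if (!response %in% names(metrics)) {
    stop("unknown response column '", response, "'")
  }
  mono <- metrics[metrics$richness == 1L &
                    metrics$detritivores_present == detritivores, ,
                  drop = FALSE]
  mono$species <- vapply(mono$composition, function(x) parse_composition(x)[1],
                         character(1))
  if (!is.null(species)) {
    absent <- setdiff(species, mono$species)
    if (length(absent)) {
      stop("data error: no monoculture replicates for species ",
           paste(absent, collapse = ", "))
    }
    mono <- mono[mono$species %in% species, , drop = FALSE]
  }
  if (nrow(mono) == 0L) stop("data error: no monoculture replicates found")
  sp <- split(mono[[response]], mono$species)
  out <- data.frame(
    species = names(sp),
    M  = vapply(sp, mean, numeric(1)),
    n  = vapply(sp, length, integer(1)),
    sd = vapply(sp, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, response = response,
            class = unique(c("monoculture_summary", class(out))))
}

#' Additive partition of a diversity effect
#'
#' Partitions the net diversity effect of one mixture replicate into
#' complementarity (CE) and selection (SE) effects. The net effect is the
#' observed mixture response minus the expectation assembled from
#' monoculture means; CE is N times the mean relative-yield deviation
#' times the mean monoculture response; SE is N times the population
#' covariance between relative-yield deviations and monoculture
#' responses, so that net = CE + SE exactly.
#'
#' @param observed Named numeric vector of per-species observed responses
#'   Y_O,i in the mixture (names = species codes).
#' @param M Named numeric vector (or [monoculture_summary()]) of
#'   monoculture means; must cover all mixture species and be positive.
#' @param proportions Seeded proportions p_i; default equal (1/N).
#' @return Object of class `lh_partition` with elements `species` (a
#'   per-species table of Y_O, Y_E, RY_O, RY_E and dRY), `N`, `net`,
#'   `CE`, `SE`.
#' @export
#' @examples
#' # pure selection: the high-performing species overyields
#' additive_partition(c(A = 8, B = 0.4), M = c(A = 10, B = 2))
additive_partition <- function(observed, M, proportions = NULL) {
  if (inherits(M, "monoculture_summary")) {
    M <- stats::setNames(M$M, M$species)
  }
  sp <- names(observed)
  if (is.null(sp) || any(!nzchar(sp))) {
    stop("observed responses must be named by species code")
  }
  missing <- setdiff(sp, names(M))
  if (length(missing)) {
    stop("data error: no monoculture mean for species ",
         paste(missing, collapse = ", "))
  }
  M <- M[sp]
  if (any(!is.finite(M)) || any(M <= 0)) {
    stop("domain error: monoculture means must be positive ",
         "(relative yield undefined otherwise)")
  }
  N <- length(sp)
  p <- proportions %||% rep(1 / N, N)
  if (length(p) != N) stop("proportions must match the number of species")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")

  Y_E <- p * M
  RY_O <- observed / M
  dRY <- RY_O - p
  net <- sum(observed) - sum(Y_E)
  CE <- N * mean(dRY) * mean(M)
  SE <- N * (mean(dRY * M) - mean(dRY) * mean(M))  # population covariance

  structure(list(
    species = data.frame(species = sp, p = p, M = unname(M),
                         Y_O = unname(observed), Y_E = unname(Y_E),
                         RY_O = unname(RY_O), RY_E = p, dRY = unname(dRY),
                         row.names = NULL, stringsAsFactors = FALSE),
    N = N, net = net, CE = CE, SE = SE
  ), class = "lh_partition")
}

#' @export
print.lh_partition <- function(x, digits = 4, ...) {
  cat(sprintf("Additive partition (%d species)\n", x$N))
  cat(sprintf("  net = %.*g  (CE = %.*g, SE = %.*g)\n",
              digits, x$net, digits, x$CE, digits, x$SE))
  print(x$species, digits = digits)
  invisible(x)
}

#' Complementarity/selection contribution percentages
#'
#' Shares of the mixture-level mean complementarity and selection effects
#' in the net diversity effect, on the absolute-value convention
#' `CE_pct = 100 |CE| / (|CE| + |SE|)` (the convention that remains
#' meaningful when one component is negative).
#'
#' @param CE,SE Mixture-level mean complementarity and selection effects
#'   (or an `lh_partition` object as first argument).
#' @return Named vector `c(CE_pct, SE_pct)`; both NA (with a warning)
#'   when CE = SE = 0.
#' @export
contribution_pct <- function(CE, SE = NULL) {
  if (inherits(CE, "lh_partition")) {
    SE <- CE$SE
    CE <- CE$CE
  }
  if (abs(CE) + abs(SE) == 0) {
    warning("CE and SE are both zero; contributions undefined")
    return(c(CE_pct = NA_real_, SE_pct = NA_real_))
  }
  ce <- 100 * abs(CE) / (abs(CE) + abs(SE))
  c(CE_pct = ce, SE_pct = 100 - ce)
}

#' Net diversity effect on FPOM production
#'
#' Observed mixture FPOM minus the expectation assembled from monoculture
#' FPOM means. No CE/SE split is possible because the FPOM of a mixture
#' cannot be attributed to individual species.
#'
#' @param observed_total Observed mixture FPOM response (one replicate).
#' @param M Named monoculture FPOM means (or [monoculture_summary()]).
#' @param species Mixture species codes (defaults to `names(M)` when `M`
#'   is a plain named vector covering exactly the mixture).
#' @param proportions Seeded proportions; default equal.
#' @return Net effect (same units as the response).
#' @export
net_effect_fpom <- function(observed_total, M, species = NULL,
                            proportions = NULL) {
  if (inherits(M, "monoculture_summary")) {
    M <- stats::setNames(M$M, M$species)
  }
  species <- species %||% names(M)
  missing <- setdiff(species, names(M))
  if (length(missing)) {
    stop("data error: no monoculture FPOM mean for species ",
         paste(missing, collapse = ", "))
  }
  N <- length(species)
  p <- proportions %||% rep(1 / N, N)
  observed_total - sum(p * M[species])
}

#' Partition every mixture replicate of an experiment
#'
#' Applies [additive_partition()] to each mixture microcosm (richness
#' >= 2) against monoculture means of the chosen arm, and the FPOM net
#' effect alongside, then aggregates replicates into mixture means and
#' standard errors with contribution percentages.
#'
#' @param metrics Metrics table from [compute_metrics()].
#' @param response Per-species response prefix: `"norm_loss"` (default,
#'   mg per mg detritivore; falls back to `"loss"` automatically for the
#'   detritivore-free arm) or `"loss"` (mg).
#' @param detritivores Analyse the detritivore-present arm (default) or
#'   the detritivore-free arm.
#' @param fpom Also compute the FPOM net effect (default TRUE).
#' @param proportions Optional named list of per-mixture proportions;
#'   default equal within each mixture (equal seeded disc numbers).
#' @param mixtures Optional character vector restricting the analysis to
#'   these compositions (default: every mixture present).
#' @return Object of class `lh_partition_set` with `$replicates` (one row
#'   per mixture microcosm: net, CE, SE, fpom_net) and `$summary` (one
#'   row per mixture: means, standard errors, CE_pct/SE_pct).
#' @export
partition_experiment <- function(metrics, response = NULL,
                                 detritivores = TRUE, fpom = TRUE,
                                 proportions = NULL, mixtures = NULL) {
  response <- response %||% if (detritivores) "norm_loss" else "loss"
  total_col <- if (response == "norm_loss") "norm_total_loss" else "total_loss"
  fpom_col <- if (detritivores) "fpom_norm" else "fpom_total"

  mix <- metrics[metrics$richness >= 2L &
                   metrics$detritivores_present == detritivores, ,
                 drop = FALSE]
  if (!is.null(mixtures)) {
    absent <- setdiff(mixtures, mix$composition)
    if (length(absent)) {
      stop("data error: no microcosms for mixture(s) ",
           paste(absent, collapse = ", "))
    }
    mix <- mix[mix$composition %in% mixtures, , drop = FALSE]
  }
  if (nrow(mix) == 0L) stop("data error: no mixture microcosms in this arm")
  species_needed <- unique(unlist(lapply(mix$composition, parse_composition)))
  mono <- monoculture_summary(metrics, total_col, detritivores,
                              species = species_needed)
  Mvec <- stats::setNames(mono$M, mono$species)
  mono_fpom <- if (fpom) {
    mf <- monoculture_summary(metrics, fpom_col, detritivores,
                              species = species_needed)
    stats::setNames(mf$M, mf$species)
  }

  reps <- do.call(rbind, lapply(seq_len(nrow(mix)), function(i) {
    sp <- parse_composition(mix$composition[i])
    obs <- stats::setNames(
      as.numeric(mix[i, per_species_col(response, sp)]), sp)
    p <- proportions[[mix$composition[i]]] %||% rep(1 / length(sp), length(sp))
    part <- additive_partition(obs, Mvec, p)
    data.frame(mixture = mix$composition[i],
               microcosm_id = mix$microcosm_id[i],
               richness = part$N, net = part$net, CE = part$CE, SE = part$SE,
               fpom_net = if (fpom)
                 net_effect_fpom(mix[[fpom_col]][i], mono_fpom, sp, p)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL

  se <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- lapply(split(reps, reps$mixture), function(d) {
    ct <- contribution_pct(mean(d$CE), mean(d$SE))
    data.frame(mixture = d$mixture[1], richness = d$richness[1],
               n = nrow(d),
               net_mean = mean(d$net), net_se = se(d$net),
               CE_mean = mean(d$CE), CE_se = se(d$CE),
               SE_mean = mean(d$SE), SE_se = se(d$SE),
               CE_pct = unname(ct["CE_pct"]), SE_pct = unname(ct["SE_pct"]),
               fpom_net_mean = mean(d$fpom_net), fpom_net_se = se(d$fpom_net),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg[order(-vapply(agg, function(d) d$richness,
                                              numeric(1)),
                                      names(agg))])
  rownames(summary) <- NULL

  structure(list(replicates = reps, summary = summary,
                 monocultures = mono, response = response,
                 detritivores = detritivores),
            class = "lh_partition_set")
}

#' @export
print.lh_partition_set <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Additive partitioning of diversity effects (%s arm, response: %s)\n",
    if (x$detritivores) "detritivore" else "detritivore-free", x$response))
  cat(sprintf("%d mixtures, %d replicates\n\n",
              nrow(x$summary), nrow(x$replicates)))
  print(x$summary, digits = digits)
  invisible(x)
}
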