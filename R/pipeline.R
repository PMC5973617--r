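## Orchestration: metrics -> partitioning -> trait metrics -> inference,
## with CSV/JSON outputs and a run log.

#' Pipeline configuration
#'
#' Collects paths and analysis switches for [run_pipeline()]. Any field
#' may be overridden; unknown fields are rejected.
#'
#' @param experiment Path to the experiment CSV (or an experiment
#'   data.frame).
#' @param traits Path to the trait CSV (or a trait data.frame); default
#'   the bundled [species_traits()].
#' @param out_dir Output directory for stage CSVs, the JSON summary and
#'   the run log; `NULL` (default) writes nothing.
#' @param leaching Named leaching factors.
#' @param allometry [allometry_params()].
#' @param arm `"detritivores"` (default), `"none"` or `"both"`: which
#'   experimental arm(s) to partition and test.
#' @param scale_convention Trait standardization convention.
#' @param equal_var Use a single residual variance in the one-way models
#'   (default FALSE: variance per group).
#' @param alpha Significance level.
#' @param n_larvae Larvae per detritivore microcosm.
#' @param seed Seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = NULL, traits = NULL,
                            out_dir = NULL,
                            leaching = leaching_factors(),
                            allometry = allometry_params(),
                            arm = c("detritivores", "none", "both"),
                            scale_convention = "sample_sd",
                            equal_var = FALSE,
                            alpha = 0.05, n_larvae = 3L, seed = NULL) {
  arm <- match.arg(arm)
  if (is.list(allometry) && !inherits(allometry, "allometry_params")) {
    allometry <- do.call(allometry_params, allometry)
  }
  if (is.list(leaching)) leaching <- unlist(leaching)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(experiment = experiment, traits = traits,
                 out_dir = out_dir, leaching = leaching,
                 allometry = allometry, arm = arm,
                 scale_convention = scale_convention,
                 equal_var = equal_var, alpha = alpha,
                 n_larvae = as.integer(n_larvae), seed = seed),
            class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the analysis sequence on an experiment table: per-microcosm
#' metrics; additive partitioning of diversity effects per mixture;
#' trait distances and mass-weighted mixture trait means; diversity-loss
#' tests per mixture nest (heteroscedastic one-way models with
#' Tukey-Kramer comparisons) for decomposition, FPOM production and
#' detritivore growth; and regressions of diversity effects on mixture
#' traits. When `config$out_dir` is set, each stage writes its CSV
#' (`metrics.csv`, `partition.csv`, `partition_summary.csv`,
#' `trait_distances.csv`, `mixture_traits.csv`, `anova.csv`,
#' `trait_models.csv`), a JSON summary and a run log.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_config()]).
#' @param experiment Optional experiment table overriding
#'   `config$experiment`.
#' @return Result bundle of class `beflitter_bundle`: list with
#'   `metrics`, `partition` (and `partition_none` for the
#'   detritivore-free arm when requested), `trait_distances`,
#'   `mixture_traits`, `anova_tests`, `anova_table`, `trait_models`,
#'   `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(), experiment = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  warn <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- "configuration"
  result <- tryCatch({
    experiment <- experiment %||% config$experiment
    if (is.null(experiment)) stop("configuration error: no experiment given")
    if (is.character(experiment)) {
      if (!file.exists(experiment)) {
        stop("configuration error: experiment file not found: ", experiment)
      }
      experiment <- read_experiment(experiment, config$n_larvae)
    } else if (!inherits(experiment, "beflitter_experiment")) {
      experiment <- validate_experiment(experiment, config$n_larvae)
    }
    traits <- config$traits %||% species_traits()
    if (is.character(traits)) {
      if (!file.exists(traits)) {
        stop("configuration error: traits file not found: ", traits)
      }
    }
    traits <- read_traits(traits)
    note("pipeline start: %d microcosms, arm = %s, alpha = %g%s",
         nrow(experiment), config$arm, config$alpha,
         if (is.null(config$seed)) "" else sprintf(", seed = %d",
                                                   config$seed))

    stage <- "metrics"
    metrics <- compute_metrics(experiment, config$leaching, config$allometry)
    if (any(metrics$mass_gain_flag)) {
      warn <- c(warn, sprintf(
        "negative per-species mass loss (apparent gain) in %d microcosm(s)",
        sum(metrics$mass_gain_flag)))
    }
    note("metrics: %d rows", nrow(metrics))

    stage <- "partitioning"
    arms <- switch(config$arm, detritivores = TRUE, none = FALSE,
                   both = c(TRUE, FALSE))
    ## canonical layout: partition the top mixture and its (richness-1)
    ## subsets when richness reaches 3; otherwise every mixture
    all_mix <- unique(metrics$composition[metrics$richness >= 2L])
    mix_rich <- vapply(all_mix, function(x) length(parse_composition(x)),
                       integer(1))
    keep <- if (max(mix_rich) >= 3L) all_mix[mix_rich >= 3L] else all_mix
    partition <- if (TRUE %in% arms) {
      partition_experiment(metrics, mixtures = keep)
    }
    partition_none <- if (FALSE %in% arms) {
      partition_experiment(metrics, detritivores = FALSE, mixtures = keep)
    }
    main_part <- partition %||% partition_none
    note("partitioning: %d mixtures", nrow(main_part$summary))

    stage <- "trait metrics"
    mixtures <- main_part$summary$mixture
    z <- standardize_traits(traits, config$scale_convention)
    dists <- pairwise_trait_distance(z)
    mixture_traits <- mixture_trait_table(traits, mixtures, experiment,
                                          config$leaching,
                                          config$scale_convention)
    note("trait metrics: %d mixtures", nrow(mixture_traits))

    stage <- "inference"
    top <- mixtures[which.max(vapply(mixtures, function(x)
      length(parse_composition(x)), integer(1)))]
    nests <- c(top, setdiff(mixtures, top))
    responses <- c(decomposition = "norm_total_loss", fpom = "fpom_norm",
                   growth = "growth_pct")
    anova_tests <- list()
    anova_rows <- list()
    for (det in arms) {
      resp <- if (det) responses else
        c(decomposition = "total_loss", fpom = "fpom_total")
      for (rn in names(resp)) {
        for (nest in nests) {
          key <- sprintf("%s.%s.%s", rn, nest,
                         if (det) "detritivores" else "none")
          tst <- tryCatch(
            diversity_loss_test(metrics, nest, resp[[rn]], det,
                                config$equal_var, config$alpha),
            error = function(e) NULL)
          if (is.null(tst)) next
          anova_tests[[key]] <- tst
          anova_rows[[key]] <- data.frame(
            response = rn, mixture = nest,
            arm = if (det) "detritivores" else "none",
            df1 = tst$fit$df1, df2 = tst$fit$df2,
            F = tst$fit$F, p = tst$fit$p.value,
            stringsAsFactors = FALSE)
        }
      }
    }
    anova_table <- do.call(rbind, anova_rows)
    rownames(anova_table) <- NULL
    note("inference: %d one-way models", nrow(anova_table))

    stage <- "trait regressions"
    trait_models <- NULL
    reg_mix <- mixture_traits[mixture_traits$richness ==
                                max(mixture_traits$richness) - 1L, ,
                              drop = FALSE]
    if (nrow(reg_mix) >= 3L && !is.null(partition)) {
      reps <- partition$replicates[partition$replicates$mixture %in%
                                     reg_mix$mixture, , drop = FALSE]
      predictors <- c(setdiff(names(reg_mix), c("mixture", "richness")),
                      NULL)
      effects <- c(net = "net", CE = "CE", SE = "SE", fpom_net = "fpom_net")
      rows <- list()
      for (en in names(effects)) {
        y <- reps[[effects[[en]]]]
        for (pn in predictors) {
          x <- reg_mix[[pn]][match(reps$mixture, reg_mix$mixture)]
          fit <- withCallingHandlers(
            regress_effect_on_trait(y, x, log_transform = TRUE),
            warning = function(w) {
              warn <<- c(warn, sprintf("%s ~ %s: %s", en, pn,
                                       conditionMessage(w)))
              invokeRestart("muffleWarning")
            })
          rows[[paste(en, pn)]] <- data.frame(
            effect = en, predictor = pn, slope = fit$slope, F = fit$F,
            p = fit$p.value, r.squared = fit$r.squared,
            log_response = fit$transform_response,
            log_predictor = fit$transform_predictor,
            stringsAsFactors = FALSE)
        }
      }
      trait_models <- do.call(rbind, rows)
      rownames(trait_models) <- NULL
      note("trait regressions: %d models", nrow(trait_models))
    } else {
      note("trait regressions skipped (no detritivore arm or < 3 mixtures)")
    }

    bundle <- structure(list(
      metrics = metrics, partition = partition,
      partition_none = partition_none,
      trait_distances = dists, mixture_traits = mixture_traits,
      anova_tests = anova_tests, anova_table = anova_table,
      trait_models = trait_models, config = config,
      warnings = warn, log = log_lines
    ), class = "beflitter_bundle")

    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundle
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.beflitter_bundle <- function(x, ...) {
  cat("beflitter result bundle\n")
  cat(sprintf("  %d microcosms, %d mixtures partitioned, %d one-way models\n",
              nrow(x$metrics),
              if (is.null(x$partition)) nrow(x$partition_none$summary)
              else nrow(x$partition$summary),
              nrow(x$anova_table)))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_results(bundle$metrics, p("metrics.csv"))
  part <- bundle$partition %||% bundle$partition_none
  write_results(part$replicates, p("partition.csv"))
  write_results(part$summary, p("partition_summary.csv"))
  d <- bundle$trait_distances$matrix
  pairs <- which(lower.tri(d), arr.ind = TRUE)
  write_results(data.frame(species1 = rownames(d)[pairs[, 1]],
                           species2 = colnames(d)[pairs[, 2]],
                           distance = d[pairs]),
                p("trait_distances.csv"))
  write_results(bundle$mixture_traits, p("mixture_traits.csv"))
  write_results(bundle$anova_table, p("anova.csv"))
  if (!is.null(bundle$trait_models)) {
    write_results(bundle$trait_models, p("trait_models.csv"))
  }
  part <- bundle$partition %||% bundle$partition_none
  summary <- list(
    mixtures = part$summary,
    anova = bundle$anova_table,
    trait_models = bundle$trait_models,
    warnings = bundle$warnings,
    config = list(arm = bundle$config$arm, alpha = bundle$config$alpha,
                  scale_convention = bundle$config$scale_convention,
                  seed = bundle$config$seed,
                  package_version = as.character(
                    utils::packageVersion("beflitter")))
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  writeLines(c(bundle$log,
               if (length(bundle$warnings))
                 paste("warning:", bundle$warnings)),
             p("run.log"))
  invisible(out_dir)
}

#' Render figures and tables from a result bundle
#'
#' Writes the standard report artifacts: mean +/- SE bar charts of the
#' responses by diversity level with significance letters, stacked
#' complementarity/selection bars per mixture, per-mixture effect plots,
#' and the one-way model and trait-regression tables as CSV.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @param format `"png"` or `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
make_report <- function(bundle, out_dir, format = c("png", "svg")) {
  stopifnot(inherits(bundle, "beflitter_bundle"))
  format <- match.arg(format)
  if (is.null(bundle$partition) && is.null(bundle$partition_none)) {
    stop("empty bundle: nothing to report")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dev_open <- function(f, w = 7, h = 5) {
    path <- file.path(out_dir, paste0(f, ".", format))
    if (format == "png") {
      grDevices::png(path, width = w, height = h, units = "in", res = 150)
    } else grDevices::svg(path, width = w, height = h)
    path
  }
  files <- character()

  ## responses by diversity level, with letters
  keys <- names(bundle$anova_tests)
  arm_key <- if (!is.null(bundle$partition)) "detritivores" else "none"
  top_keys <- keys[grepl(paste0("\\.", arm_key, "$"), keys)]
  if (length(top_keys)) {
    f <- dev_open("diversity_responses", w = 8, h = 3 * min(3, length(top_keys)))
    sel <- utils::head(top_keys, 3)
    graphics::par(mfrow = c(length(sel), 1), mar = c(4, 4, 2, 1))
    for (key in sel) {
      tst <- bundle$anova_tests[[key]]
      fit <- tst$fit
      se <- sqrt(fit$variances / fit$n)
      bp <- graphics::barplot(as.numeric(fit$means),
                              names.arg = fit$levels,
                              ylim = range(0, fit$means + 2 * se),
                              ylab = tst$response,
                              xlab = "diversity level (species richness)",
                              main = key)
      graphics::arrows(bp, fit$means - se, bp, fit$means + se,
                       angle = 90, code = 3, length = 0.05)
      graphics::text(bp, fit$means + 1.5 * se,
                     tst$pairwise$letters[fit$levels], pos = 3)
    }
    grDevices::dev.off()
    files <- c(files, f)
  }

  ## stacked CE/SE bars
  part <- bundle$partition %||% bundle$partition_none
  s <- part$summary
  f <- dev_open("partition_bars")
  m <- t(as.matrix(s[, c("CE_mean", "SE_mean")]))
  colnames(m) <- s$mixture
  graphics::barplot(m, beside = FALSE, legend.text = c("CE", "SE"),
                    ylab = "diversity effect", main =
                      "Complementarity and selection effects by mixture")
  grDevices::dev.off()
  files <- c(files, f)

  ## net / CE / SE / FPOM-net points with SE bars
  f <- dev_open("effects_by_mixture", w = 8, h = 6)
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  panels <- list(c("net_mean", "net_se", "net diversity effect"),
                 c("CE_mean", "CE_se", "complementarity effect"),
                 c("SE_mean", "SE_se", "selection effect"),
                 c("fpom_net_mean", "fpom_net_se", "FPOM net effect"))
  for (pl in panels) {
    y <- s[[pl[1]]]; e <- s[[pl[2]]]
    x <- seq_len(nrow(s))
    graphics::plot(x, y, pch = 19, xaxt = "n", xlab = "", ylab = pl[3],
                   ylim = range(c(y - 2 * e, y + 2 * e, 0)), main = pl[3])
    graphics::axis(1, at = x, labels = s$mixture, las = 2)
    graphics::arrows(x, y - e, x, y + e, angle = 90, code = 3,
                     length = 0.05)
    graphics::abline(h = 0, lty = 3)
  }
  grDevices::dev.off()
  files <- c(files, f)

  ## trait regressions figure
  if (!is.null(bundle$trait_models)) {
    f <- dev_open("trait_regressions", w = 8, h = 5)
    tm <- bundle$trait_models
    graphics::par(mar = c(7, 4, 2, 1))
    cols <- ifelse(tm$p < (bundle$config$alpha %||% 0.05), "black", "grey70")
    graphics::barplot(tm$F, names.arg = paste(tm$effect, tm$predictor),
                      las = 2, col = cols, ylab = "F statistic",
                      main = "Trait-effect regressions (dark: p < alpha)")
    grDevices::dev.off()
    files <- c(files, f)
  }

  ## tables
  t1 <- file.path(out_dir, "table_diversity_models.csv")
  write_results(bundle$anova_table, t1)
  files <- c(files, t1)
  if (!is.null(bundle$trait_models)) {
    t2 <- file.path(out_dir, "table_trait_models.csv")
    write_results(bundle$trait_models, t2)
    files <- c(files, t2)
  }
  invisible(files)
}
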