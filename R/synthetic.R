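## Seeded generator of complete microcosm experiments with injectable
## complementarity and selection mechanisms.
##
## Mechanistic core (per microcosm, duration T days):
##   post-leach AFDM_i = discs_i * disc_mass_i * leach_i
##   microbial loss_i  = postleach_i * (1 - exp(-k_micro_i * T))
##   consumption total C = gamma^[N>1] * c * B * T   (B = summed larval DM)
##   allocation_i ∝ preference_i * p_i, capped at availability with
##     proportional redistribution of the surplus
##   final AFDM_i = postleach_i - microbial_i - consumed_i
##   FPOM total = f_m * sum(microbial) + f_d * sum(consumed)
##   final detritivore DM = B + AE * sum(consumed) - maintenance * B * T
##
## Complementarity is injected as the consumption multiplier gamma
## (resource partitioning raises total consumption in mixtures);
## selection as the nitrogen-based preference exponent (consumption is
## tilted toward high-quality species). gamma = 1 with equal preferences
## and zero noise yields exactly null diversity effects.

#' Configuration of a synthetic microcosm experiment
#'
#' Defaults emulate the canonical design: 15 composition treatments (4
#' monocultures, 6 pairs, 4 triples, 1 quadrature of species A, C, Q,
#' I), 10 replicates each, half with 3 detritivore larvae, 48 leaf discs
#' per microcosm, 21-day duration with water changes on days 7, 14 and
#' 21.
#'
#' @param traits Species trait table (default [species_traits()]).
#' @param compositions Character vector of composition strings; default
#'   the full 15-treatment design over the trait table's species.
#' @param k_micro Named per-species microbial decay rate (day^-1).
#' @param consumption_rate Detritivore consumption rate c (mg leaf per
#'   mg detritivore per day).
#' @param preference_exponent Exponent mapping leaf nitrogen to
#'   consumption preference weights `N_pct^exponent`; 0 = no preference.
#' @param gamma Complementarity multiplier on consumption in mixtures
#'   (>= 0); 1 = no complementarity.
#' @param f_m,f_d Fractions of microbial loss and of consumption
#'   (egestion) entering FPOM, in [0, 1].
#' @param assimilation Assimilation efficiency of consumed litter into
#'   detritivore mass, in [0, 1].
#' @param maintenance Maintenance loss rate of detritivore mass
#'   (day^-1).
#' @param disc_mass Named per-species air-dry disc mass (mg); default
#'   disc area / SLA for 12-mm discs.
#' @param disc_area_mm2 Disc area used for the default disc mass.
#' @param leaching Named per-species leaching factors.
#' @param allometry An [allometry_params()] object.
#' @param n_discs_total Leaf discs per microcosm (split equally among
#'   species).
#' @param n_replicates Replicates per treatment and arm; the default 5
#'   gives 10 microcosms per composition treatment, half with
#'   detritivores (150 in the default 15-treatment design).
#' @param n_larvae Larvae per detritivore microcosm.
#' @param larva_dm_mean Mean initial larval dry mass (mg).
#' @param larva_dm_cv Between-larva coefficient of variation of initial
#'   dry mass.
#' @param duration Experiment duration (days).
#' @param water_change_days Days of the water changes (FPOM collections).
#' @param noise_mass_cv Multiplicative lognormal CV on final masses.
#' @param noise_filter_sd Additive SD (mg) on FPOM filter masses,
#'   truncated at zero.
#' @param noise_cl_sd Additive SD (mm) on measured case lengths.
#' @param seed Integer random seed; a fixed seed gives bit-identical
#'   output, and per-microcosm substreams ensure added replicates never
#'   change existing ones.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(traits = species_traits(),
                             compositions = NULL,
                             k_micro = c(A = 0.020, C = 0.012,
                                         Q = 0.005, I = 0.002),
                             consumption_rate = 0.25,
                             preference_exponent = 0.8,
                             gamma = 1.3,
                             f_m = 0.1, f_d = 0.4,
                             assimilation = 0.10, maintenance = 0.0105,
                             disc_mass = NULL, disc_area_mm2 = pi * 6^2,
                             leaching = leaching_factors(),
                             allometry = allometry_params(),
                             n_discs_total = 48,
                             n_replicates = 5L, n_larvae = 3L,
                             larva_dm_mean = 5.94, larva_dm_cv = 0.10,
                             duration = 21L,
                             water_change_days = c(7L, 14L, 21L),
                             noise_mass_cv = 0.05, noise_filter_sd = 0.3,
                             noise_cl_sd = 0.1,
                             seed = 42L) {
  traits <- read_traits(traits)
  species <- traits$species
  compositions <- compositions %||% default_design(species)
  disc_mass <- disc_mass %||%
    stats::setNames(disc_area_mm2 / traits$SLA, species)

  need <- function(x, what) {
    miss <- setdiff(species, names(x))
    if (length(miss)) {
      stop("invalid config field '", what, "': missing species ",
           paste(miss, collapse = ", "))
    }
    x[species]
  }
  k_micro <- need(k_micro, "k_micro")
  disc_mass <- need(disc_mass, "disc_mass")
  leaching <- need(leaching, "leaching")
  chk <- function(ok, what) if (!ok) stop("invalid config field '", what, "'")
  chk(all(k_micro >= 0), "k_micro")
  chk(consumption_rate >= 0, "consumption_rate")
  chk(gamma >= 0, "gamma")
  chk(f_m >= 0 && f_m <= 1, "f_m")
  chk(f_d >= 0 && f_d <= 1, "f_d")
  chk(assimilation >= 0 && assimilation <= 1, "assimilation")
  chk(maintenance >= 0, "maintenance")
  chk(all(disc_mass > 0), "disc_mass")
  chk(all(leaching > 0 & leaching <= 1), "leaching")
  chk(n_discs_total > 0, "n_discs_total")
  chk(n_replicates >= 1, "n_replicates")
  chk(n_larvae >= 1, "n_larvae")
  chk(larva_dm_mean > 0, "larva_dm_mean")
  chk(larva_dm_cv >= 0, "larva_dm_cv")
  chk(duration > 0, "duration")
  chk(length(water_change_days) >= 1 &&
        all(diff(c(0, water_change_days)) > 0) &&
        max(water_change_days) == duration, "water_change_days")
  chk(noise_mass_cv >= 0 && noise_filter_sd >= 0 && noise_cl_sd >= 0,
      "noise")
  chk(is.finite(seed) && abs(seed) < 2^31, "seed")
  for (cmp in compositions) {
    sp <- parse_composition(cmp)
    if (!all(sp %in% species)) {
      stop("invalid config field 'compositions': unknown species in ", cmp)
    }
  }
  structure(list(
    traits = traits, species = species, compositions = compositions,
    k_micro = k_micro, consumption_rate = consumption_rate,
    preference_exponent = preference_exponent, gamma = gamma,
    f_m = f_m, f_d = f_d, assimilation = assimilation,
    maintenance = maintenance, disc_mass = disc_mass,
    leaching = leaching, allometry = allometry,
    n_discs_total = n_discs_total, n_replicates = as.integer(n_replicates),
    n_larvae = as.integer(n_larvae), larva_dm_mean = larva_dm_mean,
    larva_dm_cv = larva_dm_cv, duration = duration,
    water_change_days = water_change_days,
    noise_mass_cv = noise_mass_cv, noise_filter_sd = noise_filter_sd,
    noise_cl_sd = noise_cl_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param species Character vector of species codes.
#' @return `default_design()` returns every non-empty subset of
#'   `species` as a composition string: monocultures, then all pairs,
#'   triples, ..., up to the full mixture (15 treatments for 4 species).
#' @export
default_design <- function(species) {
  unlist(lapply(seq_along(species), function(k) {
    utils::combn(species, k, format_composition)
  }))
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic microcosm experiment: %d treatments x 2 arms x %d reps ",
    "(%d microcosms)\n"),
    length(x$compositions), x$n_replicates,
    2 * length(x$compositions) * x$n_replicates))
  cat(sprintf("  gamma = %g, preference exponent = %g, c = %g, seed = %d\n",
              x$gamma, x$preference_exponent, x$consumption_rate, x$seed))
  invisible(x)
}

## Deterministic (noise-free) outcome of one microcosm.
## Returns per-species postleach, microbial, consumed, final AFDM plus
## FPOM and detritivore totals, given summed larval mass B.
deterministic_outcome <- function(config, composition, detritivores,
                                  B = config$n_larvae * config$larva_dm_mean) {
  sp <- parse_composition(composition)
  N <- length(sp)
  T <- config$duration
  discs <- config$n_discs_total / N
  init <- discs * config$disc_mass[sp]
  postleach <- init * config$leaching[sp]
  microbial <- postleach * (1 - exp(-config$k_micro[sp] * T))
  avail <- postleach - microbial

  consumed <- stats::setNames(rep(0, N), sp)
  if (detritivores && config$consumption_rate > 0) {
    C_tot <- config$gamma^(N > 1) * config$consumption_rate * B * T
    w <- config$traits$N_pct[match(sp, config$traits$species)] ^
      config$preference_exponent
    share <- w * (1 / N)               # preference x seeded proportion
    ## cap at availability, redistribute surplus proportionally
    active <- rep(TRUE, N)
    remaining <- C_tot
    repeat {
      if (!any(active) || remaining <= 0) break
      alloc <- remaining * share * active / sum(share[active])
      over <- active & (consumed + alloc > avail)
      if (!any(over)) {
        consumed <- consumed + alloc
        break
      }
      taken <- avail[over] - consumed[over]
      consumed[over] <- avail[over]
      remaining <- remaining - sum(taken)
      active[over] <- FALSE
    }
  }
  final_afdm <- postleach - microbial - consumed
  fpom <- config$f_m * sum(microbial) + config$f_d * sum(consumed)
  det_final <- if (detritivores) {
    B + config$assimilation * sum(consumed) - config$maintenance * B * T
  } else NA_real_
  list(species = sp, initial_airdry = init, postleach = postleach,
       microbial = microbial, consumed = consumed, final_afdm = final_afdm,
       fpom_total = fpom, B = B, detritivore_final_dm = det_final)
}

## Independent substream per microcosm so that adding replicates or
## reordering treatments never changes existing draws.
microcosm_seed <- function(seed, t_idx, arm, rep) {
  (abs(seed) * 1009 + t_idx * 7919 + arm * 3571 + rep * 104729) %% 2147483647L
}

#' Generate a synthetic microcosm experiment
#'
#' Simulates the full factorial of compositions x detritivore presence x
#' replicates under a [synthetic_config()], returning a validated
#' experiment table in the canonical flat schema. Noise: multiplicative
#' lognormal (mean 1) on final masses, additive zero-truncated Gaussian
#' on FPOM filter masses, additive Gaussian on measured case lengths.
#'
#' @param config A [synthetic_config()].
#' @return Experiment data.frame of class `beflitter_experiment`.
#' @export
#' @examples
#' exp <- generate_experiment(synthetic_config(n_replicates = 2))
#' nrow(exp)
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  species <- config$species
  fd <- config$water_change_days
  intervals <- diff(c(0, fd))
  lnorm_mult <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  rows <- list()
  idx <- 0L
  for (t_idx in seq_along(config$compositions)) {
    cmp <- config$compositions[t_idx]
    sp <- parse_composition(cmp)
    for (arm in c(1L, 0L)) {            # detritivores first, then without
      det <- arm == 1L
      for (rep_i in seq_len(config$n_replicates)) {
        idx <- idx + 1L
        set.seed(microcosm_seed(config$seed, t_idx, arm, rep_i))

        if (det) {
          larvae <- config$larva_dm_mean *
            lnorm_mult(config$n_larvae, config$larva_dm_cv)
          B <- sum(larvae)
          cl_true <- inverse_allometry(larvae, config$allometry)
          cl_obs <- pmax(cl_true + stats::rnorm(config$n_larvae,
                                                sd = config$noise_cl_sd),
                         0.1)
        } else {
          B <- NA_real_
          cl_obs <- rep(NA_real_, config$n_larvae)
        }

        out <- deterministic_outcome(config, cmp, det,
                                     B = if (det) B else 0)
        final_afdm <- out$final_afdm *
          lnorm_mult(length(sp), config$noise_mass_cv)
        ash <- config$traits$ash_pct[match(sp, config$traits$species)]
        final_dm <- final_afdm / (1 - ash / 100)

        fpom_ev <- out$fpom_total * intervals / config$duration
        if (config$noise_filter_sd > 0) {
          fpom_ev <- pmax(fpom_ev + stats::rnorm(length(fd),
                                                 sd = config$noise_filter_sd),
                          0)
        }
        det_final <- if (det) {
          max(out$detritivore_final_dm *
                lnorm_mult(1, config$noise_mass_cv), 1e-6)
        } else NA_real_

        row <- list(microcosm_id = sprintf("M%03d", idx),
                    composition = cmp,
                    detritivores_present = det,
                    n_discs_per_species = config$n_discs_total / length(sp))
        for (s in species) {
          j <- match(s, sp)
          row[[per_species_col("initial_airdry_dm", s)]] <-
            if (is.na(j)) NA_real_ else unname(out$initial_airdry[j])
          row[[per_species_col("final_dm", s)]] <-
            if (is.na(j)) NA_real_ else unname(final_dm[j])
          row[[per_species_col("final_afdm", s)]] <-
            if (is.na(j)) NA_real_ else unname(final_afdm[j])
        }
        for (k in seq_along(fd)) {
          row[[per_species_col("fpom_mg", paste0("d", fd[k]))]] <- fpom_ev[k]
        }
        for (j in seq_len(config$n_larvae)) {
          row[[per_species_col("case_length_mm", j)]] <- cl_obs[j]
        }
        row$detritivore_final_dm <- det_final
        rows[[idx]] <- row
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  validate_experiment(df, n_larvae = config$n_larvae)
}

#' Closed-form expected outcomes of a synthetic configuration
#'
#' Noise-free evaluation of the generator equations at the nominal
#' detritivore biomass: expected monoculture responses, per-mixture
#' net/complementarity/selection effects on normalised decomposition,
#' FPOM net effects and expected detritivore growth. These are the
#' ground-truth targets that the analysis pipeline should recover from
#' generated data.
#'
#' @param config A [synthetic_config()].
#' @return List with `monocultures` (species, M_norm_loss, M_fpom_norm),
#'   `mixtures` (mixture, richness, net, CE, SE, fpom_net, plus the
#'   detritivore-free nets, which are 0 by construction), and `growth`
#'   (composition, growth_pct).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  B0 <- config$n_larvae * config$larva_dm_mean
  comps <- config$compositions
  rich <- vapply(comps, function(x) length(parse_composition(x)), integer(1))

  mono_out <- lapply(comps[rich == 1L], deterministic_outcome,
                     config = config, detritivores = TRUE, B = B0)
  mono_sp <- vapply(mono_out, function(o) o$species, character(1))
  M_loss <- vapply(mono_out, function(o) {
    (sum(o$microbial) + sum(o$consumed)) / B0
  }, numeric(1))
  M_fpom <- vapply(mono_out, function(o) o$fpom_total / B0, numeric(1))
  names(M_loss) <- names(M_fpom) <- mono_sp

  mixtures <- do.call(rbind, lapply(comps[rich >= 2L], function(cmp) {
    sp <- parse_composition(cmp)
    o <- deterministic_outcome(config, cmp, TRUE, B = B0)
    Y <- (o$microbial + o$consumed) / B0
    part <- additive_partition(stats::setNames(Y, sp), M_loss)
    data.frame(mixture = cmp, richness = length(sp),
               net = part$net, CE = part$CE, SE = part$SE,
               fpom_net = net_effect_fpom(o$fpom_total / B0, M_fpom, sp),
               net_no_detritivores = 0,
               stringsAsFactors = FALSE)
  }))
  rownames(mixtures) <- NULL

  growth <- do.call(rbind, lapply(comps, function(cmp) {
    o <- deterministic_outcome(config, cmp, TRUE, B = B0)
    data.frame(composition = cmp,
               growth_pct = (o$detritivore_final_dm - B0) / B0 * 100,
               stringsAsFactors = FALSE)
  }))
  rownames(growth) <- NULL

  list(monocultures = data.frame(species = mono_sp,
                                 M_norm_loss = unname(M_loss),
                                 M_fpom_norm = unname(M_fpom),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
       mixtures = mixtures, growth = growth)
}
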