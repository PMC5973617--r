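## Derived per-microcosm quantities: leaching-corrected mass loss,
## detritivore-normalised decomposition, FPOM production and growth.

#' Allometric dry mass from case length
#'
#' Power-law estimate `DM = a * CL^b` of larval dry mass (mg) from
#' caddisfly case length (mm).
#'
#' @param case_length Case length(s), mm, > 0.
#' @param params An [allometry_params()] object.
#' @return Dry mass(es), mg.
#' @export
#' @examples
#' allometric_dm(10)            # a * 10^b with default parameters
allometric_dm <- function(case_length, params = allometry_params()) {
  if (any(!is.finite(case_length)) || any(case_length <= 0)) {
    stop("case_length must be positive")
  }
  params$a * case_length^params$b
}

#' @rdname allometric_dm
#' @param dm Dry mass(es), mg, > 0; inverted to the case length producing
#'   that mass under the allometry.
#' @export
inverse_allometry <- function(dm, params = allometry_params()) {
  if (any(!is.finite(dm)) || any(dm <= 0)) stop("dm must be positive")
  (dm / params$a)^(1 / params$b)
}

## Matrix (rows = microcosms, cols = species) of a per-species field.
species_matrix <- function(experiment, field, species = NULL) {
  species <- species %||% attr(experiment, "species") %||%
    experiment_species(experiment)
  m <- as.matrix(experiment[, per_species_col(field, species), drop = FALSE])
  colnames(m) <- species
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leaching-corrected initial AFDM
#'
#' Converts per-species initial air-dry disc mass to post-leach ash-free
#' dry mass by the per-species leaching factor (a single multiplicative
#' correction estimated from extra microcosms harvested after the 48 h
#' leaching phase).
#'
#' @param experiment Experiment table ([read_experiment()]).
#' @param factors Named per-species factors in (0, 1]
#'   ([leaching_factors()]).
#' @return Numeric matrix (microcosms x species) of corrected initial
#'   AFDM (mg); NA where a species is absent.
#' @export
corrected_initial_afdm <- function(experiment, factors = leaching_factors()) {
  species <- attr(experiment, "species") %||% experiment_species(experiment)
  missing <- setdiff(species, names(factors))
  if (length(missing)) {
    stop("configuration error: no leaching factor for species ",
         paste(missing, collapse = ", "))
  }
  f <- factors[species]
  if (any(f <= 0 | f > 1)) stop("leaching factors must be in (0, 1]")
  sweep(species_matrix(experiment, "initial_airdry_dm", species), 2, f, `*`)
}

#' Initial detritivore dry mass per microcosm
#'
#' Sums the allometric dry-mass estimates over the larvae of each
#' microcosm (initial larval mass is never measured directly; it is
#' always the allometric estimate from case length).
#'
#' @inheritParams corrected_initial_afdm
#' @param params An [allometry_params()] object.
#' @return Numeric vector (mg); NA for microcosms without detritivores.
#' @export
detritivore_initial_dm <- function(experiment, params = allometry_params()) {
  n_larvae <- attr(experiment, "n_larvae") %||% 3L
  out <- rep(NA_real_, nrow(experiment))
  det <- which(as.logical(experiment$detritivores_present))
  if (!length(det)) return(out)
  cl <- as.matrix(experiment[det, per_species_col("case_length_mm",
                                                  seq_len(n_larvae)),
                             drop = FALSE])
  out[det] <- rowSums(allometric_dm(cl, params))
  out
}

#' Litter mass loss per microcosm
#'
#' Per-species mass loss is leaching-corrected initial AFDM minus final
#' AFDM; the total is their sum. In microcosms with detritivores the
#' total and per-species losses are additionally divided by initial
#' detritivore dry mass, removing variation due to detritivore size.
#' Negative per-species losses (apparent mass gain, possible through
#' handling variance) are preserved and flagged, not clipped.
#'
#' @inheritParams corrected_initial_afdm
#' @param allometry An [allometry_params()] object (for the normalising
#'   detritivore mass).
#' @return data.frame with `microcosm_id`, per-species `loss__X` and
#'   `norm_loss__X` (mg and mg per mg detritivore), `total_loss`,
#'   `norm_total_loss` and `mass_gain_flag`.
#' @export
mass_loss <- function(experiment, factors = leaching_factors(),
                      allometry = allometry_params()) {
  init  <- corrected_initial_afdm(experiment, factors)
  final <- species_matrix(experiment, "final_afdm")
  loss  <- init - final
  total <- rowSums(loss, na.rm = TRUE)
  b     <- detritivore_initial_dm(experiment, allometry)
  det   <- as.logical(experiment$detritivores_present)
  if (any(det & !is.na(b) & b <= 0)) {
    stop("domain error: zero initial detritivore dry mass with detritivores present")
  }
  norm  <- loss / b          # NA rows where no detritivores
  out <- data.frame(microcosm_id = experiment$microcosm_id,
                    stringsAsFactors = FALSE)
  sp <- colnames(loss)
  out[per_species_col("loss", sp)] <- loss
  out$total_loss <- total
  out[per_species_col("norm_loss", sp)] <- norm
  out$norm_total_loss <- total / b
  out$mass_gain_flag <- apply(loss, 1, function(x) any(x < 0, na.rm = TRUE))
  out
}

#' FPOM production per microcosm
#'
#' Accumulated fine particulate organic matter over the successive water
#' replacements (sum of filter masses), normalised by initial detritivore
#' dry mass in microcosms with detritivores.
#'
#' @inheritParams mass_loss
#' @return data.frame with `microcosm_id`, `fpom_total` (mg) and
#'   `fpom_norm` (mg per mg detritivore; NA without detritivores).
#' @export
fpom_production <- function(experiment, allometry = allometry_params()) {
  fd <- attr(experiment, "fpom_days") %||% fpom_days(experiment)
  if (!length(fd)) stop("no FPOM collection events in the experiment table")
  ev <- as.matrix(experiment[, per_species_col("fpom_mg", paste0("d", fd)),
                             drop = FALSE])
  if (any(ev < 0, na.rm = TRUE)) {
    stop("validation error: negative FPOM filter mass")
  }
  total <- rowSums(ev)
  b <- detritivore_initial_dm(experiment, allometry)
  data.frame(microcosm_id = experiment$microcosm_id,
             fpom_total = total, fpom_norm = total / b,
             stringsAsFactors = FALSE)
}

#' Detritivore growth per microcosm
#'
#' Percentage change in detritivore dry mass over the incubation:
#' `(final DM - initial DM) / initial DM * 100`, with initial DM the
#' summed allometric estimate over larvae.
#'
#' @inheritParams mass_loss
#' @return data.frame with `microcosm_id`, `detritivore_initial_dm`,
#'   `detritivore_final_dm` and `growth_pct`; rows without detritivores
#'   carry NA.
#' @export
detritivore_growth <- function(experiment, allometry = allometry_params()) {
  det <- as.logical(experiment$detritivores_present)
  if (!any(det)) stop("domain error: no microcosms with detritivores")
  b <- detritivore_initial_dm(experiment, allometry)
  final <- if ("detritivore_final_dm" %in% names(experiment)) {
    as.numeric(experiment$detritivore_final_dm)
  } else rep(NA_real_, nrow(experiment))
  growth <- (final - b) / b * 100
  data.frame(microcosm_id = experiment$microcosm_id,
             detritivore_initial_dm = b,
             detritivore_final_dm = ifelse(det, final, NA_real_),
             growth_pct = growth, stringsAsFactors = FALSE)
}

#' All derived metrics for an experiment
#'
#' One row per microcosm combining [mass_loss()], [fpom_production()] and
#' [detritivore_growth()], plus composition and richness, ready for
#' partitioning and inference.
#'
#' @inheritParams mass_loss
#' @return data.frame of class `beflitter_metrics`.
#' @export
compute_metrics <- function(experiment, factors = leaching_factors(),
                            allometry = allometry_params()) {
  ml <- mass_loss(experiment, factors, allometry)
  fp <- fpom_production(experiment, allometry)
  det <- as.logical(experiment$detritivores_present)
  gr <- if (any(det)) detritivore_growth(experiment, allometry) else {
    data.frame(microcosm_id = experiment$microcosm_id,
               detritivore_initial_dm = NA_real_,
               detritivore_final_dm = NA_real_, growth_pct = NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- data.frame(
    microcosm_id = experiment$microcosm_id,
    composition = experiment$composition,
    richness = vapply(experiment$composition,
                      function(x) length(parse_composition(x)), integer(1)),
    detritivores_present = det,
    stringsAsFactors = FALSE
  )
  out <- cbind(out,
               ml[-1],
               fp[match(out$microcosm_id, fp$microcosm_id), -1, drop = FALSE],
               gr[match(out$microcosm_id, gr$microcosm_id), -1, drop = FALSE])
  rownames(out) <- NULL
  structure(out,
            species = attr(experiment, "species") %||%
              experiment_species(experiment),
            class = unique(c("beflitter_metrics", class(out))))
}
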