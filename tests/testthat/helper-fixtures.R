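# Fixtures are built in code; all masses mg, lengths mm.

# Case length that makes one larva weigh `dm` mg under the default allometry.
cl_for_dm <- function(dm, params = allometry_params()) {
  inverse_allometry(dm, params)
}

# Hand-built two-species experiment (species A and C):
#  - M001: detritivores, initial air-dry (100, 50), final AFDM (50, 40),
#    three larvae of 6 mg each (B = 18 mg), FPOM events 2.0 / 3.5 / 1.5.
#  - M002: same litter without detritivores.
two_species_experiment <- function() {
  cl <- cl_for_dm(6)
  df <- data.frame(
    microcosm_id = c("M001", "M002"),
    composition = "AC",
    detritivores_present = c(TRUE, FALSE),
    n_discs_per_species = 24,
    initial_airdry_dm__A = 100, initial_airdry_dm__C = 50,
    final_dm__A = 55, final_dm__C = 44,
    final_afdm__A = 50, final_afdm__C = 40,
    fpom_mg__d7 = 2.0, fpom_mg__d14 = 3.5, fpom_mg__d21 = 1.5,
    case_length_mm__1 = c(cl, NA), case_length_mm__2 = c(cl, NA),
    case_length_mm__3 = c(cl, NA),
    detritivore_final_dm = c(27, NA),
    stringsAsFactors = FALSE
  )
  validate_experiment(df)
}

# Small synthetic configuration for fast tests.
fast_config <- function(n_replicates = 2L, seed = 7L, ...) {
  synthetic_config(n_replicates = n_replicates, seed = seed, ...)
}

# Random partition instance: richness, positive monoculture means and
# observed responses.
random_partition_case <- function(richness) {
  sp <- paste0("s", seq_len(richness))
  M <- stats::setNames(stats::runif(richness, 0.5, 10), sp)
  Y <- stats::setNames(stats::runif(richness, 0.01, 12), sp)
  list(species = sp, M = M, Y = Y)
}
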