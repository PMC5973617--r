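## Domain tables, CSV schemas and validation.
##
## An experiment is a flat data.frame, one row per microcosm, with
## per-species measurements pivoted into columns named `<field>__<code>`
## (e.g. `initial_airdry_dm__A`). All masses are mg, lengths mm, days are
## integers since the start of the incubation.

#' Bundled leaf-trait table for the four default riparian species
#'
#' Mean leaf traits of the four species used as generator defaults:
#' \emph{Alnus glutinosa} (A, a nitrogen fixer), \emph{Corylus avellana}
#' (C, a fast-decomposing deciduous species), \emph{Quercus robur} (Q, a
#' slow-decomposing deciduous species) and \emph{Ilex aquifolium} (I, an
#' evergreen). Traits: nitrogen and phosphorus concentration (% dry mass),
#' specific leaf area (mm^2 mg^-1), leaf toughness (kPa) and ash
#' concentration (% dry mass).
#'
#' @return A data.frame with columns `species`, `N_pct`, `P_pct`, `SLA`,
#'   `toughness_kPa`, `ash_pct`.
#' @export
#' @examples
#' species_traits()
species_traits <- function() {
  data.frame(
    species       = c("A", "C", "Q", "I"),
    N_pct         = c(3.30, 1.48, 1.23, 1.58),
    P_pct         = c(0.084, 0.053, 0.041, 0.068),
    SLA           = c(13.28, 21.90, 11.50, 6.57),
    toughness_kPa = c(1397, 1016, 2793, 7715),
    ash_pct       = c(5.64, 5.66, 4.68, 3.93),
    stringsAsFactors = FALSE
  )
}

#' Default per-species leaching correction factors
#'
#' Multiplicative factors converting pre-leach air-dry disc mass to
#' post-leach ash-free dry mass (AFDM), estimated from extra microcosms
#' whose discs were removed after the 48 h leaching phase.
#'
#' @return Named numeric vector of factors in (0, 1].
#' @export
leaching_factors <- function() {
  c(A = 0.753, C = 0.843, Q = 0.844, I = 0.767)
}

#' Case-length to dry-mass allometry parameters
#'
#' Power-law allometry `DM = a * CL^b` relating caddisfly case length (mm)
#' to larval dry mass (mg). Defaults are the relationship fitted on extra
#' larvae spanning the experimental size range.
#'
#' @param a Coefficient (mg mm^-b), > 0.
#' @param b Exponent (dimensionless), > 0.
#' @return An object of class `allometry_params`.
#' @export
allometry_params <- function(a = 0.0043, b = 2.8041) {
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(b), length(b) == 1L)
  if (a <= 0 || b <= 0) stop("allometry parameters must be positive")
  structure(list(a = a, b = b), class = "allometry_params")
}

#' @export
print.allometry_params <- function(x, ...) {
  cat(sprintf("Case-length allometry: DM = %g * CL^%g (mg, mm)\n", x$a, x$b))
  invisible(x)
}

#' Parse a mixture composition code
#'
#' Compositions are written either as a concatenation of single-letter
#' species codes ("ACQ") or as codes joined by "+" ("A+C+Q", required when
#' any code has more than one character).
#'
#' @param x Composition string.
#' @return Character vector of species codes, in the given order.
#' @export
#' @examples
#' parse_composition("ACQI")
#' parse_composition("Aln+Cor")
parse_composition <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  sp <- if (grepl("+", x, fixed = TRUE)) {
    strsplit(x, "+", fixed = TRUE)[[1]]
  } else {
    strsplit(x, "", fixed = TRUE)[[1]]
  }
  sp <- sp[nzchar(sp)]
  if (anyDuplicated(sp)) {
    stop("duplicate species in composition '", x, "'")
  }
  sp
}

#' @rdname parse_composition
#' @param species Character vector of species codes.
#' @export
format_composition <- function(species) {
  if (all(nchar(species) == 1L)) paste(species, collapse = "")
  else paste(species, collapse = "+")
}

per_species_col <- function(field, species) paste0(field, "__", species)

## Species codes present in a table's per-species columns.
experiment_species <- function(df) {
  cols <- grep("^initial_airdry_dm__", names(df), value = TRUE)
  sub("^initial_airdry_dm__", "", cols)
}

fpom_days <- function(df) {
  cols <- grep("^fpom_mg__d", names(df), value = TRUE)
  sort(as.integer(sub("^fpom_mg__d", "", cols)))
}

#' Validate a microcosm experiment table
#'
#' Checks the experiment invariants: unique microcosm ids, non-negative
#' masses, per-species final AFDM not exceeding final DM, per-species mass
#' columns populated exactly for the species of each row's composition,
#' at least one FPOM collection column, and detritivore measurements
#' present if and only if detritivores are present.
#'
#' @param df Experiment data.frame (schema of [read_experiment()]).
#' @param n_larvae Expected number of case-length columns per detritivore
#'   microcosm.
#' @return `df`, classed as a `beflitter_experiment`, invisibly usable
#'   downstream.
#' @export
validate_experiment <- function(df, n_larvae = 3L) {
  required <- c("microcosm_id", "composition", "detritivores_present",
                "n_discs_per_species")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("experiment schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  species <- experiment_species(df)
  if (!length(species)) {
    stop("experiment schema error: no per-species 'initial_airdry_dm__*' columns")
  }
  for (f in c("final_dm", "final_afdm")) {
    miss <- setdiff(per_species_col(f, species), names(df))
    if (length(miss)) {
      stop("experiment schema error: missing required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  fd <- fpom_days(df)
  if (!length(fd)) {
    stop("experiment schema error: no 'fpom_mg__d<day>' columns")
  }
  if (anyDuplicated(df$microcosm_id)) {
    stop("validation error: duplicate microcosm_id: ",
         paste(unique(df$microcosm_id[duplicated(df$microcosm_id)]),
               collapse = ", "))
  }
  df$detritivores_present <- as.logical(df$detritivores_present)

  mass_cols <- c(per_species_col("initial_airdry_dm", species),
                 per_species_col("final_dm", species),
                 per_species_col("final_afdm", species),
                 per_species_col("fpom_mg", paste0("d", fd)))
  mass_cols <- c(mass_cols[mass_cols %in% names(df)],
                 intersect("detritivore_final_dm", names(df)))
  for (cc in mass_cols) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad)) {
      stop("validation error: negative mass in column '", cc,
           "' for microcosm ", df$microcosm_id[bad[1]])
    }
  }

  for (i in seq_len(nrow(df))) {
    sp <- parse_composition(df$composition[i])
    unknown <- setdiff(sp, species)
    if (length(unknown)) {
      stop("validation error: microcosm ", df$microcosm_id[i],
           " lists species without columns: ", paste(unknown, collapse = ", "))
    }
    for (f in c("initial_airdry_dm", "final_dm", "final_afdm")) {
      vals <- as.numeric(df[i, per_species_col(f, sp)])
      if (anyNA(vals)) {
        stop("validation error: microcosm ", df$microcosm_id[i],
             " missing ", f, " for species in its composition")
      }
    }
    afdm <- as.numeric(df[i, per_species_col("final_afdm", sp)])
    dm   <- as.numeric(df[i, per_species_col("final_dm", sp)])
    if (any(afdm > dm + 1e-9)) {
      stop("validation error: final_afdm > final_dm for microcosm ",
           df$microcosm_id[i])
    }
    if (isTRUE(df$detritivores_present[i])) {
      cl_cols <- per_species_col("case_length_mm", seq_len(n_larvae))
      if (!all(cl_cols %in% names(df)) ||
          anyNA(as.numeric(df[i, cl_cols]))) {
        stop("validation error: microcosm ", df$microcosm_id[i],
             " has detritivores but lacks ", n_larvae, " case lengths")
      }
      if (!"detritivore_final_dm" %in% names(df) ||
          is.na(df$detritivore_final_dm[i])) {
        stop("validation error: microcosm ", df$microcosm_id[i],
             " has detritivores but no detritivore_final_dm")
      }
    }
  }
  structure(df,
            species = species, fpom_days = fd, n_larvae = n_larvae,
            class = unique(c("beflitter_experiment", class(df))))
}

#' Read a microcosm experiment table from CSV
#'
#' The canonical interchange format is a flat CSV with one row per
#' microcosm and per-species measurements in columns named
#' `<field>__<code>`:
#' \describe{
#'   \item{microcosm_id}{unique identifier}
#'   \item{composition}{species codes, e.g. "ACQ" (see
#'     [parse_composition()])}
#'   \item{detritivores_present}{logical}
#'   \item{n_discs_per_species}{leaf discs seeded per species}
#'   \item{initial_airdry_dm__X, final_dm__X, final_afdm__X}{per-species
#'     masses (mg); NA for species absent from the row's composition}
#'   \item{fpom_mg__d7, ...}{FPOM filter mass (mg) per water change}
#'   \item{case_length_mm__1..L, detritivore_final_dm}{detritivore
#'     measurements, present iff `detritivores_present`}
#' }
#'
#' @param path CSV file path.
#' @param n_larvae Larvae per detritivore microcosm (default 3).
#' @return Validated experiment data.frame of class `beflitter_experiment`.
#' @export
read_experiment <- function(path, n_larvae = 3L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(structure(df, species = experiment_species(df),
                     fpom_days = fpom_days(df), n_larvae = n_larvae,
                     class = unique(c("beflitter_experiment", class(df)))))
  }
  validate_experiment(df, n_larvae = n_larvae)
}

#' Write a result table to CSV
#'
#' Plain CSV writer used for every stage output; values are written at
#' full double precision so that a read-after-write round trip is stable
#' to better than 1e-9.
#'
#' @param results Non-empty data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("refusing to write a zero-row table")
  old <- options(digits = 17)
  on.exit(options(old))
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a species trait table
#'
#' Expects columns `species`, `N_pct`, `P_pct`, `SLA`, `toughness_kPa`,
#' `ash_pct`; all trait values must be positive and complete.
#'
#' @param path CSV path, or a data.frame to validate in place.
#' @return Validated trait data.frame.
#' @export
read_traits <- function(path) {
  df <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "N_pct", "P_pct", "SLA", "toughness_kPa", "ash_pct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trait table schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$species)) stop("trait table: duplicate species codes")
  num <- df[, setdiff(required, "species")]
  if (anyNA(num)) stop("trait table: missing trait values")
  if (any(as.matrix(num) <= 0)) stop("trait table: all trait values must be > 0")
  df
}

#' Read a pipeline configuration file
#'
#' YAML configuration holding leaching factors, allometry parameters,
#' water-change days, the random seed and analysis switches. Missing
#' entries fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list (see [pipeline_config()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Import a deposited supplementary spreadsheet into the flat schema
#'
#' Adapter for experiment data deposited as a spreadsheet (one sheet of
#' underlying numbers per figure/table). It maps sheet columns of the form
#' `Microcosm`, `Mixture`, `Detritivores`, `<code>_initial_DM`,
#' `<code>_final_DM`, `<code>_final_AFDM`, `FPOM_d<day>`, `CL<j>` and
#' `Detritivore_final_DM` onto the canonical flat schema of
#' [read_experiment()]. The adapter fails loudly when the sheet stores
#' only mixture totals: per-species final AFDM columns are required for
#' the additive partition.
#'
#' @param path An `.xlsx` file (read via the readxl package when
#'   installed) or a CSV export of the relevant sheet.
#' @param sheet Sheet name or index for spreadsheet input.
#' @param n_larvae Larvae per detritivore microcosm.
#' @return Validated experiment data.frame of class `beflitter_experiment`.
#' @export
read_s1_data <- function(path, sheet = 1L, n_larvae = 3L) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the 'readxl' package; ",
           "export the sheet to CSV instead")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  ren <- c(Microcosm = "microcosm_id", Mixture = "composition",
           Detritivores = "detritivores_present",
           Discs_per_species = "n_discs_per_species",
           Detritivore_final_DM = "detritivore_final_dm")
  for (from in names(ren)) {
    if (from %in% names(df)) names(df)[names(df) == from] <- ren[[from]]
  }
  nm <- names(df)
  nm <- sub("^([A-Za-z]+)_initial_DM$",  "initial_airdry_dm__\\1", nm)
  nm <- sub("^([A-Za-z]+)_final_DM$",    "final_dm__\\1", nm)
  nm <- sub("^([A-Za-z]+)_final_AFDM$",  "final_afdm__\\1", nm)
  nm <- sub("^FPOM_d([0-9]+)$",          "fpom_mg__d\\1", nm)
  nm <- sub("^CL([0-9]+)$",              "case_length_mm__\\1", nm)
  names(df) <- nm

  if (!"composition" %in% names(df)) {
    stop("supplementary data import: no 'Mixture' column found")
  }
  if (!"n_discs_per_species" %in% names(df)) {
    df$n_discs_per_species <- NA_integer_   # metadata only, may be absent
  }
  species <- unique(unlist(lapply(df$composition, parse_composition)))
  no_afdm <- setdiff(species, experiment_species(df))
  no_afdm <- union(no_afdm,
                   species[!per_species_col("final_afdm", species) %in% names(df)])
  if (length(no_afdm)) {
    stop("supplementary data import: per-species final AFDM columns are ",
         "absent for species ", paste(sort(unique(no_afdm)), collapse = ", "),
         "; mixture totals alone cannot be partitioned")
  }
  if ("detritivores_present" %in% names(df) &&
      !is.logical(df$detritivores_present)) {
    df$detritivores_present <-
      tolower(as.character(df$detritivores_present)) %in%
      c("true", "yes", "y", "1")
  }
  validate_experiment(df, n_larvae = n_larvae)
}
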