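## Trait standardization, pairwise species distances and mixture-level
## trait metrics. The trait-variability metric of a mixture is the mean
## standardized Euclidean distance between its species pairs; mixture
## trait means are weighted by per-species litter mass.

#' Standardize a trait table to z-scores
#'
#' Centers and scales each trait across species so that traits measured
#' in very different units (e.g. kPa toughness vs % nitrogen) contribute
#' comparably to distances.
#'
#' @param traits Trait data.frame (see [read_traits()]); the `species`
#'   column labels rows, all other numeric columns are traits.
#' @param scale_convention `"sample_sd"` (divide by the n-1 standard
#'   deviation, default) or `"population_sd"` (divide by the n
#'   denominator SD).
#' @return Object of class `standardized_traits`: `z` (species x traits
#'   matrix), `center`, `scale`, `convention`.
#' @export
standardize_traits <- function(traits,
                               scale_convention = c("sample_sd",
                                                    "population_sd")) {
  scale_convention <- match.arg(scale_convention)
  traits <- read_traits(traits) # validates; accepts data.frame or path
  if (nrow(traits) < 2L) stop("need at least 2 species to standardize")
  x <- as.matrix(traits[, setdiff(names(traits), "species"), drop = FALSE])
  rownames(x) <- traits$species
  center <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (scale_convention == "population_sd") {
    s <- s * sqrt((nrow(x) - 1) / nrow(x))
  }
  degenerate <- colnames(x)[s == 0]
  if (length(degenerate)) {
    stop("degenerate trait(s) with zero spread: ",
         paste(degenerate, collapse = ", "))
  }
  z <- sweep(sweep(x, 2, center), 2, s, `/`)
  structure(list(z = z, center = center, scale = s,
                 convention = scale_convention),
            class = "standardized_traits")
}

#' @export
print.standardized_traits <- function(x, digits = 4, ...) {
  cat(sprintf("Standardized traits (%s convention), %d species x %d traits\n",
              x$convention, nrow(x$z), ncol(x$z)))
  print(round(x$z, digits))
  invisible(x)
}

#' Pairwise species trait distances
#'
#' Euclidean distance between species in standardized trait space.
#'
#' @param z A [standardize_traits()] object (or a plain numeric matrix of
#'   standardized traits with species rownames).
#' @return Object of class `trait_distance` holding the symmetric,
#'   zero-diagonal distance `matrix`.
#' @export
pairwise_trait_distance <- function(z) {
  if (inherits(z, "standardized_traits")) z <- z$z
  if (nrow(z) < 2L) {
    warning("fewer than 2 species; empty distance matrix")
    m <- matrix(numeric(0), 0, 0)
    return(structure(list(matrix = m), class = "trait_distance"))
  }
  m <- as.matrix(stats::dist(z, method = "euclidean"))
  structure(list(matrix = m), class = "trait_distance")
}

#' @export
print.trait_distance <- function(x, digits = 3, ...) {
  cat("Standardized Euclidean trait distances\n")
  m <- x$matrix
  m[upper.tri(m, diag = TRUE)] <- NA
  print(round(m, digits), na.print = "")
  invisible(x)
}

#' Mean trait distance of a mixture (trait variability)
#'
#' The trait-variability metric of a mixture: the arithmetic mean of the
#' `choose(N, 2)` pairwise standardized trait distances among its
#' species.
#'
#' @param dist A [pairwise_trait_distance()] object (or distance matrix).
#' @param mixture Composition string or character vector of species
#'   codes; richness must be >= 2.
#' @return Scalar mean pairwise distance.
#' @export
mean_trait_distance <- function(dist, mixture) {
  m <- if (inherits(dist, "trait_distance")) dist$matrix else as.matrix(dist)
  sp <- if (length(mixture) == 1L) parse_composition(mixture) else mixture
  if (length(sp) < 2L) {
    stop("domain error: trait variability needs at least 2 species")
  }
  missing <- setdiff(sp, rownames(m))
  if (length(missing)) {
    stop("species not in the distance matrix: ",
         paste(missing, collapse = ", "))
  }
  sub <- m[sp, sp]
  mean(sub[lower.tri(sub)])
}

#' Mass-weighted mixture trait means
#'
#' Average trait values of a mixture, each species weighted by its litter
#' dry mass in the mixture (typically the leaching-corrected initial
#' AFDM); with equal weights this is the simple mean.
#'
#' @param traits Trait data.frame (see [read_traits()]).
#' @param mixture Composition string or character vector of species codes.
#' @param weights Named per-species weights (> 0) for the mixture
#'   species; default equal.
#' @return Named numeric vector of per-trait weighted means.
#' @export
weighted_mixture_traits <- function(traits, mixture, weights = NULL) {
  traits <- read_traits(traits)
  sp <- if (length(mixture) == 1L) parse_composition(mixture) else mixture
  missing <- setdiff(sp, traits$species)
  if (length(missing)) {
    stop("species missing from trait table: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(weights)) {
    w <- stats::setNames(rep(1, length(sp)), sp)
  } else {
    if (is.null(names(weights))) stop("weights must be named by species")
    miss_w <- setdiff(sp, names(weights))
    if (length(miss_w)) {
      stop("configuration error: missing weight for species ",
           paste(miss_w, collapse = ", "))
    }
    w <- weights[sp]
    if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  }
  x <- as.matrix(traits[match(sp, traits$species),
                        setdiff(names(traits), "species"), drop = FALSE])
  colSums(x * w) / sum(w)
}

#' Mixture-level trait summary table
#'
#' Weighted trait means and trait variability for each mixture of a
#' design, with weights taken from mean per-species leaching-corrected
#' initial AFDM across that mixture's microcosms when an experiment is
#' supplied (falling back to equal weights otherwise).
#'
#' @param traits Trait data.frame.
#' @param mixtures Character vector of composition strings (richness
#'   >= 2).
#' @param experiment Optional experiment table used to derive mass
#'   weights.
#' @param factors Leaching factors for the weight computation.
#' @param scale_convention Passed to [standardize_traits()].
#' @return data.frame: one row per mixture with weighted trait means and
#'   `mean_trait_distance`.
#' @export
mixture_trait_table <- function(traits, mixtures, experiment = NULL,
                                factors = leaching_factors(),
                                scale_convention = "sample_sd") {
  traits <- read_traits(traits)
  z <- standardize_traits(traits, scale_convention)
  d <- pairwise_trait_distance(z)
  weights_for <- function(mixture) {
    if (is.null(experiment)) return(NULL)
    rows <- experiment$composition == mixture
    if (!any(rows)) return(NULL)
    init <- corrected_initial_afdm(experiment[rows, , drop = FALSE], factors)
    w <- colMeans(init, na.rm = TRUE)
    w[parse_composition(mixture)]
  }
  out <- do.call(rbind, lapply(mixtures, function(mx) {
    wm <- weighted_mixture_traits(traits, mx, weights_for(mx))
    cbind(data.frame(mixture = mx,
                     richness = length(parse_composition(mx)),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(wm)),
          data.frame(mean_trait_distance = mean_trait_distance(d, mx)))
  }))
  rownames(out) <- NULL
  out
}
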