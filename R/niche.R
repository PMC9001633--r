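# Climate-niche summaries: per-species climate means, correlation-matrix
# PCA with broken-stick axis retention, and climate stability through time.

#' Per-species mean climate values
#'
#' Extracts each climate layer at every occurrence point and averages per
#' species. Points falling on no-data cells are excluded from the mean of
#' that variable; duplicated records deliberately weight the mean (point
#' density is information). Species with no valid extraction on one or more
#' variables are dropped with a warning so the result has no missing cells.
#'
#' @param occurrences Data frame `species`, `lon`, `lat`.
#' @param rasters Named list of [climate_raster()] objects on a shared grid.
#' @return A tibble: `species` plus one numeric column per climate variable.
#' @export
species_climate_means <- function(occurrences, rasters) {
  stopifnot(is.data.frame(occurrences), length(rasters) >= 1)
  if (is.null(names(rasters)) || any(!nzchar(names(rasters)))) {
    names(rasters) <- vapply(rasters, function(r) r$name, character(1))
  }
  g0 <- rasters[[1]]$grid
  same <- vapply(rasters, function(r) identical(r$grid, g0), logical(1))
  if (!all(same)) stop("all rasters must share one grid.", call. = FALSE)
  vals <- purrr::map(rasters, raster_extract,
                     lon = occurrences$lon, lat = occurrences$lat)
  long <- tibble::tibble(species = occurrences$species, !!!vals)
  out <- long |>
    tidyr::pivot_longer(-"species", names_to = "variable") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("species", "variable")) |>
    tidyr::pivot_wider(names_from = "variable")
  complete <- stats::complete.cases(out)
  covered <- unique(occurrences$species)
  dropped <- union(setdiff(covered, out$species), out$species[!complete])
  if (length(dropped) > 0) {
    warning("species dropped for lacking valid climate extractions: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out[complete, ]
}

# broken-stick expected eigenvalue proportions for p components
broken_stick_ <- function(p) {
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
}

#' Correlation-matrix PCA of species climate niches
#'
#' Standardises the climate matrix (so the decomposition is of the variable
#' correlation matrix) and runs a principal components analysis. The number
#' of axes worth interpreting is chosen by the broken-stick criterion: axis
#' k is retained while its eigenvalue proportion exceeds the broken-stick
#' expectation \eqn{b_k = (1/p) \sum_{i=k}^{p} 1/i}. Each loading vector is
#' oriented so its largest-magnitude element is positive, which fixes the
#' sign convention across linear-algebra backends.
#'
#' @param data A data frame with a `species` column and >= 2 numeric climate
#'   columns; >= 3 species required, all variables with nonzero variance.
#' @return A `niche_pca` object: `scores` (tibble, species x PCs),
#'   `loadings` (variables x PCs matrix), `eigenvalues`,
#'   `percent_variance`, `broken_stick` (expected percents), `n_retained`,
#'   `center`, `scale`.
#' @export
niche_pca <- function(data) {
  if (!"species" %in% names(data)) {
    stop("`data` must have a `species` column.", call. = FALSE)
  }
  num <- data[vapply(data, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("need at least 3 species.", call. = FALSE)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(names(num)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  pc <- stats::prcomp(as.matrix(num), center = TRUE, scale. = TRUE)
  # sign convention: dominant loading positive on every axis
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  eig <- pc$sdev^2
  p <- length(eig)
  prop <- eig / sum(eig)
  bs <- broken_stick_(p)
  below <- which(prop <= bs)
  n_retained <- if (length(below) == 0) p else below[1] - 1L
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(species = data$species),
                              tibble::as_tibble(pc$x)),
    loadings = pc$rotation,
    eigenvalues = eig,
    percent_variance = 100 * prop,
    broken_stick = 100 * bs,
    n_retained = as.integer(n_retained),
    center = pc$center,
    scale = pc$scale
  ), class = "niche_pca")
}

#' @export
print.niche_pca <- function(x, ...) {
  cat(sprintf("<niche_pca> %d species x %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  k <- min(3, length(x$percent_variance))
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), x$percent_variance[seq_len(k)]),
            collapse = ", "), "\n")
  cat("  broken-stick retains", x$n_retained, "axis/axes\n")
  invisible(x)
}

#' Relative climate stability from time-sliced layers
#'
#' For each variable, the per-cell deviation is the mean over consecutive
#' time slices of `|value change| / |time step|` (uneven spacing is thereby
#' handled by rating each step per Myr). Stability is `1 / (deviation +
#' eps)`, rescaled to a maximum of 1; the combined surface is the product of
#' per-variable stabilities, again rescaled to 1.
#'
#' @param slices Either a list of `climate_raster`s (one variable) or a
#'   named list of such lists (one per variable), all on one grid, ordered
#'   oldest first to match `ages`.
#' @param ages Slice ages in Myr before present, strictly decreasing,
#'   aligned with `slices`.
#' @param eps Guard added to the deviation before inversion (default 1e-9).
#' @return A `stability_result`: `stability` (combined `climate_raster` in
#'   \[0, 1\]), `per_variable` (list of stability rasters), `deviation`
#'   (list of deviation rasters).
#' @export
climate_stability <- function(slices, ages, eps = 1e-9) {
  if (length(slices) > 0 && inherits(slices[[1]], "climate_raster")) {
    slices <- list(layer = slices)
  }
  if (any(diff(ages) >= 0)) {
    stop("`ages` must be strictly decreasing (oldest slice first).",
         call. = FALSE)
  }
  g0 <- slices[[1]][[1]]$grid
  deviation <- purrr::imap(slices, function(sl, nm) {
    if (length(sl) != length(ages)) {
      stop("variable '", nm, "' has ", length(sl), " slices for ",
           length(ages), " ages.", call. = FALSE)
    }
    ok <- vapply(sl, function(r) identical(r$grid, g0), logical(1))
    if (!all(ok)) stop("slice grids differ for variable '", nm, "'.",
                       call. = FALSE)
    steps <- purrr::map(seq_len(length(sl) - 1), function(k) {
      abs(sl[[k + 1]]$values - sl[[k]]$values) / abs(ages[k + 1] - ages[k])
    })
    climate_raster(Reduce(`+`, steps) / length(steps), g0,
                   name = paste0(nm, "_deviation"))
  })
  per_var <- purrr::imap(deviation, function(d, nm) {
    s <- 1 / (d$values + eps)
    climate_raster(s / max(s, na.rm = TRUE), g0,
                   name = paste0(nm, "_stability"))
  })
  comb <- Reduce(`*`, purrr::map(per_var, "values"))
  comb <- comb / max(comb, na.rm = TRUE)
  structure(list(
    stability = climate_raster(comb, g0, name = "stability"),
    per_variable = per_var,
    deviation = deviation,
    ages = ages, eps = eps
  ), class = "stability_result")
}
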