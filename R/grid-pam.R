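# Regular lon/lat grids, presence-absence matrices, and per-cell diversity
# metrics (species richness, Faith's PD, quartile richness residuals).

#' Define a regular longitude/latitude grid
#'
#' Cells are half-open intervals `[x, x + size) x [y, y + size)` anchored at
#' the grid's south-west corner, so every in-bounds point maps to exactly
#' one cell. Cell 1 is the SW corner; cells are numbered row-major, rows
#' running south to north.
#'
#' @param lon_min,lat_min Coordinates of the SW corner (decimal degrees).
#' @param n_cols,n_rows Grid dimensions.
#' @param cell_size Cell edge in degrees (default 0.5).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(lon_min, lat_min, n_cols, n_rows, cell_size = 0.5) {
  stopifnot(n_cols >= 1, n_rows >= 1, cell_size > 0)
  structure(
    list(lon_min = lon_min, lat_min = lat_min,
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         cell_size = cell_size),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, SW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$lon_min, x$lat_min))
  invisible(x)
}

n_cells_ <- function(grid) grid$n_rows * grid$n_cols

# tibble of cell ids with row/col indices and centre coordinates
grid_cells_ <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    cell = seq_len(n_cells_(grid)),
    row = row, col = col,
    lon = grid$lon_min + (col - 0.5) * grid$cell_size,
    lat = grid$lat_min + (row - 0.5) * grid$cell_size
  )
}

# Map points to cell ids; NA for out-of-bounds (N/E outer boundary included,
# per the half-open convention).
point_to_cell_ <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$cell_size) + 1
  row <- floor((lat - grid$lat_min) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- as.integer((row[ok] - 1) * grid$n_cols + col[ok])
  out
}

#' Build a presence-absence matrix from occurrence records
#'
#' @param occurrences Data frame with columns `species`, `lon`, `lat`
#'   (WGS84 decimal degrees).
#' @param grid A [grid_spec()].
#' @return A `pam` object: binary cells x species incidence plus the grid.
#'   Out-of-bounds records (including points on the N/E outer boundary) are
#'   dropped with a message; species left without any in-bounds record are
#'   dropped with a warning.
#' @export
build_pam <- function(occurrences, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.data.frame(occurrences) || nrow(occurrences) == 0) {
    stop("`occurrences` must be a non-empty data frame.", call. = FALSE)
  }
  req <- c("species", "lon", "lat")
  if (!all(req %in% names(occurrences))) {
    stop("`occurrences` needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  cell <- point_to_cell_(grid, occurrences$lon, occurrences$lat)
  n_drop <- sum(is.na(cell))
  if (n_drop > 0) {
    message(n_drop, " out-of-bounds occurrence record(s) dropped.")
  }
  keep <- !is.na(cell)
  if (!any(keep)) stop("no occurrence falls inside the grid.", call. = FALSE)
  lost <- setdiff(unique(occurrences$species), unique(occurrences$species[keep]))
  if (length(lost) > 0) {
    warning("species with no in-bounds record dropped: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  species <- sort(unique(occurrences$species[keep]))
  inc <- matrix(0L, n_cells_(grid), length(species),
                dimnames = list(NULL, species))
  inc[cbind(cell[keep], match(occurrences$species[keep], species))] <- 1L
  new_pam(inc, grid)
}

new_pam <- function(incidence, grid) {
  structure(list(incidence = incidence, grid = grid,
                 species = colnames(incidence)),
            class = "divscape_pam")
}

#' @export
print.divscape_pam <- function(x, ...) {
  cat(sprintf("<pam> %d cells x %d species, %d occupied cells\n",
              nrow(x$incidence), ncol(x$incidence),
              sum(rowSums(x$incidence) > 0)))
  print(x$grid)
  invisible(x)
}

#' Per-cell species richness
#'
#' @param pam A `pam` object.
#' @return A tibble `cell`, `row`, `col`, `lon`, `lat`, `sr` covering every
#'   grid cell (empty cells have `sr = 0`).
#' @export
cell_richness <- function(pam) {
  stopifnot(inherits(pam, "divscape_pam"))
  out <- grid_cells_(pam$grid)
  out$sr <- as.integer(rowSums(pam$incidence))
  out
}

# cells x edges incidence: a branch is present in a cell iff the cell holds
# at least one tip descending from it. Shared by PD, PE, and CANAPE.
branch_cell_incidence_ <- function(pam, tree) {
  missing <- setdiff(pam$species, tree$tip.label)
  if (length(missing) > 0) {
    stop("species absent from the tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tip_inc <- edge_tip_incidence_(tree) # edges x tips
  p <- pam$incidence[, tree$tip.label[tree$tip.label %in% pam$species],
                     drop = FALSE]
  d <- tip_inc[, colnames(p), drop = FALSE]
  m <- (p %*% t(d)) > 0 # cells x edges
  storage.mode(m) <- "double"
  m
}

#' Per-cell Faith's phylogenetic diversity
#'
#' PD of a cell is the total branch length of the minimal subtree connecting
#' the cell's species to the root (root path included, so a cell holding all
#' species has PD equal to the tree's total branch length).
#'
#' @param pam A `pam` object whose species all appear in `tree`.
#' @param tree A `phylo` object; tips not in the PAM are allowed for PD
#'   (their branches simply never enter a cell).
#' @return A tibble `cell`, `row`, `col`, `lon`, `lat`, `sr`, `pd` (Myr);
#'   `pd` is `NA` for empty cells.
#' @export
cell_pd <- function(pam, tree) {
  stopifnot(inherits(pam, "divscape_pam"))
  tree <- validate_tree(tree)
  m <- branch_cell_incidence_(pam, tree)
  out <- cell_richness(pam)
  out$pd <- as.numeric(m %*% tree$edge.length)
  out$pd[out$sr == 0] <- NA_real_
  out
}

#' Quartile richness residual maps
#'
#' For each DR quartile, regresses per-cell quartile richness on total cell
#' richness over occupied cells (ordinary least squares) and returns the
#' residuals: positive residuals flag cells holding more species of that
#' quartile than overall richness predicts.
#'
#' @param pam A `pam` object.
#' @param quartiles Data frame `species`, `quartile` (e.g. from
#'   [equal_splits_dr()]) or a named vector.
#' @return A long tibble: `cell`, `row`, `col`, `lon`, `lat`, `quartile`,
#'   `richness`, `total_richness`, `fitted`, `residual`, one row per
#'   occupied cell and quartile.
#' @export
quartile_residual_map <- function(pam, quartiles) {
  stopifnot(inherits(pam, "divscape_pam"))
  if (is.data.frame(quartiles)) {
    q <- stats::setNames(quartiles$quartile, quartiles$species)
  } else {
    q <- quartiles
  }
  missing <- setdiff(pam$species, names(q))
  if (length(missing) > 0) {
    stop("no quartile for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  q <- q[pam$species]
  total <- rowSums(pam$incidence)
  occupied <- which(total >= 1)
  if (length(occupied) < 3) {
    stop("fewer than 3 occupied cells; residual regression is not defined.",
         call. = FALSE)
  }
  cells <- grid_cells_(pam$grid)[occupied, ]
  cells$total_richness <- as.integer(total[occupied])
  purrr::map_dfr(sort(unique(q)), function(qq) {
    rq <- rowSums(pam$incidence[occupied, q == qq, drop = FALSE])
    fit <- stats::lm(rq ~ cells$total_richness)
    dplyr::mutate(cells,
                  quartile = qq,
                  richness = as.integer(rq),
                  fitted = as.numeric(stats::fitted(fit)),
                  residual = as.numeric(stats::residuals(fit)))
  })
}

#' Pairwise correlations between diversity metrics
#'
#' Pearson and Spearman correlations with p-values for every pair of numeric
#' columns (e.g. SR and PD per cell, or DR and species age per species).
#'
#' @param data A data frame; non-numeric columns are ignored.
#' @return A tibble `metric_x`, `metric_y`, `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
metric_correlation <- function(data) {
  num <- data[vapply(data, is.numeric, logical(1))]
  num <- num[, !(names(num) %in% c("cell", "row", "col", "rank", "quartile")),
             drop = FALSE]
  if (ncol(num) < 2) stop("need at least two numeric metric columns.", call. = FALSE)
  pairs <- utils::combn(names(num), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- num[[pr[1]]]; y <- num[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) stop("fewer than 3 paired observations for ",
                            pr[1], " ~ ", pr[2], call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("zero variance in ", pr[1], " or ", pr[2],
           "; correlation undefined.", call. = FALSE)
    }
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    tibble::tibble(metric_x = pr[1], metric_y = pr[2], n = length(x),
                   pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                   spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  })
}
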