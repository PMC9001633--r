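# Synthetic-data generators: birth-death trees, BM and Mk traits,
# gradient-plus-noise climate landscapes, niche-driven occurrences, and
# bundled scenario fixtures. Every generator is seed-deterministic and
# reports the true generating parameters alongside the data.

#' Simulate a birth-death tree
#'
#' Forward (Gillespie) simulation from a single lineage, stopping either
#' when `n_tips` lineages are simultaneously extant (the clock then runs to
#' the next event time so terminal branches are positive) or at `max_time`.
#' Extinct lineages are pruned, so the returned tree is ultrametric. When
#' every lineage dies before the stopping condition the simulation is
#' retried up to `max_retries` times, then errors; note that retrying
#' conditions the output on survival.
#'
#' @param birth,death Speciation and extinction rates (events per lineage
#'   per Myr); `birth > death >= 0`.
#' @param n_tips Stop when this many lineages are extant (exclusive with
#'   `max_time`).
#' @param max_time Stop at this time (Myr from the starting lineage).
#' @param seed Integer seed, or `NULL`.
#' @param max_retries Retries after total extinction.
#' @return An ultrametric `phylo`; a single-tip tree when only one lineage
#'   survives to `max_time`.
#' @export
simulate_bd_tree <- function(birth, death = 0, n_tips = NULL, max_time = NULL,
                             seed = NULL, max_retries = 100) {
  if (!(birth > death && death >= 0)) {
    stop("need birth > death >= 0.", call. = FALSE)
  }
  if (is.null(n_tips) == is.null(max_time)) {
    stop("give exactly one of `n_tips` or `max_time`.", call. = FALSE)
  }
  if (!is.null(n_tips) && n_tips < 1) stop("n_tips must be >= 1.", call. = FALSE)
  with_seed_(seed, {
    for (try in seq_len(max_retries)) {
      res <- bd_forward_(birth, death, n_tips, max_time)
      if (!is.null(res)) return(res)
    }
    stop("total extinction in every attempt (", max_retries, " retries).",
         call. = FALSE)
  })
}

# One forward pass; NULL on total extinction.
bd_forward_ <- function(birth, death, n_tips, max_time) {
  # lineage records
  parent <- c(NA_integer_)
  t_birth <- c(0)
  t_end <- c(NA_real_)
  children <- list(integer(0))
  active <- 1L
  now <- 0
  repeat {
    n_act <- length(active)
    if (n_act == 0) return(NULL)
    if (!is.null(n_tips) && n_act >= n_tips) {
      now <- now + stats::rexp(1, n_act * (birth + death))
      break
    }
    dt <- stats::rexp(1, n_act * (birth + death))
    if (!is.null(max_time) && now + dt > max_time) {
      now <- max_time
      break
    }
    now <- now + dt
    who <- active[if (n_act == 1L) 1L else sample.int(n_act, 1)]
    if (stats::runif(1) < birth / (birth + death)) {
      id1 <- length(parent) + 1L
      id2 <- id1 + 1L
      parent <- c(parent, who, who)
      t_birth <- c(t_birth, now, now)
      t_end <- c(t_end, NA_real_, NA_real_)
      children[[who]] <- c(children[[who]], id1, id2)
      children[[id1]] <- integer(0)
      children[[id2]] <- integer(0)
      t_end[who] <- now
      active <- c(setdiff(active, who), id1, id2)
    } else {
      t_end[who] <- now
      active <- setdiff(active, who)
    }
  }
  t_end[active] <- now
  extant <- active
  if (length(extant) == 0) return(NULL)
  if (length(extant) == 1L) {
    tr <- ape::read.tree(text = sprintf("(t1:%.12g);", now - t_birth[extant]))
    return(tr)
  }
  # build Newick over the stored intervals, then drop extinct tips
  labels <- character(length(parent))
  labels[extant] <- paste0("t", seq_along(extant))
  dead <- which(!is.na(t_end) & lengths(children) == 0 & !(seq_along(parent) %in% extant))
  labels[dead] <- paste0("x", seq_along(dead))
  build <- function(id) {
    kids <- children[[id]]
    if (length(kids) == 0) {
      return(sprintf("%s:%.12g", labels[id], t_end[id] - t_birth[id]))
    }
    sprintf("(%s,%s):%.12g", build(kids[1]), build(kids[2]),
            t_end[id] - t_birth[id])
  }
  # the starting lineage has no parent edge; wrap its subtree as the root
  kids <- children[[1L]]
  txt <- if (length(kids) == 0) {
    sprintf("(%s:%.12g);", labels[1L], t_end[1L] - t_birth[1L])
  } else {
    sprintf("(%s,%s):%.12g;", build(kids[1]), build(kids[2]),
            t_end[1L] - t_birth[1L])
  }
  tr <- ape::read.tree(text = txt)
  drop <- grep("^x", tr$tip.label, value = TRUE)
  if (length(drop) > 0) {
    if (length(setdiff(tr$tip.label, drop)) < 2) return(NULL)
    tr <- ape::drop.tip(tr, drop)
  }
  tr$root.edge <- NULL # stem interval is not part of the crown tree
  tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
  tr
}

# tips x n_sim BM simulations with unit structure: increments per edge,
# accumulated through the path incidence matrix (fast for repeated sims).
bm_sim_matrix_ <- function(tree, sigma2, n_sim, z0 = 0) {
  ne <- nrow(tree$edge)
  paths <- tip_path_edges_(tree)
  A <- matrix(0, ape::Ntip(tree), ne)
  for (i in seq_along(paths)) A[i, paths[[i]]] <- 1
  inc <- matrix(stats::rnorm(ne * n_sim, 0,
                             sqrt(pmax(sigma2 * tree$edge.length, 0))),
                ne, n_sim)
  z0 + A %*% inc
}

#' Simulate a continuous trait under (multi-rate) Brownian motion
#'
#' On a plain tree, increments along each branch are Gaussian with variance
#' `sigma2 * branch length`. On a [stochastic_map()]-style painted tree,
#' `sigma2` is a named per-state vector and each branch segment contributes
#' variance `sigma2[state] * duration`, so the tip covariance equals the
#' state-time-weighted shared path length.
#'
#' @param tree A `phylo` or `painted_tree`.
#' @param sigma2 Rate (trait^2/Myr); named per-state vector for painted
#'   trees.
#' @param z0 Root state.
#' @param seed Integer seed, or `NULL`.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, z0 = 0, seed = NULL) {
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0.", call. = FALSE)
  with_seed_(seed, {
    if (inherits(tree, "painted_tree")) {
      st <- edge_state_times_(tree)
      if (is.null(names(sigma2)) && length(sigma2) == 1) {
        sigma2 <- stats::setNames(rep(sigma2, ncol(st)), colnames(st))
      }
      missing <- setdiff(colnames(st), names(sigma2))
      if (length(missing) > 0) {
        stop("sigma2 missing for state(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      var_e <- as.numeric(st %*% sigma2[colnames(st)])
      phy <- tree$tree
    } else {
      phy <- validate_tree(tree)
      var_e <- sigma2 * phy$edge.length
    }
    n_tip <- ape::Ntip(phy)
    val <- numeric(n_tip + phy$Nnode)
    val[n_tip + 1L] <- z0
    pre <- ape::reorder.phylo(phy, "cladewise")
    ord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                 paste(phy$edge[, 1], phy$edge[, 2]))
    for (e in seq_len(nrow(pre$edge))) {
      val[pre$edge[e, 2]] <- val[pre$edge[e, 1]] +
        stats::rnorm(1, 0, sqrt(var_e[ord[e]]))
    }
    stats::setNames(val[seq_len(n_tip)], phy$tip.label)
  })
}

#' Simulate a discrete trait under the equal-rates Mk process
#'
#' Forward simulation from a (uniform or fixed) root state; returns both
#' the tip states and the true branch painting, so parsimony and mapping
#' diagnostics can be validated against the real history.
#'
#' @param tree A `phylo` object.
#' @param q Transition rate (per Myr, per ordered state pair).
#' @param states Vector of state labels (>= 2).
#' @param root_state Optional fixed root state; sampled uniformly when
#'   `NULL`.
#' @param seed Integer seed, or `NULL`.
#' @return A list: `states` (named tip vector), `history` (`painted_tree`),
#'   `n_changes`, `q`.
#' @export
simulate_mk_trait <- function(tree, q, states = c("A", "B"),
                              root_state = NULL, seed = NULL) {
  tree <- validate_tree(tree)
  if (q < 0) stop("q must be >= 0.", call. = FALSE)
  k <- length(states)
  if (k < 2) stop("need >= 2 states.", call. = FALSE)
  with_seed_(seed, {
    n_tip <- ape::Ntip(tree)
    root <- n_tip + 1L
    node_state <- integer(n_tip + tree$Nnode)
    node_state[root] <- if (is.null(root_state)) sample.int(k, 1) else {
      match(root_state, states)
    }
    pre <- ape::reorder.phylo(tree, "cladewise")
    eidx <- edge_index_(tree)
    edge_maps <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1]
      ch <- pre$edge[e, 2]
      t_e <- pre$edge.length[e]
      cur <- node_state[p]
      segs <- numeric(0)
      seg_states <- integer(0)
      now <- 0
      if (q > 0) {
        repeat {
          dt <- stats::rexp(1, (k - 1) * q)
          if (now + dt >= t_e) break
          segs <- c(segs, dt)
          seg_states <- c(seg_states, cur)
          cur <- pick_other_(k, cur)
          now <- now + dt
        }
      }
      segs <- c(segs, t_e - now)
      seg_states <- c(seg_states, cur)
      edge_maps[[eidx$edge_of[ch]]] <- stats::setNames(segs,
                                                       states[seg_states])
      node_state[ch] <- cur
    }
    history <- new_painted_tree(tree, edge_maps,
                                tip_states = stats::setNames(
                                  states[node_state[seq_len(n_tip)]],
                                  tree$tip.label),
                                node_states = states[node_state[(n_tip + 1):
                                                                  length(node_state)]])
    list(states = history$tip_states, history = history,
         n_changes = n_state_changes(history), q = q)
  })
}

# Gaussian-ish smoothing of a matrix by repeated 3x3 box blurs.
smooth_matrix_ <- function(m, passes = 2) {
  if (passes <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    padded <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
    acc <- matrix(0, nr, nc)
    for (dr in 0:2) for (dc in 0:2) {
      acc <- acc + padded[dr + seq_len(nr), dc + seq_len(nc)]
    }
    m <- acc / 9
  }
  m
}

#' Generate a synthetic climate landscape
#'
#' Emulates bioclim-style layers on a regular grid: temperature-like
#' variables carry a north-to-south latitudinal gradient plus a shared
#' smooth "elevation" field and per-variable smooth noise; precipitation-
#' like variables are clamped non-negative. Optional time slices add a
#' smooth per-slice drift field to the base layer, emulating paleoclimate
#' reconstructions for the stability analysis.
#'
#' @param grid A [grid_spec()].
#' @param n_temperature,n_precipitation Number of layers of each flavour
#'   (defaults 11 + 8 = the 19 bioclim-style variables).
#' @param gradient Mean equator-to-pole temperature drop across the grid
#'   (deg C; the realised north-minus-south difference averages `-gradient`).
#' @param elevation_sd Amplitude of the shared smooth elevation field.
#' @param noise_sd Per-variable smooth-noise amplitude.
#' @param n_slices Number of time slices per variable (0 = none).
#' @param slice_ages Ages (Myr, strictly decreasing) when `n_slices > 0`;
#'   defaults to an even ladder from 3.3 Myr to 0.
#' @param drift_sd Amplitude of the per-slice drift fields.
#' @param seed Integer seed, or `NULL`.
#' @return A list: `rasters` (named list of [climate_raster()]), `slices`
#'   (per variable, oldest first; empty when `n_slices = 0`),
#'   `slice_ages`, `params`.
#' @export
generate_landscape <- function(grid, n_temperature = 11, n_precipitation = 8,
                               gradient = 15, elevation_sd = 3, noise_sd = 1,
                               n_slices = 0, slice_ages = NULL, drift_sd = 1,
                               seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_slices > 0 && is.null(slice_ages)) {
    slice_ages <- seq(3.3, 0, length.out = n_slices)
  }
  with_seed_(seed, {
    nr <- grid$n_rows; nc <- grid$n_cols
    lat_norm <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
    elevation <- smooth_matrix_(matrix(stats::rnorm(nr * nc), nr, nc), 3)
    elevation <- elevation / max(stats::sd(elevation), 1e-12) * elevation_sd
    nm_t <- sprintf("bio%02d", seq_len(n_temperature))
    nm_p <- sprintf("bio%02d", n_temperature + seq_len(n_precipitation))
    base <- list()
    for (i in seq_len(n_temperature)) {
      noise <- smooth_matrix_(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc), 2) *
        noise_sd
      vals <- 25 - gradient * lat_norm - 0.8 * elevation + noise +
        stats::rnorm(1, 0, 2)
      base[[nm_t[i]]] <- climate_raster(vals, grid, nm_t[i])
    }
    for (i in seq_len(n_precipitation)) {
      noise <- smooth_matrix_(matrix(stats::rnorm(nr * nc, 0, 1), nr, nc), 2) *
        noise_sd * 100
      vals <- pmax(1200 - 600 * lat_norm + 150 * elevation + noise, 0)
      base[[nm_p[i]]] <- climate_raster(vals, grid, nm_p[i])
    }
    slices <- list()
    if (n_slices > 0) {
      slices <- purrr::imap(base, function(r, nm) {
        lapply(seq_len(n_slices), function(s) {
          drift <- smooth_matrix_(matrix(stats::rnorm(nr * nc), nr, nc), 2) *
            drift_sd * (if (nm %in% nm_p) 100 else 1)
          climate_raster(r$values + drift * (s < n_slices), grid,
                         sprintf("%s_slice%d", nm, s))
        })
      })
    }
    list(rasters = base, slices = slices, slice_ages = slice_ages,
         params = list(gradient = gradient, elevation_sd = elevation_sd,
                       noise_sd = noise_sd, drift_sd = drift_sd,
                       n_temperature = n_temperature,
                       n_precipitation = n_precipitation))
  })
}

#' Generate occurrence records around species niche centroids
#'
#' Draws, for each species, either a single record (with probability
#' `single_fraction`, emulating the point endemics that dominate real
#' compilations) or several records scattered around the species' centroid
#' with Gaussian dispersion. Points are redrawn until they fall inside the
#' grid.
#'
#' @param species Character vector of species names.
#' @param grid A [grid_spec()].
#' @param centroids Optional tibble `species`, `lon`, `lat`; drawn
#'   uniformly inside the grid when `NULL`.
#' @param dispersion Gaussian scatter (degrees) around the centroid.
#' @param single_fraction Probability that a species is represented by a
#'   single record (default 0.65).
#' @param max_points Upper bound for multi-record species (2 to
#'   `max_points`, uniform).
#' @param seed Integer seed, or `NULL`.
#' @return A tibble `species`, `lon`, `lat`; attribute `centroids` holds
#'   the generating centroids.
#' @export
generate_occurrences <- function(species, grid, centroids = NULL,
                                 dispersion = 0.5, single_fraction = 0.65,
                                 max_points = 10, seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  lon_max <- grid$lon_min + grid$n_cols * grid$cell_size
  lat_max <- grid$lat_min + grid$n_rows * grid$cell_size
  with_seed_(seed, {
    if (is.null(centroids)) {
      centroids <- tibble::tibble(
        species = species,
        lon = stats::runif(length(species), grid$lon_min, lon_max - 1e-9),
        lat = stats::runif(length(species), grid$lat_min, lat_max - 1e-9))
    }
    bad <- is.na(point_to_cell_(grid, centroids$lon, centroids$lat))
    if (any(bad)) {
      stop("centroid(s) outside the grid for: ",
           paste(centroids$species[bad], collapse = ", "), call. = FALSE)
    }
    out <- purrr::pmap_dfr(centroids, function(species, lon, lat) {
      n_pts <- if (stats::runif(1) < single_fraction) 1L else {
        if (max_points <= 2) 2L else sample(2:max_points, 1)
      }
      pts <- matrix(NA_real_, n_pts, 2)
      for (i in seq_len(n_pts)) {
        for (draw in 1:100) {
          p <- c(lon, lat) + stats::rnorm(2, 0, dispersion)
          if (!is.na(point_to_cell_(grid, p[1], p[2]))) break
          p <- c(lon, lat) # dispersion may exceed the grid; fall back
        }
        pts[i, ] <- p
      }
      tibble::tibble(species = species, lon = pts[, 1], lat = pts[, 2])
    })
    attr(out, "centroids") <- centroids
    out
  })
}

#' Bundled synthetic scenarios with known truth
#'
#' Fully populated tree + traits + landscape + occurrence bundles whose
#' generating parameters are recorded, for end-to-end pipeline tests:
#'
#' * `"null"` — Yule tree, single-rate BM niche trait, occurrences with no
#'   endemism structure beyond the niche-latitude coupling.
#' * `"two_rate_niche"` — island/mainland history evolved under Mk; island
#'   lineages evolve their niche 10x faster.
#' * `"paleo_island"` — one relict species on a branch an order of
#'   magnitude longer than any other, endemic to a single cell; the
#'   classic paleo-endemism signature.
#' * `"mode_shift"` — four reproductive modes (AQ/GN/FN/DD) evolved under
#'   Mk with mode-dependent niche rates.
#'
#' Species niche values set centroid latitude (cool-adapted species sit on
#' the poleward, cooler side of the gradient), so climate PCA axes have
#' recoverable structure.
#'
#' @param name One of `"null"`, `"two_rate_niche"`, `"paleo_island"`,
#'   `"mode_shift"`.
#' @param seed Integer seed (default 1).
#' @return A `synthetic_scenario` list: `name`, `seed`, `tree`, `traits`
#'   (tibble: species, niche, mode, island, region), `histories`,
#'   `occurrences`, `grid`, `landscape`, `params` (all true generating
#'   values), and for `"paleo_island"` the `target_cell`.
#' @export
scenario_fixture <- function(name = c("null", "two_rate_niche",
                                      "paleo_island", "mode_shift"),
                             seed = 1) {
  name <- match.arg(name)
  grid <- grid_spec(lon_min = 95, lat_min = -5, n_cols = 20, n_rows = 20,
                    cell_size = 0.5)
  params <- list(birth = 0.09, n_species = 100, sigma2_niche = 0.05,
                 q_mode = 0.02, q_island = 0.02, dispersion = 0.6,
                 single_fraction = 0.65)
  s <- function(o) child_seed_(seed, o)

  if (name == "paleo_island") {
    base <- simulate_bd_tree(params$birth, 0, n_tips = 40, seed = s(1))
    crown <- max(ape::node.depth.edgelength(base))
    stem <- crown # the relict branch is crown + stem = 2x crown age
    txt <- sub(";$", "", write_newick(base))
    tree <- read_newick(sprintf("(%s:%.10g,relict:%.10g);", txt, stem,
                                crown + stem))
  } else {
    tree <- simulate_bd_tree(params$birth, 0, n_tips = params$n_species,
                             seed = s(1))
  }
  n <- ape::Ntip(tree)

  island_sim <- simulate_mk_trait(tree, params$q_island,
                                  states = c("island", "mainland"),
                                  seed = s(2))
  mode_sim <- simulate_mk_trait(tree, params$q_mode,
                                states = c("AQ", "GN", "FN", "DD"),
                                root_state = "AQ", seed = s(3))

  sigma2_true <- switch(name,
    null = params$sigma2_niche,
    paleo_island = params$sigma2_niche,
    two_rate_niche = c(island = 10 * params$sigma2_niche,
                       mainland = params$sigma2_niche),
    mode_shift = c(AQ = 0.02, GN = 0.05, FN = 0.2, DD = 0.3))
  niche <- if (name %in% c("null", "paleo_island")) {
    simulate_bm_trait(tree, sigma2_true, seed = s(4))
  } else if (name == "two_rate_niche") {
    simulate_bm_trait(island_sim$history, sigma2_true, seed = s(4))
  } else {
    simulate_bm_trait(mode_sim$history, sigma2_true, seed = s(4))
  }

  # niche-latitude coupling: cool-adapted (low niche value) species sit
  # further north on the cooler side of the gradient
  lat_max <- grid$lat_min + grid$n_rows * grid$cell_size
  lat_span <- lat_max - grid$lat_min - grid$cell_size
  lat_c <- grid$lat_min + grid$cell_size / 2 +
    lat_span * (rank(-niche) - 0.5) / n
  lon_max <- grid$lon_min + grid$n_cols * grid$cell_size
  centroids <- with_seed_(s(5), tibble::tibble(
    species = tree$tip.label,
    lon = stats::runif(n, grid$lon_min + 0.25, lon_max - 0.25),
    lat = lat_c))
  occurrences <- generate_occurrences(tree$tip.label, grid,
                                      centroids = centroids,
                                      dispersion = params$dispersion,
                                      single_fraction = params$single_fraction,
                                      seed = s(6))
  target_cell <- NULL
  if (name == "paleo_island") {
    # confine the relict to one dedicated cell (single record)
    target_cell <- point_to_cell_(grid, grid$lon_min + 0.25,
                                  grid$lat_min + 0.25)
    occurrences <- occurrences |>
      dplyr::filter(.data$species != "relict") |>
      dplyr::bind_rows(tibble::tibble(species = "relict",
                                      lon = grid$lon_min + 0.25,
                                      lat = grid$lat_min + 0.25))
  }
  landscape <- generate_landscape(grid, n_slices = 4, seed = s(7))
  region <- cut(centroids$lon, 3, labels = c("west", "central", "east"))
  traits <- tibble::tibble(
    species = tree$tip.label,
    niche = unname(niche),
    mode = unname(mode_sim$states),
    island = unname(island_sim$states),
    region = as.character(region))
  structure(list(
    name = name, seed = seed, tree = tree, traits = traits,
    histories = list(island = island_sim$history, mode = mode_sim$history),
    occurrences = occurrences, grid = grid, landscape = landscape,
    target_cell = target_cell,
    params = c(params, list(sigma2_true = sigma2_true))
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> '%s' (seed %d): %d species, %d occurrences\n",
              x$name, x$seed, ape::Ntip(x$tree), nrow(x$occurrences)))
  invisible(x)
}
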