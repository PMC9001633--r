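# Configuration-driven orchestration of the full analysis pipeline with
# pre-flight validation, per-stage CSV outputs, and a JSON run manifest.

#' Read a pipeline run configuration
#'
#' The configuration is a YAML file with the documented keys: `seed`,
#' `output.dir`, `stages` (logical toggles: `tip_rates`, `pam`,
#' `diversity`, `canape`, `niche`, `stability`, `trait_evolution`,
#' `essim`), `grid` (`lon_min`, `lat_min`, `n_cols`, `n_rows`,
#' `cell_size`), `inputs` (either `scenario: {name, seed}` for synthetic
#' data, or file paths `tree`, `occurrences`, `traits`, plus optional
#' `rasters`, a directory of ASCII grids), and `params` (`n_reps`,
#' `n_swaps`, `alpha`, `super_alpha`, `n_sim`, `n_null`, `n_maps`).
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

default_stages_ <- function() {
  list(tip_rates = TRUE, pam = TRUE, diversity = TRUE, canape = TRUE,
       niche = TRUE, stability = TRUE, trait_evolution = TRUE, essim = TRUE)
}

default_params_ <- function() {
  list(n_reps = 199, n_swaps = 1000, alpha = 0.05, super_alpha = 0.01,
       n_sim = 100, n_null = 199, n_maps = 10)
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in dependency order — tree validation, tip
#' rates, PAM, richness/PD/quartile residual maps, CANAPE, climate means,
#' PCA, climate stability, BM/DTT/traitgram, Mk + stochastic maps +
#' multi-rate BM, ES-sim — writing one CSV per stage, a JSON manifest
#' (package version, seeds, parameters, stage timings, warnings), and a
#' plain-text summary. Inputs are validated against the enabled stages
#' before any computation; a stage failure halts the run naming the stage,
#' with earlier outputs retained.
#'
#' @param config A `run_config`, a config list, or a YAML path.
#' @param out_dir Output directory (created if needed); overrides
#'   `config$output$dir`.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- utils::modifyList(default_stages_(), config$stages %||% list())
  params <- utils::modifyList(default_params_(), config$params %||% list())
  out_dir <- out_dir %||% config$output$dir %||% stop("no output directory.")
  seed <- config$seed %||% 1L
  inputs <- config$inputs %||% list()

  # ---- pre-flight validation ----
  uses_occurrences <- stages$pam || stages$diversity || stages$canape ||
    stages$niche
  synthetic <- !is.null(inputs$scenario)
  if (!synthetic) {
    if (is.null(inputs$tree)) {
      stop("pre-flight: stage 'tree' requires inputs$tree.", call. = FALSE)
    }
    if (uses_occurrences && is.null(inputs$occurrences)) {
      stop("pre-flight: stages pam/diversity/canape/niche require ",
           "inputs$occurrences.", call. = FALSE)
    }
    if ((stages$trait_evolution || stages$essim) && is.null(inputs$traits)) {
      stop("pre-flight: stages trait_evolution/essim require inputs$traits.",
           call. = FALSE)
    }
    if (stages$niche && is.null(inputs$rasters)) {
      stop("pre-flight: stage niche requires inputs$rasters.", call. = FALSE)
    }
    if (stages$stability && is.null(inputs$rasters) && is.null(inputs$scenario)) {
      stop("pre-flight: stage stability requires time-sliced rasters ",
           "(synthetic scenario input only, in this release).", call. = FALSE)
    }
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(package = "divscape",
                   version = as.character(utils::packageVersion("divscape")),
                   seed = seed, params = params,
                   stages = stages, started = format(Sys.time()),
                   warnings = character(0), log = list())
  log_stage <- function(name, note) {
    manifest$log[[name]] <<- note
    message(sprintf("[%s] %s", name, note))
  }
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    log_stage(name, sprintf("done in %.2fs", as.numeric(Sys.time() - t0,
                                                        units = "secs")))
    res
  }

  # ---- load inputs ----
  if (synthetic) {
    scen <- run_stage("simulate", scenario_fixture(
      inputs$scenario$name %||% "null",
      seed = inputs$scenario$seed %||% seed))
    tree <- scen$tree
    occurrences <- scen$occurrences
    traits <- scen$traits
    grid <- scen$grid
    rasters <- scen$landscape$rasters
    slices <- scen$landscape$slices
    slice_ages <- scen$landscape$slice_ages
    manifest$scenario <- list(name = scen$name, seed = scen$seed)
  } else {
    tree <- run_stage("tree", read_newick(inputs$tree))
    occurrences <- if (!is.null(inputs$occurrences)) {
      utils::read.csv(inputs$occurrences)
    }
    traits <- if (!is.null(inputs$traits)) utils::read.csv(inputs$traits)
    g <- config$grid
    grid <- if (!is.null(g)) {
      grid_spec(g$lon_min, g$lat_min, g$n_cols, g$n_rows,
                g$cell_size %||% 0.5)
    }
    rasters <- if (!is.null(inputs$rasters)) {
      files <- sort(list.files(inputs$rasters, pattern = "\\.asc$",
                               full.names = TRUE))
      stats::setNames(lapply(files, read_ascii_grid),
                      sub("\\.asc$", "", basename(files)))
    }
    slices <- NULL
    slice_ages <- NULL
  }
  write_out <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }

  if (stages$tip_rates) {
    results$tip_rates <- run_stage("tiprates", {
      tr <- equal_splits_dr(tree)
      dplyr::left_join(tr, species_age(tree), by = "species")
    })
    write_out(results$tip_rates, "tip_rates.csv")
  }
  if (stages$pam || stages$diversity || stages$canape) {
    if (is.null(grid)) {
      # default grid snapped to the occurrence extent
      grid <- grid_spec(floor(min(occurrences$lon) / 0.5) * 0.5,
                        floor(min(occurrences$lat) / 0.5) * 0.5,
                        ceiling(diff(range(occurrences$lon)) / 0.5) + 1,
                        ceiling(diff(range(occurrences$lat)) / 0.5) + 1)
    }
    pam <- run_stage("pam", build_pam(occurrences, grid))
    results$pam <- pam
    write_out(dplyr::mutate(grid_cells_(grid),
                            sr = as.integer(rowSums(pam$incidence))),
              "pam_cell_summary.csv")
  }
  if (stages$diversity) {
    results$diversity <- run_stage("diversity", {
      pd <- cell_pd(pam, tree)
      res <- quartile_residual_map(pam, results$tip_rates %||%
                                     equal_splits_dr(tree))
      list(pd = pd, residuals = res,
           correlations = metric_correlation(
             dplyr::filter(pd, .data$sr > 0)[, c("sr", "pd")]))
    })
    write_out(results$diversity$pd, "cell_diversity.csv")
    write_out(results$diversity$residuals, "quartile_residuals.csv")
  }
  if (stages$canape) {
    results$canape <- run_stage("canape", canape_classify(
      pam, tree, n_reps = params$n_reps, n_swaps = params$n_swaps,
      seed = child_seed_(seed, 11), alpha = params$alpha,
      super_alpha = params$super_alpha))
    write_out(results$canape, "canape.csv")
  }
  if (stages$niche) {
    results$niche <- run_stage("niche", {
      clim <- species_climate_means(occurrences, rasters)
      pca <- niche_pca(clim)
      list(climate = clim, pca = pca)
    })
    write_out(results$niche$climate, "species_climate.csv")
    write_out(results$niche$pca$scores, "pca_scores.csv")
  }
  if (stages$stability && !is.null(slices) && length(slices) > 0) {
    # mirror the two-variable convention: one temperature layer (bio01)
    # and one precipitation layer (bio12) drive the stability surface
    pick <- intersect(c("bio01", "bio12"), names(slices))
    if (length(pick) == 0) pick <- names(slices)[1]
    results$stability <- run_stage("stability",
      climate_stability(slices[pick], slice_ages))
    stab <- results$stability$stability
    write_out(dplyr::mutate(grid_cells_(stab$grid),
                            stability = as.vector(t(stab$values))),
              "stability.csv")
  }
  if (stages$trait_evolution) {
    results$trait_evolution <- run_stage("traitevol", {
      niche_trait <- stats::setNames(traits$niche, traits$species)
      fit <- bm_fit(tree, niche_trait)
      d <- dtt(tree, niche_trait, n_null = params$n_null,
               seed = child_seed_(seed, 12))
      tg <- traitgram(tree, niche_trait)
      mk <- mk_fit(tree, stats::setNames(traits$island, traits$species))
      maps <- stochastic_map(tree, stats::setNames(traits$island,
                                                   traits$species),
                             fit = mk, n_maps = params$n_maps,
                             seed = child_seed_(seed, 13))
      mr <- multirate_bm(maps, niche_trait)
      list(bm = fit, dtt = d, traitgram = tg, mk = mk, multirate = mr)
    })
    write_out(results$trait_evolution$dtt$curve, "dtt_curve.csv")
    write_out(results$trait_evolution$traitgram, "traitgram.csv")
    write_out(results$trait_evolution$multirate$rates, "multirate_rates.csv")
  }
  if (stages$essim) {
    results$essim <- run_stage("essim", essim(
      tree, stats::setNames(traits$niche, traits$species),
      n_sim = params$n_sim, seed = child_seed_(seed, 14)))
    write_out(tibble::tibble(rho = results$essim$rho,
                             p_value = results$essim$p_value,
                             n_sim = results$essim$n_sim),
              "essim.csv")
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  summary_lines <- c(
    sprintf("divscape pipeline run (seed %s)", seed),
    sprintf("tree: %d tips, crown age %.2f Myr", ape::Ntip(tree),
            max(ape::node.depth.edgelength(tree))),
    if (!is.null(results$tip_rates)) {
      sprintf("DR: median %.4f [%.4f, %.4f]",
              stats::median(results$tip_rates$dr),
              min(results$tip_rates$dr), max(results$tip_rates$dr))
    },
    if (!is.null(results$canape)) {
      sprintf("CANAPE: %d/%d occupied cells significant (%s)",
              sum(results$canape$significant), nrow(results$canape),
              paste(names(table(results$canape$endemism_type)),
                    table(results$canape$endemism_type),
                    sep = "=", collapse = ", "))
    },
    if (!is.null(results$niche)) {
      sprintf("PCA: PC1 %.1f%%, broken stick retains %d axes",
              results$niche$pca$percent_variance[1],
              results$niche$pca$n_retained)
    },
    if (!is.null(results$essim)) {
      sprintf("ES-sim: rho = %.3f, p = %.3f", results$essim$rho,
              results$essim$p_value)
    })
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(list(results = results, manifest = manifest))
}
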