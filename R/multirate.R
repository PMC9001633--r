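# Multi-rate ("brownie") Brownian motion over painted trees, compared to
# single-rate BM by AICc with Akaike-weight model averaging across maps.

# per-edge time in each state, edges in tree$edge row order
edge_state_times_ <- function(painted) {
  states <- sort(unique(unlist(lapply(painted$edge_maps, names))))
  m <- matrix(0, length(painted$edge_maps), length(states),
              dimnames = list(NULL, states))
  for (e in seq_along(painted$edge_maps)) {
    seg <- painted$edge_maps[[e]]
    agg <- tapply(unname(seg), names(seg), sum)
    m[e, names(agg)] <- agg
  }
  m
}

# ML multi-rate fit for one painting; rate of the first state is profiled
# analytically (overall scale), remaining log-ratios numerically.
fit_one_painting_ <- function(painted, x) {
  tree <- painted$tree
  st <- edge_state_times_(painted)
  states <- colnames(st)
  k <- length(states)
  tot <- colSums(st)
  if (any(tot == 0)) {
    stop("state(s) with zero total branch time: ",
         paste(states[tot == 0], collapse = ", "), call. = FALSE)
  }
  rescaled <- function(log_ratio) {
    rates <- exp(c(0, log_ratio))
    tr <- tree
    tr$edge.length <- as.numeric(st %*% rates)
    tr
  }
  if (k == 1) {
    fit <- bm_profile_loglik_(tree, x)
    return(list(states = states, sigma2 = stats::setNames(fit$sigma2, states),
                z0 = fit$z0, loglik = fit$loglik, k_par = 2))
  }
  obj <- function(log_ratio) {
    -bm_profile_loglik_(rescaled(log_ratio), x)$loglik
  }
  opt <- if (k == 2) {
    stats::optim(0, obj, method = "Brent", lower = -15, upper = 15)
  } else {
    stats::optim(rep(0, k - 1), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  }
  fit <- bm_profile_loglik_(rescaled(opt$par), x)
  rates <- fit$sigma2 * exp(c(0, opt$par))
  list(states = states, sigma2 = stats::setNames(rates, states),
       z0 = fit$z0, loglik = fit$loglik, k_par = k + 1)
}

#' Multi-rate Brownian motion over stochastic maps
#'
#' Fits, for each painted tree, (i) the single-rate BM model and (ii) a
#' model with one Brownian rate per mapped state, the tip covariance being
#' \eqn{C_{ij} = \sum_s \sigma^2_s \times} (shared path time spent in state
#' s). The root state is profiled by GLS and the overall rate scale
#' analytically, so only the \eqn{k - 1} rate ratios are searched
#' numerically. Models are compared by AICc (k = 2 vs k = 1 + number of
#' states, n = number of tips) and Akaike weights; per-state rates are
#' model-averaged and, when a list of maps is supplied, averaged across
#' maps — the standard way to propagate stochastic-mapping uncertainty.
#'
#' @param painted A `painted_tree` or a list of them (e.g. from
#'   [stochastic_map()]).
#' @param trait Per-tip continuous values (named vector or data frame).
#' @return A `multirate_bm` object: `per_map` tibble (one row per map:
#'   loglik and AICc of both models, weights, per-state ML rates),
#'   `rates` tibble of model-averaged per-state rates (averaged over maps),
#'   `mean_weight_multi`, `single` (the shared single-rate [bm_fit()]).
#' @export
multirate_bm <- function(painted, trait) {
  if (inherits(painted, "painted_tree")) painted <- list(painted)
  stopifnot(length(painted) >= 1,
            all(vapply(painted, inherits, logical(1), "painted_tree")))
  tree <- painted[[1]]$tree
  x <- as_trait_vector(trait, tree)
  n <- ape::Ntip(tree)
  single <- suppressWarnings(bm_fit(tree, x, check_ultrametric = FALSE))

  per_map <- purrr::imap_dfr(painted, function(pt, m) {
    fit <- fit_one_painting_(pt, x)
    aicc_multi <- aicc_(fit$loglik, k = fit$k_par, n = n)
    d <- c(single = single$aicc, multi = aicc_multi)
    w <- exp(-(d - min(d)) / 2)
    w <- w / sum(w)
    tibble::tibble(
      map = m,
      loglik_single = single$loglik, aicc_single = single$aicc,
      loglik_multi = fit$loglik, aicc_multi = aicc_multi,
      weight_single = w[["single"]], weight_multi = w[["multi"]],
      rates = list(fit$sigma2)
    )
  })

  states <- names(per_map$rates[[1]])
  averaged <- purrr::pmap(per_map, function(weight_single, weight_multi,
                                            rates, ...) {
    weight_single * single$sigma2 + weight_multi * rates
  })
  rates <- tibble::tibble(
    state = states,
    sigma2_ml = colMeans(do.call(rbind, per_map$rates)),
    sigma2_averaged = colMeans(do.call(rbind, averaged))
  )
  structure(list(per_map = per_map, rates = rates,
                 mean_weight_multi = mean(per_map$weight_multi),
                 single = single, n_maps = length(painted), n_tips = n),
            class = "multirate_bm")
}

#' @export
print.multirate_bm <- function(x, ...) {
  cat(sprintf("<multirate_bm> %d map(s), %d tips\n", x$n_maps, x$n_tips))
  cat(sprintf("  single-rate sigma2 = %.6g (AICc %.3f)\n",
              x$single$sigma2, x$single$aicc))
  cat(sprintf("  mean Akaike weight of multi-rate model: %.3f\n",
              x$mean_weight_multi))
  print(x$rates)
  invisible(x)
}
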