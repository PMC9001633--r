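# Brownian-motion niche evolution: pruning likelihood, ML fit, ancestral
# states, traitgrams, and disparity-through-time with resampled nulls.

# Felsenstein pruning pass for BM with unit rate. Returns the contrast
# quadratic form Q = (x - z0)' C^{-1} (x - z0) evaluated at the GLS root,
# the log-determinant of C, and the GLS/ML root state. Works on any rooted
# binary tree with branch lengths (polytomies are folded pairwise, which is
# equivalent to zero-length resolution).
bm_prune_ <- function(tree, x) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  mu <- numeric(n_all)
  vtot <- numeric(n_all) # variance carried up through each node's edge
  mu[seq_len(n_tip)] <- x
  first <- rep(TRUE, n_all)
  Q <- 0
  logdet <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    vc <- vtot[ch] + po$edge.length[e]
    if (first[p]) {
      mu[p] <- mu[ch]
      vtot[p] <- vc
      first[p] <- FALSE
    } else {
      w <- vtot[p] + vc
      Q <- Q + (mu[p] - mu[ch])^2 / w
      logdet <- logdet + log(w)
      mu[p] <- (mu[p] * vc + mu[ch] * vtot[p]) / w
      vtot[p] <- vtot[p] * vc / w
    }
  }
  root <- n_tip + 1L
  logdet <- logdet + log(vtot[root])
  list(Q = Q, logdet = logdet, z0 = mu[root])
}

# Profile log-likelihood pieces for a tree whose branch lengths already
# absorb relative rates: ML overall scale c = Q/n, and
# loglik = -n/2 log(2*pi*Q/n) - logdet/2 - n/2.
bm_profile_loglik_ <- function(tree, x) {
  pr <- bm_prune_(tree, x)
  n <- ape::Ntip(tree)
  if (pr$Q <= 0) return(list(loglik = NA_real_, sigma2 = 0, z0 = pr$z0))
  list(loglik = -n / 2 * log(2 * pi * pr$Q / n) - pr$logdet / 2 - n / 2,
       sigma2 = pr$Q / n, z0 = pr$z0)
}

aicc_ <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit single-rate Brownian motion to a continuous trait
#'
#' Maximum-likelihood estimate of the Brownian rate \eqn{\sigma^2}
#' (trait^2 per Myr) and root state \eqn{z_0} under the multivariate normal
#' model with covariance \eqn{\sigma^2 C}, where \eqn{C_{ij}} is the shared
#' root-to-tip path length. Computed by Felsenstein's pruning algorithm in
#' O(n); \eqn{\hat\sigma^2_{ML} = Q/n}.
#'
#' @param tree An ultrametric `phylo` object.
#' @param trait Per-tip values: named numeric vector or `species`/value
#'   data frame.
#' @param check_ultrametric Error on non-ultrametric input (default TRUE).
#' @return A `bm_fit` object: `sigma2`, `z0`, `loglik`, `aicc` (k = 2),
#'   `n_tips`.
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' fit <- bm_fit(tr, c(A = 0, B = 2))
#' fit$sigma2 # 1
#' @export
bm_fit <- function(tree, trait, check_ultrametric = TRUE) {
  tree <- validate_tree(tree)
  if (check_ultrametric && !is_ultrametric(tree)) {
    stop("bm_fit() expects an ultrametric tree.", call. = FALSE)
  }
  x <- as_trait_vector(trait, tree)
  n <- ape::Ntip(tree)
  if (stats::sd(x) == 0) {
    warning("trait has zero variance; sigma2 = 0.", call. = FALSE)
    fit <- list(sigma2 = 0, z0 = unname(x[1]), loglik = NA_real_)
  } else {
    fit <- bm_profile_loglik_(tree, x)
  }
  structure(list(sigma2 = fit$sigma2, z0 = fit$z0, loglik = fit$loglik,
                 aicc = aicc_(fit$loglik, k = 2, n = n), n_tips = n),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("<bm_fit> sigma2 = %.6g, z0 = %.6g, loglik = %.4f, AICc = %.4f (n = %d)\n",
              x$sigma2, x$z0, x$loglik, x$aicc, x$n_tips))
  invisible(x)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS/ML reconstruction: internal node states are the conditional means
#' \eqn{\hat z = z_0 + C_{AT} C_{TT}^{-1} (x - z_0)} with \eqn{z_0} the ML
#' root state, so the root reconstruction equals [bm_fit()]'s `z0`.
#'
#' @inheritParams bm_fit
#' @return A tibble `node` (ape numbering, internal nodes), `state`.
#' @export
ancestral_states_bm <- function(tree, trait, check_ultrametric = TRUE) {
  tree <- validate_tree(tree)
  if (check_ultrametric && !is_ultrametric(tree)) {
    stop("ancestral_states_bm() expects an ultrametric tree.", call. = FALSE)
  }
  x <- as_trait_vector(trait, tree)
  n_tip <- ape::Ntip(tree)
  nodes <- n_tip + seq_len(tree$Nnode)
  if (stats::sd(x) == 0) {
    return(tibble::tibble(node = nodes, state = unname(x[1])))
  }
  z0 <- bm_prune_(tree, x)$z0
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  c_tt <- matrix(depth[mr[seq_len(n_tip), seq_len(n_tip)]], n_tip, n_tip)
  c_at <- matrix(depth[mr[nodes, seq_len(n_tip), drop = FALSE]],
                 length(nodes), n_tip)
  state <- as.numeric(z0 + c_at %*% solve(c_tt, x - z0))
  tibble::tibble(node = nodes, state = state)
}

#' Traitgram (phenogram) segments
#'
#' Projects the tree into (time, trait) space: tips sit at their observed
#' values, internal nodes at their ML ancestral states, and each edge
#' becomes a segment from parent to child.
#'
#' @inheritParams bm_fit
#' @return A tibble of segments: `parent`, `child`, `time_parent`,
#'   `value_parent`, `time_child`, `value_child`, `label` (tip label or
#'   `NA`). Plot with [plot_traitgram()].
#' @export
traitgram <- function(tree, trait, check_ultrametric = TRUE) {
  tree <- validate_tree(tree)
  x <- as_trait_vector(trait, tree)
  n_tip <- ape::Ntip(tree)
  anc <- ancestral_states_bm(tree, trait, check_ultrametric = check_ultrametric)
  value <- c(unname(x), anc$state)
  depth <- ape::node.depth.edgelength(tree)
  tibble::tibble(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    time_parent = depth[tree$edge[, 1]],
    value_parent = value[tree$edge[, 1]],
    time_child = depth[tree$edge[, 2]],
    value_child = value[tree$edge[, 2]],
    label = ifelse(tree$edge[, 2] <= n_tip,
                   tree$tip.label[tree$edge[, 2]], NA_character_)
  )
}

# --- disparity through time ------------------------------------------------

# disparity = mean squared pairwise Euclidean distance; for a trait matrix
# (tips x axes) restricted to `idx`, equals sum over axes of 2 * var / 1
# via sum_{i<j} d^2 = n * SS, mean over n(n-1)/2 pairs.
disparity_ <- function(mat, idx) {
  m <- length(idx)
  if (m < 2) return(0)
  sub <- mat[idx, , drop = FALSE]
  ss <- sum(apply(sub, 2, function(v) sum((v - mean(v))^2)))
  2 * ss / (m - 1)
}

# Disparity for many simulated trait sets at once: `arr` is tips x nsim
# (single axis) — returns nsim disparities for the same tip subset.
disparity_cols_ <- function(arr, idx) {
  m <- length(idx)
  if (m < 2) return(rep(0, ncol(arr)))
  sub <- arr[idx, , drop = FALSE]
  ss <- colSums(sub^2) - colSums(sub)^2 / m
  2 * ss / (m - 1)
}

# Shared scaffolding: node times and the lineages (child-end nodes of edges)
# crossing each time.
dtt_scaffold_ <- function(tree) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  crown <- max(depth[seq_len(n_tip)])
  node_times <- sort(unique(depth[(n_tip + 1):(n_tip + tree$Nnode)]))
  sets <- node_tip_sets_(tree)
  lineages <- lapply(node_times, function(t) {
    sel <- depth[tree$edge[, 1]] <= t & depth[tree$edge[, 2]] > t
    tree$edge[sel, 2]
  })
  list(times = node_times, rel_times = node_times / crown,
       lineages = lineages, sets = sets, crown = crown, n_tip = n_tip)
}

# Observed (or one simulated) relative-disparity curve on the scaffold.
dtt_curve_ <- function(scaf, mat) {
  total <- disparity_(mat, seq_len(scaf$n_tip))
  if (total == 0) return(rep(0, length(scaf$times) + 1))
  vals <- vapply(seq_along(scaf$times), function(k) {
    if (k == 1) return(1) # root: the whole clade relative to itself
    mean(vapply(scaf$lineages[[k]],
                function(nd) disparity_(mat, scaf$sets[[nd]]), numeric(1))) / total
  }, numeric(1))
  c(vals, 0) # present-day: every lineage is a single tip
}

# Vectorized curves for an n_tip x nsim matrix of single-axis simulations.
dtt_curves_sim_ <- function(scaf, sims) {
  total <- disparity_cols_(sims, seq_len(scaf$n_tip))
  total[total == 0] <- Inf
  out <- matrix(0, length(scaf$times) + 1, ncol(sims))
  out[1, ] <- 1
  for (k in seq_along(scaf$times)[-1]) {
    nds <- scaf$lineages[[k]]
    acc <- matrix(0, length(nds), ncol(sims))
    for (j in seq_along(nds)) {
      acc[j, ] <- disparity_cols_(sims, scaf$sets[[nds[j]]])
    }
    out[k, ] <- colMeans(acc) / total
  }
  out
}

#' Disparity through time with a Brownian-motion null envelope
#'
#' Tracks how trait disparity (mean squared pairwise Euclidean distance) is
#' partitioned among subclades as time advances: at each branching time the
#' mean relative disparity of the lineages alive at that moment is recorded
#' (1 at the root by construction, 0 at the present). The null expectation
#' resamples the curve from Brownian-motion simulations at the ML rate of
#' each axis; the envelope is the pointwise 2.5/97.5 percentile band and
#' MDI is the signed area (trapezoidal, in relative time) between the
#' observed curve and the null median — positive when disparity stays
#' within subclades later than Brownian motion expects.
#'
#' @param tree An ultrametric `phylo` with >= 4 tips.
#' @param traits One axis (named vector / species-value data frame) or a
#'   data frame with `species` plus several numeric axis columns, analysed
#'   jointly as a Euclidean trait space.
#' @param n_null Number of null simulations (>= 99; default 999).
#' @param seed Integer seed for the null, or `NULL`.
#' @param level Envelope coverage (default 0.95).
#' @return A `dtt_result`: `curve` tibble (`rel_time`, `observed`,
#'   `null_median`, `lower`, `upper`), `mdi`, `n_null`, `sigma2` per axis.
#' @export
dtt <- function(tree, traits, n_null = 999, seed = NULL, level = 0.95) {
  tree <- validate_tree(tree)
  if (!is_ultrametric(tree)) stop("dtt() expects an ultrametric tree.", call. = FALSE)
  if (ape::Ntip(tree) < 4) stop("dtt() needs at least 4 tips.", call. = FALSE)
  if (n_null < 99) stop("n_null must be at least 99.", call. = FALSE)
  mat <- traits_matrix_(traits, tree)
  scaf <- dtt_scaffold_(tree)
  observed <- dtt_curve_(scaf, mat)

  sigma2 <- apply(mat, 2, function(x) {
    f <- suppressWarnings(bm_fit(tree, stats::setNames(x, tree$tip.label),
                                 check_ultrametric = FALSE))
    f$sigma2
  })
  null_curves <- with_seed_(seed, {
    per_axis <- lapply(seq_len(ncol(mat)), function(a) {
      bm_sim_matrix_(tree, sigma2[a], n_sim = n_null)
    })
    # joint-axis disparity: totals and subclade disparities add over axes,
    # but the ratio does not decompose, so accumulate numerators per axis.
    if (length(per_axis) == 1) {
      dtt_curves_sim_(scaf, per_axis[[1]])
    } else {
      # build combined curves by summing disparities across axes
      totals <- Reduce(`+`, lapply(per_axis, function(s)
        disparity_cols_(s, seq_len(scaf$n_tip))))
      totals[totals == 0] <- Inf
      out <- matrix(0, length(scaf$times) + 1, n_null)
      out[1, ] <- 1
      for (k in seq_along(scaf$times)[-1]) {
        nds <- scaf$lineages[[k]]
        acc <- matrix(0, length(nds), n_null)
        for (j in seq_along(nds)) {
          acc[j, ] <- Reduce(`+`, lapply(per_axis, function(s)
            disparity_cols_(s, scaf$sets[[nds[j]]])))
        }
        out[k, ] <- colMeans(acc) / totals
      }
      out
    }
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(null_curves, 1, stats::quantile, probs = c(probs[1], 0.5, probs[2]))
  rel_time <- c(scaf$rel_times, 1)
  mdi <- sum(diff(rel_time) *
               (utils::head(observed - qs[2, ], -1) +
                utils::tail(observed - qs[2, ], -1)) / 2)
  curve <- tibble::tibble(rel_time = rel_time, observed = observed,
                          null_median = qs[2, ], lower = qs[1, ],
                          upper = qs[3, ])
  structure(list(curve = curve, mdi = mdi, n_null = n_null, level = level,
                 sigma2 = sigma2, seed = seed),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf("<dtt_result> %d time points, MDI = %.4f (%d null reps, %g%% envelope)\n",
              nrow(x$curve), x$mdi, x$n_null, 100 * x$level))
  invisible(x)
}

# Coerce trait input (vector, species/value df, or species + axis columns)
# to a tips x axes matrix in tip order.
traits_matrix_ <- function(traits, tree) {
  if (is.data.frame(traits) && sum(vapply(traits, is.numeric, logical(1))) > 1) {
    if (!"species" %in% names(traits)) {
      stop("trait data frame must have a `species` column.", call. = FALSE)
    }
    num <- traits[vapply(traits, is.numeric, logical(1))]
    mat <- as.matrix(num)
    rownames(mat) <- traits$species
    missing <- setdiff(tree$tip.label, rownames(mat))
    if (length(missing) > 0) {
      stop("traits missing for tips: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    mat[tree$tip.label, , drop = FALSE]
  } else {
    matrix(as_trait_vector(traits, tree), ncol = 1,
           dimnames = list(tree$tip.label, "trait"))
  }
}
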