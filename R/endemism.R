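# Phylogenetic endemism, curveball randomization, and CANAPE: categorical
# analysis of neo- and paleo-endemism.

#' Per-cell phylogenetic endemism
#'
#' PE partitions the tree's branch lengths among grid cells by range size:
#' each branch contributes `length / (number of cells holding a descendant
#' tip)` to every cell in its range. Summed over cells, PE recovers the
#' tree's total branch length exactly, so range-restricted branches
#' concentrate their full length in few cells.
#'
#' @param pam A `pam` object; every tree tip must occupy at least one cell.
#' @param tree A `phylo` object covering exactly the PAM's species.
#' @return A tibble `cell`, `row`, `col`, `lon`, `lat`, `sr`, `pe` over all
#'   cells (`pe = 0` for empty cells).
#' @export
phylogenetic_endemism <- function(pam, tree) {
  stopifnot(inherits(pam, "divscape_pam"))
  tree <- validate_tree(tree)
  orphan <- setdiff(tree$tip.label, pam$species)
  empty <- pam$species[colSums(pam$incidence) == 0]
  if (length(orphan) > 0 || length(empty) > 0) {
    stop("species with zero occupied cells: ",
         paste(c(orphan, empty), collapse = ", "), call. = FALSE)
  }
  m <- branch_cell_incidence_(pam, tree)
  out <- cell_richness(pam)
  out$pe <- as.numeric(m %*% (tree$edge.length / colSums(m)))
  out
}

#' Equal-branch-length comparison tree
#'
#' Returns the same topology with every branch set to the mean branch
#' length, preserving total tree length. PE on this tree isolates the
#' range-size component of endemism; the ratio of observed to comparison
#' PE (RPE) then separates endemism carried by unusually long branches
#' (paleo) from endemism carried by unusually short ones (neo).
#'
#' @param tree A `phylo` object.
#' @return A `phylo` object with equalized branch lengths.
#' @export
comparison_tree <- function(tree) {
  tree <- validate_tree(tree)
  tree$edge.length <- rep(mean(tree$edge.length), length(tree$edge.length))
  tree
}

#' Curveball randomization of a presence-absence matrix
#'
#' Draws from the fixed-row-sum / fixed-column-sum null model by applying
#' `n_swaps` curveball trades (via [vegan::nullmodel()]), preserving every
#' species' prevalence and every cell's richness.
#'
#' @param pam A `pam` object with at least 2 occupied dimensions.
#' @param n_swaps Number of curveball trades applied from the observed
#'   matrix.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A randomized `pam` on the same grid and species.
#' @export
curveball_randomize <- function(pam, n_swaps = 1000, seed = NULL) {
  stopifnot(inherits(pam, "divscape_pam"))
  if (nrow(pam$incidence) < 2 || ncol(pam$incidence) < 2) {
    stop("PAM must have at least 2 rows and 2 columns.", call. = FALSE)
  }
  sims <- curveball_ensemble_(pam, n_reps = 1, n_swaps = n_swaps, seed = seed)
  new_pam(sims[, , 1], pam$grid)
}

# n_reps draws from the curveball null as a cells x species x reps array.
# Samples are taken along a single chain thinned by n_swaps trades.
curveball_ensemble_ <- function(pam, n_reps, n_swaps, seed) {
  nm <- vegan::nullmodel(pam$incidence, "curveball")
  sims <- stats::simulate(nm, nsim = n_reps, seed = seed,
                          burnin = n_swaps, thin = n_swaps)
  dimnames(sims) <- list(NULL, colnames(pam$incidence), NULL)
  storage.mode(sims) <- "integer"
  sims
}

#' CANAPE: categorical analysis of neo- and paleo-endemism
#'
#' Computes per-cell PE on the observed tree and on the equal-branch-length
#' comparison tree, builds their null distributions from `n_reps` curveball
#' randomizations of the PAM, and classifies each occupied cell:
#'
#' * a cell is *significant* when either PE exceeds its one-tailed
#'   `(1 - alpha)` null quantile;
#' * among significant cells, RPE (observed / comparison PE) in the upper
#'   `alpha/2` tail marks *paleo*-endemism (old, long-branch lineages), the
#'   lower tail *neo*-endemism (recent short-branch radiations), otherwise
#'   *mixed*;
#' * cells whose two PE values both clear the `(1 - super_alpha)` quantile
#'   additionally carry the *super* flag (`endemism_type` reports mixed
#'   super cells as `"super"`).
#'
#' P-values are rank-based with the +1 correction,
#' `p = (1 + #\{null >= obs\}) / (n_reps + 1)`.
#'
#' @inheritParams phylogenetic_endemism
#' @param n_reps Number of null randomizations (>= 99).
#' @param n_swaps Curveball trades between null samples.
#' @param seed Integer seed; identical seed and inputs give identical
#'   categories.
#' @param alpha Significance level for the PE tests (default 0.05).
#' @param super_alpha Level for the super-endemism flag (default 0.01).
#' @return A `canape_result` tibble over occupied cells: coordinates,
#'   `pe_obs`, `pe_alt`, `rpe`, `p_pe_obs`, `p_pe_alt`, `p_rpe_upper`,
#'   `p_rpe_lower`, `significant`, `category`, `super`, `endemism_type`.
#' @export
canape_classify <- function(pam, tree, n_reps = 999, n_swaps = 1000,
                            seed = NULL, alpha = 0.05, super_alpha = 0.01) {
  stopifnot(inherits(pam, "divscape_pam"))
  tree <- validate_tree(tree)
  if (n_reps < 99) stop("n_reps must be at least 99.", call. = FALSE)
  if ((n_reps + 1) * alpha / 2 < 1) {
    stop("n_reps too small to resolve alpha = ", alpha, call. = FALSE)
  }
  orphan <- setdiff(tree$tip.label, pam$species)
  empty <- pam$species[colSums(pam$incidence) == 0]
  if (length(orphan) > 0 || length(empty) > 0) {
    stop("species with zero occupied cells: ",
         paste(c(orphan, empty), collapse = ", "), call. = FALSE)
  }
  alt <- comparison_tree(tree)
  len_obs <- tree$edge.length
  len_alt <- alt$edge.length

  tip_inc <- edge_tip_incidence_(tree) # identical topology for both trees
  pe_of <- function(incidence) {
    p <- incidence[, tree$tip.label, drop = FALSE]
    m <- (p %*% t(tip_inc)) > 0
    storage.mode(m) <- "double"
    rng <- colSums(m)
    cbind(obs = as.numeric(m %*% (len_obs / rng)),
          alt = as.numeric(m %*% (len_alt / rng)))
  }

  obs <- pe_of(pam$incidence)
  occupied <- which(rowSums(pam$incidence) > 0)
  sims <- curveball_ensemble_(pam, n_reps = n_reps, n_swaps = n_swaps,
                              seed = seed)
  null_obs <- matrix(0, length(occupied), n_reps)
  null_alt <- matrix(0, length(occupied), n_reps)
  null_rpe <- matrix(0, length(occupied), n_reps)
  for (r in seq_len(n_reps)) {
    pe_r <- pe_of(sims[, , r])
    occ_r <- rowSums(sims[, , r]) > 0
    # a cell occupied in the observed PAM is occupied in every null draw
    # (row sums are preserved), so indexing by `occupied` is safe
    null_obs[, r] <- pe_r[occupied, "obs"]
    null_alt[, r] <- pe_r[occupied, "alt"]
    null_rpe[, r] <- ifelse(occ_r[occupied],
                            pe_r[occupied, "obs"] / pe_r[occupied, "alt"],
                            NA_real_)
  }

  rank_p_upper <- function(obs_v, null_m) {
    (1 + rowSums(null_m >= obs_v)) / (n_reps + 1)
  }
  rank_p_lower <- function(obs_v, null_m) {
    (1 + rowSums(null_m <= obs_v)) / (n_reps + 1)
  }

  pe_obs <- obs[occupied, "obs"]
  pe_alt <- obs[occupied, "alt"]
  rpe <- pe_obs / pe_alt
  p_obs <- rank_p_upper(pe_obs, null_obs)
  p_alt <- rank_p_upper(pe_alt, null_alt)
  p_rpe_up <- rank_p_upper(rpe, null_rpe)
  p_rpe_lo <- rank_p_lower(rpe, null_rpe)

  significant <- p_obs <= alpha | p_alt <= alpha
  category <- rep("not_significant", length(occupied))
  category[significant & p_rpe_up <= alpha / 2] <- "paleo"
  category[significant & p_rpe_lo <= alpha / 2] <- "neo"
  category[significant & category == "not_significant"] <- "mixed"
  super <- significant & p_obs <= super_alpha & p_alt <= super_alpha
  endemism_type <- ifelse(super & category == "mixed", "super", category)

  out <- grid_cells_(pam$grid)[occupied, ]
  out <- dplyr::mutate(out,
    sr = as.integer(rowSums(pam$incidence)[occupied]),
    pe_obs = pe_obs, pe_alt = pe_alt, rpe = rpe,
    p_pe_obs = p_obs, p_pe_alt = p_alt,
    p_rpe_upper = p_rpe_up, p_rpe_lower = p_rpe_lo,
    significant = significant, category = category, super = super,
    endemism_type = endemism_type)
  class(out) <- c("canape_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "super_alpha") <- super_alpha
  attr(out, "n_reps") <- n_reps
  attr(out, "n_swaps") <- n_swaps
  attr(out, "seed") <- seed
  out
}
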