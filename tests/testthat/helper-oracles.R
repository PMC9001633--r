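# Independent oracles and small generators used across the suite. These
# deliberately avoid the package's own computational paths.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# Random ultrametric tree via coalescent times (independent of the
# package's birth-death simulator).
random_ultrametric_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Brute-force equal-splits: enumerate the root-to-tip edge list per tip by
# walking the edge matrix directly, then apply the halving weights.
oracle_equal_splits <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  sapply(seq_len(n), function(tip) {
    node <- tip
    lens <- numeric(0)
    while (node != root) {
      row <- which(tree$edge[, 2] == node)
      lens <- c(lens, tree$edge.length[row])
      node <- tree$edge[row, 1]
    }
    sum(lens * 0.5^(seq_along(lens) - 1))
  })
}

# Dense multivariate-normal BM log-likelihood at the ML estimates, using
# the explicit covariance matrix C = vcv(tree): the "linear algebra by the
# book" reference for the pruning implementation.
oracle_bm_loglik <- function(tree, x, scaled_edge_lengths = NULL) {
  tr <- tree
  if (!is.null(scaled_edge_lengths)) tr$edge.length <- scaled_edge_lengths
  C <- ape::vcv(tr)
  x <- x[rownames(C)]
  n <- length(x)
  one <- rep(1, n)
  Ci <- solve(C)
  z0 <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  Q <- as.numeric(t(x - z0) %*% Ci %*% (x - z0))
  s2 <- Q / n
  ld <- determinant(C, logarithm = TRUE)$modulus
  list(loglik = -n / 2 * log(2 * pi * s2) - as.numeric(ld) / 2 - n / 2,
       sigma2 = s2, z0 = z0)
}

# Dense GLS ancestral state for one internal node.
oracle_ancestral_state <- function(tree, x, node) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  one <- rep(1, n)
  Ci <- solve(C)
  z0 <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  cav <- depth[mr[node, match(rownames(C), tree$tip.label)]]
  as.numeric(z0 + cav %*% Ci %*% (x - z0))
}

# Fitch parsimony score (minimum number of state changes).
oracle_fitch <- function(tree, states) {
  n <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- states[tree$tip.label[i]]
  score <- 0
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (p in unique(po$edge[, 1])) {
    acc <- NULL
    for (ch in kids[[as.character(p)]]) {
      s <- sets[[ch]]
      if (is.null(acc)) {
        acc <- s
      } else if (length(intersect(acc, s)) > 0) {
        acc <- intersect(acc, s)
      } else {
        acc <- union(acc, s)
        score <- score + 1
      }
    }
    sets[[p]] <- acc
  }
  score
}

# Brute-force Mk(ER) log-likelihood by explicit matrix exponentials and
# full state-combination enumeration over internal nodes (tiny trees only).
oracle_mk_loglik <- function(tree, states_idx, k, q) {
  n <- ape::Ntip(tree)
  Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
  P <- lapply(tree$edge.length, function(t) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  })
  internals <- n + seq_len(tree$Nnode)
  combos <- expand.grid(rep(list(seq_len(k)), length(internals)))
  tot <- 0
  for (r in seq_len(nrow(combos))) {
    assign_state <- c(states_idx, as.integer(combos[r, ]))
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[e]][assign_state[tree$edge[e, 1]],
                          assign_state[tree$edge[e, 2]]]
    }
    tot <- tot + lik
  }
  log(tot)
}

# Random PAM guaranteed to have every species somewhere and >= 2 x 2 shape.
random_pam <- function(n_cells_side, n_species, fill = 0.15, seed = NULL) {
  g <- grid_spec(0, 0, n_cells_side, n_cells_side, 1)
  gen <- function() {
    m <- matrix(rbinom(n_cells_side^2 * n_species, 1, fill),
                n_cells_side^2, n_species)
    # guarantee occupancy per species and at least one multi-cell row
    for (j in which(colSums(m) == 0)) m[sample.int(nrow(m), 1), j] <- 1L
    m
  }
  m <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  colnames(m) <- paste0("t", seq_len(n_species))
  divscape:::new_pam(m, g)
}

# PAM aligned to a tree's tips (species names t1..tn).
random_pam_for_tree <- function(tree, n_cells_side = 5, fill = 0.2,
                                seed = NULL) {
  p <- random_pam(n_cells_side, ape::Ntip(tree), fill = fill, seed = seed)
  stopifnot(identical(colnames(p$incidence), tree$tip.label))
  p
}
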