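# Equal-rates Mk model for discrete traits and stochastic character
# mapping (sampling full branch histories consistent with tip states).

# ER transition probability matrix: P(t) = 1/k + (I - 1/k) exp(-k q t).
mk_pmat_ <- function(k, q, t) {
  e <- exp(-k * q * t)
  matrix((1 - e) / k, k, k) + diag(e, k)
}

# Scaled pruning pass; returns per-node conditional likelihoods (rows sum
# rescaled) and the total log-likelihood under a uniform root prior.
mk_prune_ <- function(tree, state_idx, k, q) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, n_all, k)
  L[seq_len(n_tip), ] <- 0
  L[cbind(seq_len(n_tip), state_idx)] <- 1
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    pm <- mk_pmat_(k, q, po$edge.length[e])
    msg <- as.numeric(pm %*% L[ch, ])
    L[p, ] <- L[p, ] * msg
    sc <- sum(L[p, ])
    if (sc > 0 && (sc < 1e-100 || sc > 1e100)) {
      L[p, ] <- L[p, ] / sc
      logscale <- logscale + log(sc)
    }
  }
  root <- n_tip + 1L
  list(L = L, loglik = log(mean(L[root, ])) + logscale)
}

#' Fit an equal-rates Mk model to a discrete character
#'
#' Maximum-likelihood transition rate under the continuous-time Markov
#' model with all transitions at rate `q` (ER), computed by the pruning
#' algorithm with a uniform root prior and a deterministic bounded 1-D
#' search.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param states Per-tip states: named character/factor vector or a
#'   `species`/state data frame. Factor levels define the state space; with
#'   a plain vector the observed values do.
#' @param model Only `"ER"` is implemented.
#' @return An `mk_fit` object: `q` (transitions per Myr per ordered pair),
#'   `k`, `states` (levels), `loglik`, `model`, `root_prior`.
#' @export
mk_fit <- function(tree, states, model = "ER") {
  tree <- validate_tree(tree)
  model <- match.arg(model, "ER")
  s <- as_state_vector(states, tree)
  lev <- attr(s, "levels")
  k <- length(lev)
  if (k < 2) stop("need at least 2 states in the state space.", call. = FALSE)
  idx <- match(s, lev)
  n_obs <- length(unique(idx))
  crown <- max(ape::node.depth.edgelength(tree))
  if (n_obs == 1L) {
    warning("single observed state; ML rate is 0.", call. = FALSE)
    fit <- list(q = 0, loglik = log(1 / k))
  } else {
    f <- function(q) mk_prune_(tree, idx, k, q)$loglik
    # the profile can flatten toward the high-rate plateau, which defeats a
    # plain golden-section search: bracket the optimum on a log grid first
    grid_q <- exp(seq(log(1e-4 / crown), log(500 / crown), length.out = 60))
    ll <- vapply(grid_q, f, numeric(1))
    best <- which.max(ll)
    lo <- grid_q[max(1, best - 1)]
    hi <- grid_q[min(length(grid_q), best + 1)]
    opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    fit <- list(q = opt$maximum, loglik = opt$objective)
  }
  structure(list(q = fit$q, k = k, states = lev, loglik = fit$loglik,
                 model = model, root_prior = "uniform",
                 n_tips = ape::Ntip(tree)),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("<mk_fit> ER, k = %d states (%s), q = %.6g, loglik = %.4f\n",
              x$k, paste(x$states, collapse = "/"), x$q, x$loglik))
  invisible(x)
}

# ---- painted trees --------------------------------------------------------

# A painted tree is a phylo plus, per edge (tree$edge row order), an ordered
# run-length encoding of states along the branch, root side first:
# a named numeric vector of durations, names = states.
new_painted_tree <- function(tree, edge_maps, tip_states, node_states) {
  structure(list(tree = tree, edge_maps = edge_maps,
                 tip_states = tip_states, node_states = node_states),
            class = "painted_tree")
}

#' @export
print.painted_tree <- function(x, ...) {
  cat(sprintf("<painted_tree> %d tips, states {%s}, %d state changes\n",
              ape::Ntip(x$tree),
              paste(sort(unique(unlist(lapply(x$edge_maps, names)))),
                    collapse = ", "),
              n_state_changes(x)))
  invisible(x)
}

#' Number of state changes on a painted tree
#'
#' @param painted A `painted_tree`.
#' @return Integer count of state transitions along all branches (changes
#'   at nodes are impossible by construction: a branch starts in its
#'   parent-node state).
#' @export
n_state_changes <- function(painted) {
  stopifnot(inherits(painted, "painted_tree"))
  sum(vapply(painted$edge_maps, function(m) length(m) - 1L, integer(1)))
}

#' Time spent in each state on a painted tree
#'
#' @param painted A `painted_tree`.
#' @return A tibble `state`, `time` (Myr summed over all branches).
#' @export
state_times <- function(painted) {
  stopifnot(inherits(painted, "painted_tree"))
  all <- unlist(painted$edge_maps)
  tibble::tibble(state = names(all), time = unname(all)) |>
    dplyr::summarise(time = sum(.data$time), .by = "state") |>
    dplyr::arrange(.data$state)
}

# Serialize a painted tree in a simmap-style annotated Newick dialect:
# branch annotations {state,dur:state,dur:...} root side first.
#' Write a painted tree as annotated Newick
#'
#' Branch state histories are embedded as comment blocks
#' `[&map={state,duration:...}]` (root-side segment first), a plain-text
#' dialect that round-trips within the package.
#'
#' @param painted A `painted_tree`.
#' @return A single annotated-Newick string.
#' @export
write_painted_newick <- function(painted) {
  tree <- painted$tree
  idx <- edge_index_(tree)
  lab <- function(node) {
    if (node <= ape::Ntip(tree)) tree$tip.label[node] else ""
  }
  build <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    core <- if (length(kids) == 0) lab(node) else {
      paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")")
    }
    if (node == idx$root) return(paste0(core, ";"))
    e <- idx$edge_of[node]
    m <- painted$edge_maps[[e]]
    ann <- paste(sprintf("%s,%.10g", names(m), unname(m)), collapse = ":")
    paste0(core, "[&map={", ann, "}]:",
           format(tree$edge.length[e], digits = 12))
  }
  build(idx$root)
}

# ---- stochastic mapping ---------------------------------------------------

# sample() treats a length-1 vector as 1:n; avoid that trap
pick_other_ <- function(k, i) {
  others <- (1:k)[-i]
  if (length(others) == 1L) others else sample(others, 1)
}

# Sample a full ER path on one branch conditional on endpoint states,
# by rejection sampling up to `cap` attempts, then by uniformization.
# Returns the run-length encoding (named durations, start side first).
sample_branch_history_ <- function(i, j, t, k, q, cap, fallback, lev) {
  if (q == 0 || t == 0) {
    if (i != j) stop("impossible endpoint combination at rate 0.", call. = FALSE)
    return(stats::setNames(t, lev[i]))
  }
  leave <- (k - 1) * q
  for (try in seq_len(cap)) {
    states <- i
    times <- numeric(0)
    now <- 0
    if (i != j) {
      # condition on at least one event: first waiting time truncated to t
      u <- stats::runif(1)
      now <- -log(1 - u * (1 - exp(-leave * t))) / leave
      states <- c(states, pick_other_(k, i))
      times <- now
    }
    repeat {
      dt <- stats::rexp(1, leave)
      if (now + dt > t) break
      now <- now + dt
      cur <- states[length(states)]
      states <- c(states, pick_other_(k, cur))
      times <- c(times, now)
    }
    if (states[length(states)] == j) {
      bounds <- c(0, times, t)
      return(stats::setNames(diff(bounds), lev[states]))
    }
  }
  if (!fallback) {
    stop("rejection cap exceeded while sampling a branch history.",
         call. = FALSE)
  }
  # uniformization with rate k*q: the auxiliary jump chain is uniform over
  # all k states (self-jumps included), so intermediate states are iid
  # uniform and only the event count needs conditional sampling.
  lam <- k * q * t
  nmax <- max(10, stats::qpois(1 - 1e-12, lam))
  nn <- 0:nmax
  wt <- stats::dpois(nn, lam) * ifelse(nn == 0, as.numeric(i == j), 1 / k)
  n_ev <- sample(nn, 1, prob = wt)
  if (n_ev == 0) return(stats::setNames(t, lev[i]))
  times <- sort(stats::runif(n_ev, 0, t))
  states <- c(i, if (n_ev > 1) sample.int(k, n_ev - 1, replace = TRUE), j)
  bounds <- c(0, times, t)
  dur <- diff(bounds)
  keep <- c(TRUE, states[-1] != states[-length(states)])
  # collapse runs of identical states
  grp <- cumsum(keep)
  out <- tapply(dur, grp, sum)
  stats::setNames(as.numeric(out), lev[states[keep]])
}

#' Stochastic character maps under a fitted Mk model
#'
#' Samples complete state histories on every branch, consistent with the
#' observed tip states: node states are drawn from their conditional
#' distributions (pruning pass followed by a preorder sampling pass), and
#' branch histories are filled in by rejection sampling against the
#' endpoint states, falling back to uniformization after `rejection_cap`
#' failed attempts.
#'
#' @inheritParams mk_fit
#' @param fit An [mk_fit()] result; fitted on the fly when `NULL`. With
#'   `q = 0` every map is the trivial constant painting.
#' @param n_maps Number of maps to draw.
#' @param seed Integer seed; identical seeds give identical paintings.
#' @param rejection_cap Attempts per branch before the uniformization
#'   fallback (set `uniformization = FALSE` to error instead).
#' @param uniformization Enable the exact uniformization fallback.
#' @return A list of `painted_tree` objects of length `n_maps`.
#' @export
stochastic_map <- function(tree, states, fit = NULL, n_maps = 1, seed = NULL,
                           rejection_cap = 1000, uniformization = TRUE) {
  tree <- validate_tree(tree)
  s <- as_state_vector(states, tree)
  lev <- attr(s, "levels")
  k <- length(lev)
  if (is.null(fit)) fit <- mk_fit(tree, states)
  stopifnot(inherits(fit, "mk_fit"))
  idx_states <- match(s, lev)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  q <- fit$q

  pruned <- mk_prune_(tree, idx_states, k, max(q, 0))
  L <- pruned$L
  pre <- ape::reorder.phylo(tree, "cladewise")

  with_seed_(seed, {
    lapply(seq_len(n_maps), function(m) {
      node_state <- integer(n_tip + tree$Nnode)
      wr <- L[root, ] / sum(L[root, ])
      node_state[root] <- sample.int(k, 1, prob = wr)
      edge_maps <- vector("list", nrow(tree$edge))
      eidx <- edge_index_(tree)
      for (e in seq_len(nrow(pre$edge))) {
        p <- pre$edge[e, 1]
        ch <- pre$edge[e, 2]
        t_e <- pre$edge.length[e]
        pm <- mk_pmat_(k, max(q, 0), t_e)
        w <- pm[node_state[p], ] * L[ch, ]
        node_state[ch] <- sample.int(k, 1, prob = w / sum(w))
        hist <- sample_branch_history_(node_state[p], node_state[ch], t_e,
                                       k, q, rejection_cap, uniformization,
                                       lev)
        edge_maps[[eidx$edge_of[ch]]] <- hist
      }
      new_painted_tree(tree, edge_maps,
                       tip_states = stats::setNames(lev[node_state[seq_len(n_tip)]],
                                                    tree$tip.label),
                       node_states = lev[node_state[(n_tip + 1):length(node_state)]])
    })
  })
}
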