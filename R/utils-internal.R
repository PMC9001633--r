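# Internal helpers shared across modules. Nothing here is exported.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. `seed = NULL` means "use the current RNG stream".
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL.", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed; keeps values well below 2^31.
child_seed_ <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 31L + as.integer(offset)) %% 1000000007L
}

# Coerce a per-species trait given as a named vector or a two-column
# data frame (species, value) to a named numeric vector aligned to the
# tree's tip labels. Errors if any tip is missing.
as_trait_vector <- function(trait, tree, what = "trait") {
  if (is.data.frame(trait)) {
    if (!"species" %in% names(trait)) {
      stop("trait data frame must have a `species` column.", call. = FALSE)
    }
    value_col <- setdiff(names(trait), "species")[1]
    if (is.na(value_col)) stop("trait data frame has no value column.", call. = FALSE)
    v <- trait[[value_col]]
    names(v) <- trait$species
    trait <- v
  }
  if (is.null(names(trait))) {
    stop(what, " must be named by species (or be a species/value data frame).",
         call. = FALSE)
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0) {
    stop(what, " missing for tips: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  out <- trait[tree$tip.label]
  names(out) <- tree$tip.label
  out
}

# Same idea for discrete states; returns a named character vector.
as_state_vector <- function(states, tree, what = "states") {
  if (is.data.frame(states)) {
    if (!"species" %in% names(states)) {
      stop("states data frame must have a `species` column.", call. = FALSE)
    }
    value_col <- setdiff(names(states), "species")[1]
    v <- states[[value_col]]
    names(v) <- states$species
    states <- v
  }
  lev <- if (is.factor(states)) levels(states) else sort(unique(as.character(states)))
  states <- stats::setNames(as.character(states), names(states))
  missing <- setdiff(tree$tip.label, names(states))
  if (length(missing) > 0) {
    stop(what, " missing for tips: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- states[tree$tip.label]
  attr(out, "levels") <- lev
  out
}

# Edge index by child node and parent lookup.
edge_index_ <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  eidx <- integer(n_node)
  parent <- integer(n_node)
  eidx[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  list(edge_of = eidx, parent = parent, root = ape::Ntip(tree) + 1L)
}

# For every node, the set of descendant tip indices (tips map to themselves).
node_tip_sets_ <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Edge x tip incidence: TRUE if the tip descends from (the child end of)
# the edge. Row order matches tree$edge.
edge_tip_incidence_ <- function(tree) {
  n_tip <- ape::Ntip(tree)
  sets <- node_tip_sets_(tree)
  m <- matrix(FALSE, nrow(tree$edge), n_tip,
              dimnames = list(NULL, tree$tip.label))
  for (e in seq_len(nrow(tree$edge))) {
    m[e, sets[[tree$edge[e, 2]]]] <- TRUE
  }
  m
}

# Root-to-tip edge lists, ordered tip-first (j = 1 is the terminal edge).
tip_path_edges_ <- function(tree) {
  idx <- edge_index_(tree)
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != idx$root) {
      path <- c(path, idx$edge_of[node])
      node <- idx$parent[node]
    }
    path
  })
}
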