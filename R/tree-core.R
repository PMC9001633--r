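# Tree I/O and basic chronometry: Newick reading with validation, node
# heights, species ages, and lineage-through-time curves.

#' Read and validate a Newick tree
#'
#' Parses a Newick string (or a file containing one tree) into an
#' [ape::phylo] object and enforces the structural contract used throughout
#' the package: branch lengths on every non-root edge, non-negative lengths,
#' unique tip labels, and a binary topology. Polytomies are rejected unless
#' `resolve_polytomies = TRUE`, in which case they are resolved into
#' zero-length binary splits (which leaves all likelihood computations
#' unchanged).
#'
#' @param x A Newick string, or the path of a file whose first line is one.
#' @param resolve_polytomies Resolve multifurcations into zero-length binary
#'   splits instead of rejecting them.
#' @return A rooted `phylo` object.
#' @seealso [write_newick()], [read_newick_trees()]
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length)
#' @export
read_newick <- function(x, resolve_polytomies = FALSE) {
  if (length(x) != 1L || !is.character(x)) {
    stop("`x` must be a single Newick string or file path.", call. = FALSE)
  }
  text <- if (grepl("\\(", x) && grepl(";", x)) x else {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick: parser returned nothing.", call. = FALSE)
  validate_tree(tree, resolve_polytomies = resolve_polytomies)
}

#' Read a multi-tree Newick file (one tree per line)
#'
#' @inheritParams read_newick
#' @param path File with one Newick string per line.
#' @return A list of `phylo` objects.
#' @export
read_newick_trees <- function(path, resolve_polytomies = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_newick, resolve_polytomies = resolve_polytomies)
}

#' Write a tree as Newick text
#'
#' Branch lengths are written with enough digits to round-trip through
#' [read_newick()] to at least 12 significant digits.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Shared validation used by read_newick() and the simulators.
validate_tree <- function(tree, resolve_polytomies = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object.", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths are required on all edges.", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths.", call. = FALSE)
  if (ape::Ntip(tree) > 1 && !ape::is.binary(tree)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree, random = FALSE)
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop("tree contains polytomies; set `resolve_polytomies = TRUE` ",
           "to resolve them into zero-length splits.", call. = FALSE)
    }
  }
  tree
}

#' Node depths, heights, and ultrametricity
#'
#' Time runs from the root (depth 0) toward the present. `height` is the
#' distance below the deepest tip, so for an ultrametric tree it is the
#' usual "age" of a node in Myr before present.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (fraction of crown age) within which tip
#'   depths may differ while the tree still counts as ultrametric. The
#'   default absorbs the numerical jitter typical of dating software output.
#' @return A tibble with one row per node (tips first, ape numbering):
#'   `node`, `label`, `is_tip`, `depth`, `height`. Attributes `crown_age`,
#'   `total_length`, and `is_ultrametric` summarise the tree.
#' @examples
#' nh <- node_heights(read_newick("((A:1,B:1):1,C:2);"))
#' attr(nh, "is_ultrametric")
#' @export
node_heights <- function(tree, tol = 1e-6) {
  tree <- validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  crown <- max(depth[seq_len(n_tip)])
  tip_spread <- diff(range(depth[seq_len(n_tip)]))
  ultra <- n_tip == 1L || crown == 0 || tip_spread <= tol * crown
  out <- tibble::tibble(
    node = seq_along(depth),
    label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
    is_tip = seq_along(depth) <= n_tip,
    depth = depth,
    height = crown - depth
  )
  attr(out, "crown_age") <- crown
  attr(out, "total_length") <- sum(tree$edge.length)
  attr(out, "is_ultrametric") <- ultra
  attr(out, "tol") <- tol
  out
}

#' Is a tree ultrametric (within tolerance)?
#'
#' @inheritParams node_heights
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  attr(node_heights(tree, tol = tol), "is_ultrametric")
}

#' Species ages (terminal branch lengths)
#'
#' The age of a species is the length of the terminal branch subtending it,
#' i.e. the time back to its most recent speciation event.
#'
#' @param tree A `phylo` object.
#' @return A tibble `species`, `age` (Myr), in tip-label order.
#' @export
species_age <- function(tree) {
  tree <- validate_tree(tree)
  idx <- edge_index_(tree)
  n_tip <- ape::Ntip(tree)
  age <- if (n_tip == 1L && idx$edge_of[1] == 0) {
    # degenerate single-tip tree without a recorded edge
    numeric(1)
  } else {
    tree$edge.length[idx$edge_of[seq_len(n_tip)]]
  }
  if (any(age == 0)) {
    warning("zero-length terminal branch(es): species age 0 for ",
            paste(tree$tip.label[age == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(species = tree$tip.label, age = age)
}

#' Lineage-through-time curve
#'
#' Counts lineages forward in time on an ultrametric tree: 2 at the root
#' split, +1 at each subsequent internal node, ending at the number of tips.
#'
#' @param tree An ultrametric `phylo` object.
#' @param tol Ultrametricity tolerance passed to [node_heights()].
#' @return A tibble `time`, `lineages` with one row per branching time plus
#'   a closing row at the present.
#' @export
ltt_curve <- function(tree, tol = 1e-6) {
  nh <- node_heights(tree, tol = tol)
  if (!attr(nh, "is_ultrametric")) {
    stop("ltt_curve() requires an ultrametric tree.", call. = FALSE)
  }
  n_tip <- ape::Ntip(tree)
  if (n_tip < 2) return(tibble::tibble(time = 0, lineages = 1L))
  split_times <- sort(nh$depth[!nh$is_tip])
  counts <- seq_along(split_times) + 1L
  crown <- attr(nh, "crown_age")
  out <- tibble::tibble(time = split_times, lineages = counts)
  if (max(split_times) < crown) {
    out <- dplyr::bind_rows(out, tibble::tibble(time = crown, lineages = n_tip))
  }
  out
}
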