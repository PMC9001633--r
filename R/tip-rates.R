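# Equal-splits tip speciation rates (the DR statistic) and quartile ranking.

#' Equal-splits tip speciation rate (DR statistic)
#'
#' For each tip the inverse equal-splits measure is
#' \deqn{ES_i = \sum_{j=1}^{N_i} \ell_j \, 2^{-(j-1)}}
#' where \eqn{\ell_1} is the terminal branch and successive branches toward
#' the root are discounted by halving. The DR statistic is \eqn{1/ES_i}: a
#' non-model-based, tip-level estimator of speciation rate that is high for
#' species embedded in recent, rapid radiations and low for species on long
#' isolated branches.
#'
#' @param tree A rooted `phylo` object with branch lengths in Myr.
#' @return A tibble `species`, `es` (Myr), `dr` (1/Myr), `rank`
#'   (1 = lowest DR), `quartile` (1 = oldest/least diverse lineages,
#'   4 = youngest/most diverse), when the tree has at least 4 tips;
#'   otherwise `rank`/`quartile` are `NA`.
#' @examples
#' equal_splits_dr(read_newick("((A:1,B:1):1,C:2);"))
#' @export
equal_splits_dr <- function(tree) {
  tree <- validate_tree(tree)
  paths <- tip_path_edges_(tree)
  es <- vapply(paths, function(p) {
    sum(tree$edge.length[p] * 2^(-(seq_along(p) - 1)))
  }, numeric(1))
  if (any(es == 0)) {
    stop("tip(s) with zero root-to-tip path length: ",
         paste(tree$tip.label[es == 0], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(species = tree$tip.label, es = es, dr = 1 / es)
  if (nrow(out) >= 4) {
    out <- assign_quartiles(out, dr)
  } else {
    out$rank <- NA_integer_
    out$quartile <- NA_integer_
  }
  out
}

#' Rank species and assign DR quartiles
#'
#' Ranks species ascending on a scalar metric and cuts the ranks into four
#' near-equal groups (sizes differing by at most one). With the DR statistic,
#' quartile 1 holds the oldest and least diverse lineages and quartile 4 the
#' youngest, fastest-diversifying ones. Ties are broken by species name so
#' the assignment is stable and reproducible.
#'
#' @param data A data frame with a `species` column.
#' @param value Unquoted column holding the metric to rank on.
#' @return `data` with `rank` and `quartile` columns appended.
#' @export
assign_quartiles <- function(data, value) {
  if (!is.data.frame(data) || !"species" %in% names(data)) {
    stop("`data` must be a data frame with a `species` column.", call. = FALSE)
  }
  v <- dplyr::pull(data, {{ value }})
  n <- length(v)
  if (n < 4) stop("at least 4 species are required for quartiles.", call. = FALSE)
  if (length(unique(v)) == 1L) {
    warning("all values are equal; quartiles assigned by species-name order.",
            call. = FALSE)
  }
  ord <- order(v, data$species)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  data$rank <- rank
  data$quartile <- as.integer(ceiling(4 * rank / n))
  data
}
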