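test_that("BM fit matches the closed-form cherry and the dense oracle", {
  fit <- bm_fit(read_newick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(fit$sigma2, 1)
  expect_equal(fit$z0, 1)
  expect_equal(fit$loglik, -log(2 * pi) - 1, tolerance = 1e-12)

  expect_warning(cf <- bm_fit(read_newick("(A:1,B:1);"), c(A = 2, B = 2)),
                 "zero variance")
  expect_equal(cf$sigma2, 0)

  withr::with_seed(55, {
    for (i in 1:20) {
      tr <- random_ultrametric_tree(8)
      x <- setNames(rnorm(8), tr$tip.label)
      fit <- bm_fit(tr, x)
      ref <- oracle_bm_loglik(tr, x)
      expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
      expect_equal(fit$sigma2, ref$sigma2, tolerance = 1e-8)
      expect_equal(fit$z0, ref$z0, tolerance = 1e-8)
    }
  })
  expect_error(bm_fit(read_newick("((A:1,B:1):1,C:1.5);"), c(A = 1, B = 2, C = 3)),
               "ultrametric")
})

test_that("ancestral states solve the GLS normal equations", {
  # cherry: symmetric weighting -> root 1
  anc <- ancestral_states_bm(read_newick("(A:1,B:1);"), c(A = 0, B = 2))
  expect_equal(anc$state, 1)

  # constant trait: every node equals it
  anc0 <- ancestral_states_bm(toy_tree(), c(A = 3, B = 3, C = 3))
  expect_equal(anc0$state, c(3, 3))

  tr <- toy_tree()
  x <- c(A = 0, B = 2, C = 1)
  anc3 <- ancestral_states_bm(tr, x)
  # root equals bm_fit z0 and the dense-GLS oracle
  expect_equal(anc3$state[1], bm_fit(tr, x)$z0, tolerance = 1e-10)
  for (k in seq_len(nrow(anc3))) {
    expect_equal(anc3$state[k], oracle_ancestral_state(tr, x, anc3$node[k]),
                 tolerance = 1e-8)
  }
  # independent package cross-check on a bigger tree
  withr::with_seed(66, {
    tr2 <- random_ultrametric_tree(12)
    x2 <- setNames(rnorm(12), tr2$tip.label)
    mine <- ancestral_states_bm(tr2, x2)
    ref <- phytools::fastAnc(tr2, x2)
    expect_equal(mine$state, unname(as.numeric(ref)), tolerance = 1e-5)
  })
})

test_that("traitgram endpoints are exact", {
  tr <- read_newick("(A:1,B:1);")
  tg <- traitgram(tr, c(A = 0, B = 2))
  expect_equal(nrow(tg), 2)
  expect_equal(tg$time_parent, c(0, 0))
  expect_equal(tg$value_parent, c(1, 1))
  expect_setequal(tg$value_child, c(0, 2))
  # tip ordinates equal the input trait exactly
  tg3 <- traitgram(toy_tree(), c(A = 0, B = 2, C = 1))
  tips <- tg3[!is.na(tg3$label), ]
  expect_equal(tips$value_child[match(c("A", "B", "C"), tips$label)],
               c(0, 2, 1))
})

test_that("DTT starts at 1, ends at 0, and calibrates against its own null", {
  withr::with_seed(88, {
    tr <- random_ultrametric_tree(30)
    x <- simulate_bm_trait(tr, sigma2 = 1, seed = 7)
    d <- dtt(tr, x, n_null = 199, seed = 11)
    expect_equal(d$curve$observed[1], 1)
    expect_equal(d$curve$observed[nrow(d$curve)], 0)
    expect_equal(d$curve$null_median[1], 1)
    expect_true(all(d$curve$lower <= d$curve$upper))
    # BM data should sit inside its own 95% envelope most of the time
    inside <- mean(d$curve$observed >= d$curve$lower &
                     d$curve$observed <= d$curve$upper)
    expect_gt(inside, 0.7)
    # determinism
    d2 <- dtt(tr, x, n_null = 199, seed = 11)
    expect_equal(d$curve, d2$curve)
    expect_equal(d$mdi, d2$mdi)
  })
  # star-like tree: single interior time point, curve is 1 then 0
  star <- read_newick("((A:1,B:1):1e-12,(C:1,D:1):1e-12);")
  ds <- dtt(star, c(A = 0, B = 1, C = 2, D = 4), n_null = 99, seed = 1)
  expect_equal(ds$curve$observed[1], 1)
  expect_error(dtt(toy_tree(), c(A = 1, B = 2, C = 3), n_null = 99),
               "at least 4")
  withr::with_seed(89, {
    expect_error(dtt(random_ultrametric_tree(10),
                     setNames(rnorm(10), paste0("t", 1:10)), n_null = 50),
                 "at least 99")
  })
})

test_that("Mk fit matches limit case, grid-search oracle, and phytools", {
  # all tips one state in a 2-state space: q -> 0, loglik -> log(1/2)
  tr <- toy_tree()
  expect_warning(f0 <- mk_fit(tr, factor(c(A = "x", B = "x", C = "x"),
                                         levels = c("x", "y"))),
                 "single observed state")
  expect_equal(f0$q, 0)
  expect_equal(f0$loglik, log(0.5))

  # 3-tip toy {0,0,1}: compare to a brute-force grid over q
  st <- c(A = "0", B = "0", C = "1")
  fit <- mk_fit(tr, st)
  grid_q <- seq(0.01, 2, by = 1e-4)
  ll <- vapply(grid_q, function(q) oracle_mk_loglik(tr, c(1, 1, 2), 2, q),
               numeric(1))
  q_star <- grid_q[which.max(ll)]
  expect_equal(fit$q, q_star, tolerance = 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)

  # cross-check against phytools::fitMk on a simulated 4-state character
  withr::with_seed(99, {
    tr2 <- random_ultrametric_tree(40)
    tr2$edge.length <- tr2$edge.length * 20
    sim <- simulate_mk_trait(tr2, 0.05, states = c("AQ", "GN", "FN", "DD"),
                             seed = 2)
    if (length(unique(sim$states)) >= 2) {
      mine <- mk_fit(tr2, sim$states)
      ref <- phytools::fitMk(tr2, sim$states, model = "ER", pi = "equal")
      expect_equal(mine$q, as.numeric(ref$rates), tolerance = 1e-3)
      expect_equal(mine$loglik, as.numeric(ref$logLik), tolerance = 1e-4)
    }
  })
})

test_that("stochastic maps honour tip states, parsimony, and determinism", {
  withr::with_seed(123, {
    tr <- random_ultrametric_tree(25)
    tr$edge.length <- tr$edge.length * 10
    sim <- simulate_mk_trait(tr, 0.08, states = c("A", "B"), seed = 3)
  })
  fit <- mk_fit(tr, sim$states)
  maps <- stochastic_map(tr, sim$states, fit, n_maps = 50, seed = 9)
  pars <- oracle_fitch(tr, sim$states)
  for (m in maps) {
    expect_identical(m$tip_states, sim$states)
    expect_gte(n_state_changes(m), pars)
    # segment durations on each branch sum to its length
    lens <- vapply(m$edge_maps, sum, numeric(1))
    expect_equal(lens, tr$edge.length, tolerance = 1e-9)
  }
  maps2 <- stochastic_map(tr, sim$states, fit, n_maps = 50, seed = 9)
  expect_identical(
    lapply(maps, `[[`, "edge_maps"), lapply(maps2, `[[`, "edge_maps"))

  # q = 0 with uniform tips: trivial constant painting
  expect_warning(f0 <- mk_fit(tr, factor(setNames(rep("A", 25), tr$tip.label),
                                         levels = c("A", "B"))))
  m0 <- stochastic_map(tr, factor(setNames(rep("A", 25), tr$tip.label),
                                  levels = c("A", "B")), f0, n_maps = 3,
                       seed = 1)
  expect_true(all(vapply(m0, n_state_changes, integer(1)) == 0L))
})

test_that("painted-tree serialization is self-consistent", {
  withr::with_seed(31, {
    tr <- random_ultrametric_tree(8)
    sim <- simulate_mk_trait(tr, 0.3, states = c("A", "B"), seed = 5)
  })
  txt <- write_painted_newick(sim$history)
  expect_match(txt, "\\[&map=\\{")
  expect_match(txt, ";$")
  st <- state_times(sim$history)
  expect_equal(sum(st$time), sum(tr$edge.length), tolerance = 1e-9)
})

test_that("multirate BM reduces to single-rate and matches the dense oracle", {
  withr::with_seed(77, {
    tr <- random_ultrametric_tree(12)
    x <- setNames(rnorm(12), tr$tip.label)
  })
  # single-state painting: identical to bm_fit to 1e-10
  one <- divscape:::new_painted_tree(
    tr, lapply(tr$edge.length, function(l) c(S = l)),
    tip_states = setNames(rep("S", 12), tr$tip.label),
    node_states = rep("S", tr$Nnode))
  mr <- multirate_bm(one, x)
  single <- bm_fit(tr, x)
  expect_equal(mr$per_map$loglik_multi[1], single$loglik, tolerance = 1e-10)
  expect_equal(unname(mr$per_map$rates[[1]]), single$sigma2, tolerance = 1e-10)

  # two-state cherry with one branch per state, traits {0, 2}: the profile
  # likelihood has a ridge sigma2_a + sigma2_b = 2 (worked by hand: the
  # contrast has variance sigma2_a + sigma2_b and the root term is free)
  cherry <- read_newick("(A:1,B:1);")
  paint <- divscape:::new_painted_tree(
    cherry, list(c(a = 1), c(b = 1))[order(cherry$edge[, 2])],
    tip_states = c(A = "a", B = "b"), node_states = "a")
  eidx <- divscape:::edge_index_(cherry)
  paint$edge_maps <- vector("list", 2)
  paint$edge_maps[[eidx$edge_of[which(cherry$tip.label == "A")]]] <- c(a = 1)
  paint$edge_maps[[eidx$edge_of[which(cherry$tip.label == "B")]]] <- c(b = 1)
  mr2 <- multirate_bm(paint, c(A = 0, B = 2))
  rates <- mr2$per_map$rates[[1]]
  expect_equal(unname(rates["a"] + rates["b"]), 2, tolerance = 1e-4)
  st2 <- divscape:::edge_state_times_(paint)
  scaled2 <- as.numeric(st2[, names(rates), drop = FALSE] %*% rates)
  expect_equal(mr2$per_map$loglik_multi[1],
               oracle_bm_loglik(cherry, c(A = 0, B = 2),
                                scaled_edge_lengths = scaled2)$loglik,
               tolerance = 1e-6)

  # random two-state paintings: profile loglik equals the dense oracle on
  # the state-rescaled covariance
  withr::with_seed(303, {
    for (i in 1:10) {
      tree <- random_ultrametric_tree(8)
      sim <- simulate_mk_trait(tree, 0.5 / max(ape::node.depth.edgelength(tree)),
                               states = c("a", "b"), seed = 40 + i)
      if (length(unique(names(unlist(sim$history$edge_maps)))) < 2) next
      xx <- setNames(rnorm(8), tree$tip.label)
      fit <- multirate_bm(sim$history, xx)
      st <- divscape:::edge_state_times_(sim$history)
      rates <- fit$per_map$rates[[1]]
      scaled <- as.numeric(st[, names(rates), drop = FALSE] %*% rates)
      ref <- oracle_bm_loglik(tree, xx, scaled_edge_lengths = scaled)
      # the oracle re-profiles the scale; at the ML rates it matches
      expect_equal(fit$per_map$loglik_multi[1], ref$loglik, tolerance = 1e-5)
    }
  })
})

test_that("multirate AICc bookkeeping and averaging behave", {
  withr::with_seed(404, {
    tr <- random_ultrametric_tree(40)
    sim <- simulate_mk_trait(tr, 1 / max(ape::node.depth.edgelength(tr)),
                             states = c("a", "b"), seed = 1)
    x <- simulate_bm_trait(tr, 1, seed = 2)
  })
  fit <- multirate_bm(sim$history, x)
  # multi-rate never has lower loglik than single-rate (nested models)
  expect_gte(fit$per_map$loglik_multi[1], fit$per_map$loglik_single[1] - 1e-8)
  expect_equal(fit$per_map$weight_single[1] + fit$per_map$weight_multi[1], 1)
  # model-averaged rates sit between the two models' estimates
  avg <- fit$rates$sigma2_averaged
  for (k in seq_along(avg)) {
    lo <- min(fit$single$sigma2, fit$rates$sigma2_ml[k])
    hi <- max(fit$single$sigma2, fit$rates$sigma2_ml[k])
    expect_gte(avg[k], lo - 1e-12)
    expect_lte(avg[k], hi + 1e-12)
  }
  expect_error(multirate_bm(divscape:::new_painted_tree(
    tr, lapply(tr$edge.length, function(l) c(a = l, b = 0)),
    tip_states = setNames(rep("a", 40), tr$tip.label),
    node_states = rep("a", tr$Nnode)), x), "zero total branch time")
})
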