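test_that("birth-death simulator honours stopping rules and seeds", {
  tr <- simulate_bd_tree(1, 0, n_tips = 50, seed = 1)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(is_ultrametric(tr))

  # extinction: extinct lineages pruned, survivors ultrametric
  tr2 <- simulate_bd_tree(1, 0.4, n_tips = 30, seed = 2)
  expect_equal(ape::Ntip(tr2), 30)
  expect_true(is_ultrametric(tr2))

  expect_identical(write_newick(simulate_bd_tree(1, 0, n_tips = 20, seed = 7)),
                   write_newick(simulate_bd_tree(1, 0, n_tips = 20, seed = 7)))

  expect_error(simulate_bd_tree(0.5, 0.5, n_tips = 10), "birth > death")
  expect_error(simulate_bd_tree(1, 0, n_tips = 10, max_time = 5),
               "exactly one")
})

test_that("pure-birth tip counts over a fixed window average to e^(lambda T)", {
  # E[N(T)] = e^{(lambda - mu) T} from one starting lineage; modest
  # replicate count here, the full-scale check lives in the acceptance suite
  withr::with_seed(19, {
    n <- replicate(400, ape::Ntip(simulate_bd_tree(1, 0, max_time = 1)))
  })
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - exp(1)), 4 * se)
})

test_that("BM trait simulation matches the analytic tip covariance", {
  cherry <- read_newick("(A:1,B:1);")
  withr::with_seed(23, {
    sims <- replicate(3000, simulate_bm_trait(cherry, sigma2 = 1))
  })
  expect_lt(abs(var(sims["A", ]) - 1), 0.1)
  expect_lt(abs(cov(sims["A", ], sims["B", ])), 0.08)

  # sigma2 = 0 -> all tips at the root state
  expect_equal(unname(simulate_bm_trait(toy_tree(), 0, z0 = 3.5)),
               rep(3.5, 3))

  # painted tree: per-state rates shape the variance contributions
  paint <- divscape:::new_painted_tree(
    cherry, list(c(fast = 1), c(slow = 1)), tip_states = c(A = "fast", B = "slow"),
    node_states = "fast")
  eidx <- divscape:::edge_index_(cherry)
  paint$edge_maps <- vector("list", 2)
  paint$edge_maps[[eidx$edge_of[1]]] <- c(fast = 1)
  paint$edge_maps[[eidx$edge_of[2]]] <- c(slow = 1)
  withr::with_seed(29, {
    ps <- replicate(3000, simulate_bm_trait(paint, c(fast = 4, slow = 0.25)))
  })
  expect_lt(abs(var(ps["A", ]) - 4), 0.45)
  expect_lt(abs(var(ps["B", ]) - 0.25), 0.04)
})

test_that("Mk simulation returns a true history consistent with the tips", {
  withr::with_seed(37, {
    tr <- random_ultrametric_tree(40)
    tr$edge.length <- tr$edge.length * 10
  })
  sim <- simulate_mk_trait(tr, 0.05, states = c("A", "B"), seed = 11)
  expect_identical(sim$states, sim$history$tip_states)
  expect_gte(sim$n_changes, oracle_fitch(tr, sim$states))
  lens <- vapply(sim$history$edge_maps, sum, numeric(1))
  expect_equal(lens, tr$edge.length, tolerance = 1e-9)

  # q = 0: all tips inherit the root state, zero changes
  sim0 <- simulate_mk_trait(tr, 0, states = c("A", "B"), seed = 1)
  expect_equal(length(unique(sim0$states)), 1L)
  expect_equal(sim0$n_changes, 0L)

  # q = 0.1 on a 300-tip tree: both states essentially always observed
  withr::with_seed(38, {
    big <- simulate_bd_tree(0.2, 0, n_tips = 300)
    hits <- replicate(20, length(unique(
      simulate_mk_trait(big, 0.1, states = c("A", "B"))$states)))
  })
  expect_gte(mean(hits == 2), 0.95)
})

test_that("landscapes carry the latitudinal gradient and stay in range", {
  g <- grid_spec(95, -5, 20, 20, 0.5)
  land <- generate_landscape(g, noise_sd = 0.1, elevation_sd = 0.1,
                             gradient = 15, seed = 3)
  expect_length(land$rasters, 19)
  t1 <- land$rasters$bio01$values
  north <- mean(t1[16:20, ]); south <- mean(t1[1:5, ])
  expect_lt(north, south) # poleward rows are cooler
  expect_gt(south - north, 15 * 0.5) # a healthy share of the gradient
  p1 <- land$rasters$bio12$values
  expect_true(all(p1 >= 0))

  # zero drift and slices: stability of identical slices is 1
  land2 <- generate_landscape(g, n_slices = 3, drift_sd = 0, seed = 4)
  s <- climate_stability(land2$slices$bio01, land2$slice_ages)
  expect_true(all(abs(s$stability$values - 1) < 1e-12))
  expect_identical(
    generate_landscape(g, seed = 9)$rasters$bio01$values,
    generate_landscape(g, seed = 9)$rasters$bio01$values)
})

test_that("occurrence generation respects bounds, dispersion, and endemism", {
  g <- grid_spec(0, 0, 10, 10, 0.5)
  sp <- paste0("s", 1:200)
  occ <- generate_occurrences(sp, g, dispersion = 0.4,
                              single_fraction = 0.65, seed = 5)
  expect_true(all(!is.na(divscape:::point_to_cell_(g, occ$lon, occ$lat))))
  expect_setequal(unique(occ$species), sp)
  n_single <- sum(table(occ$species) == 1)
  # binomial(200, 0.65): allow 4 sd
  expect_lt(abs(n_single - 130), 4 * sqrt(200 * 0.65 * 0.35))

  # zero dispersion: every record of a species in one cell
  occ0 <- generate_occurrences(sp[1:20], g, dispersion = 0,
                               single_fraction = 0, seed = 6)
  cells <- divscape:::point_to_cell_(g, occ0$lon, occ0$lat)
  expect_true(all(tapply(cells, occ0$species,
                         function(x) length(unique(x))) == 1))

  expect_error(generate_occurrences(
    "a", g, centroids = tibble::tibble(species = "a", lon = 99, lat = 0)),
    "outside the grid")
})

test_that("scenario fixtures are reproducible, validated bundles", {
  s1 <- scenario_fixture("null", seed = 2)
  s2 <- scenario_fixture("null", seed = 2)
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
  expect_identical(s1$occurrences, s2$occurrences)
  expect_identical(s1$traits, s2$traits)

  # bundles satisfy the input contracts of the downstream modules
  expect_true(is_ultrametric(s1$tree))
  expect_setequal(s1$traits$species, s1$tree$tip.label)
  expect_setequal(unique(s1$occurrences$species), s1$tree$tip.label)
  pam <- build_pam(s1$occurrences, s1$grid)
  expect_equal(sort(pam$species), sort(s1$tree$tip.label))
  expect_true(all(colSums(pam$incidence) >= 1))

  tw <- scenario_fixture("two_rate_niche", seed = 3)
  expect_equal(unname(tw$params$sigma2_true["island"] /
                        tw$params$sigma2_true["mainland"]), 10)
  st <- state_times(tw$histories$island)
  expect_setequal(st$state, c("island", "mainland"))

  pi_ <- scenario_fixture("paleo_island", seed = 4)
  expect_true("relict" %in% pi_$tree$tip.label)
  sa <- species_age(pi_$tree)
  relict_age <- sa$age[sa$species == "relict"]
  expect_gt(relict_age / max(sa$age[sa$species != "relict"]), 2)
  rel_occ <- dplyr::filter(pi_$occurrences, species == "relict")
  expect_equal(nrow(rel_occ), 1)

  ms <- scenario_fixture("mode_shift", seed = 5)
  expect_true(all(ms$traits$mode %in% c("AQ", "GN", "FN", "DD")))

  expect_error(scenario_fixture("nope"), "arg")
})
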