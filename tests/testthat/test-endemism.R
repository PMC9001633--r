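test_that("phylogenetic endemism matches hand-evaluated branch ranges", {
  # cells c1 = {A}, c2 = {A,B,C}: PE(c1) = 1/2 + 1/2 = 1, PE(c2) = 4
  tr <- toy_tree()
  g <- grid_spec(0, 0, 2, 1, 1)
  occ <- data.frame(species = c("A", "A", "B", "C"),
                    lon = c(0.5, 1.5, 1.5, 1.5), lat = rep(0.5, 4))
  pe <- phylogenetic_endemism(build_pam(occ, g), tr)
  expect_equal(pe$pe, c(1, 4))

  # single cell holding everything: PE = total branch length
  occ1 <- data.frame(species = c("A", "B", "C"), lon = 0.5, lat = 0.5)
  pe1 <- phylogenetic_endemism(build_pam(occ1, g), tr)
  expect_equal(pe1$pe[1], 5)

  # an endemic species' cell gets at least its terminal branch in full
  occ2 <- data.frame(species = c("A", "B", "C", "A", "B"),
                     lon = c(0.5, 0.5, 1.5, 1.5, 1.5), lat = rep(0.5, 5))
  pe2 <- phylogenetic_endemism(build_pam(occ2, g), tr)
  expect_gte(pe2$pe[2], 2) # C (terminal branch 2) is endemic to cell 2

  expect_error(phylogenetic_endemism(build_pam(occ1[1:2, ], g), tr),
               "zero occupied cells")
})

test_that("PE conservation holds on random scenarios and randomized PAMs", {
  withr::with_seed(31, {
    for (i in 1:10) {
      tree <- random_ultrametric_tree(sample(5:15, 1))
      pam <- random_pam_for_tree(tree, sample(3:6, 1), seed = 500 + i)
      expect_equal(sum(phylogenetic_endemism(pam, tree)$pe),
                   sum(tree$edge.length), tolerance = 1e-8)
      # on the comparison tree too, and after randomization
      ct <- comparison_tree(tree)
      rand <- curveball_randomize(pam, n_swaps = 500, seed = i)
      expect_equal(sum(phylogenetic_endemism(rand, ct)$pe),
                   sum(ct$edge.length), tolerance = 1e-8)
    }
  })
})

test_that("comparison tree equalizes branches and preserves total length", {
  ct <- comparison_tree(toy_tree())
  expect_equal(unique(ct$edge.length), 1.25)
  expect_equal(sum(ct$edge.length), 5)
  already <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(comparison_tree(already)$edge.length, already$edge.length)
})

test_that("curveball randomization preserves margins and is seed-stable", {
  pam <- random_pam(5, 8, seed = 12)
  r1 <- curveball_randomize(pam, n_swaps = 2000, seed = 99)
  r2 <- curveball_randomize(pam, n_swaps = 2000, seed = 99)
  expect_identical(r1$incidence, r2$incidence)
  expect_equal(rowSums(r1$incidence), rowSums(pam$incidence))
  expect_equal(colSums(r1$incidence), colSums(pam$incidence))

  # 2x2 checkerboard: the null space is exactly the two checkerboard states
  chk <- divscape:::new_pam(
    matrix(c(1L, 0L, 0L, 1L), 2, 2, dimnames = list(NULL, c("a", "b"))),
    grid_spec(0, 0, 2, 1, 1))
  seen <- unique(vapply(1:30, function(s) {
    paste(curveball_randomize(chk, n_swaps = 7, seed = s)$incidence,
          collapse = "")
  }, character(1)))
  expect_true(all(seen %in% c("1001", "0110")))
  expect_equal(length(seen), 2L)

  ones <- divscape:::new_pam(
    matrix(1L, 3, 3, dimnames = list(NULL, c("a", "b", "c"))),
    grid_spec(0, 0, 3, 1, 1))
  expect_identical(curveball_randomize(ones, 100, seed = 1)$incidence,
                   ones$incidence)

  expect_error(curveball_randomize(divscape:::new_pam(
    matrix(1L, 3, 1, dimnames = list(NULL, "a")), grid_spec(0, 0, 1, 3, 1)),
    100), "at least 2")
})

test_that("CANAPE classifies constructed paleo and neo cells", {
  scen <- scenario_fixture("paleo_island", seed = 4)
  pam <- build_pam(scen$occurrences, scen$grid)
  res <- canape_classify(pam, scen$tree, n_reps = 999, seed = 8)
  target <- dplyr::filter(res, .data$cell == scen$target_cell)
  expect_equal(nrow(target), 1)
  expect_equal(target$category, "paleo")

  # mirrored construction: a recent 6-species short-branch radiation,
  # endemic to one cell but nested shallowly inside the tree (sister to a
  # widespread tip), comes out as neo
  base <- simulate_bd_tree(0.09, 0, n_tips = 40, seed = 21)
  crown <- max(ape::node.depth.edgelength(base))
  eps <- crown / 50
  rad <- ape::read.tree(text = paste0(
    "(((((r1:", eps, ",r2:", eps, "):", eps, ",r3:", 2 * eps,
    "):", eps, ",r4:", 3 * eps, "):", eps, ",r5:", 4 * eps,
    "):", eps, ",r6:", 5 * eps, "):", eps, ";"))
  host <- species_age(base)
  host <- host$species[which.max(host$age)] # needs terminal depth > 6 eps
  tree <- ape::bind.tree(base, rad, where = which(base$tip.label == host),
                         position = 6 * eps)
  expect_true(is_ultrametric(tree))
  grid <- scen$grid
  occ <- generate_occurrences(base$tip.label, grid, dispersion = 0.6,
                              single_fraction = 0.3, seed = 5)
  occ <- dplyr::bind_rows(
    occ, tibble::tibble(species = paste0("r", 1:6),
                        lon = grid$lon_min + 0.25, lat = grid$lat_min + 0.25))
  target_cell <- divscape:::point_to_cell_(grid, grid$lon_min + 0.25,
                                           grid$lat_min + 0.25)
  resn <- canape_classify(build_pam(occ, grid), tree, n_reps = 999, seed = 8)
  tn <- dplyr::filter(resn, .data$cell == target_cell)
  expect_equal(tn$category, "neo")
})

test_that("CANAPE output is deterministic and respects significance rules", {
  withr::with_seed(61, {
    tree <- random_ultrametric_tree(12)
    pam <- random_pam_for_tree(tree, 4, seed = 3)
  })
  a <- canape_classify(pam, tree, n_reps = 99, seed = 17)
  b <- canape_classify(pam, tree, n_reps = 99, seed = 17)
  expect_identical(a$category, b$category)
  expect_identical(a$pe_obs, b$pe_obs)

  # structural rules: categories only on significant cells; p-values have
  # the +1 correction floor; super implies both PE tails extreme
  expect_true(all(a$category[!a$significant] == "not_significant"))
  expect_true(all(a$p_pe_obs >= 1 / 100))
  expect_true(all(!a$super | (a$p_pe_obs <= 0.01 & a$p_pe_alt <= 0.01)))
  expect_true(all(a$endemism_type[a$super & a$category == "mixed"] == "super"))
  expect_error(canape_classify(pam, tree, n_reps = 50), "at least 99")
})
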