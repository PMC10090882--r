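# Synthetic-data generator: trees, traits, fixture.

test_that("simulated trees are ultrametric with the requested tips and depth", {
  cfg <- simulation_config(n_tips = 50, tree_depth = 120, seed = 4)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 50)
  d <- node_depths(tr)[1:50]
  expect_lt(diff(range(d)), 1e-9 * max(d))
  expect_equal(max(d), 120, tolerance = 1e-12)
  expect_equal(anyDuplicated(tr$tip.label), 0L)
})

test_that("the two-tip tree is two pendant branches at the stated depth", {
  cfg <- simulation_config(seed = 1)
  cfg$n_tips <- 2L
  cfg$tree_depth <- 10
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(unname(node_depths(tr)[1:2]), c(10, 10))
})

test_that("tree simulation is deterministic in the seed", {
  cfg <- simulation_config(n_tips = 20, seed = 1)
  t1 <- ape::write.tree(simulate_tree(cfg))
  t2 <- ape::write.tree(simulate_tree(cfg))
  expect_identical(t1, t2)
  t3 <- ape::write.tree(simulate_tree(simulation_config(n_tips = 20, seed = 2)))
  expect_false(identical(t1, t3))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_tips = 3), class = "nasallom_error_config")
  expect_error(simulation_config(sigma_x2 = -1), class = "nasallom_error_config")
  bad <- simulation_config(seed = 1)
  bad$n_tips <- 1
  expect_error(simulate_tree(bad), class = "nasallom_error_config")
})

test_that("noise-free traits fall exactly on the group line", {
  cfg <- simulation_config(n_tips = 12, sigma_e2 = 0, slope_endo = 2,
                           slope_ecto = 2, intercept_endo = 1,
                           intercept_ecto = 1, seed = 3)
  tr <- simulate_tree(cfg)
  tt <- simulate_allometric_traits(tr, cfg)
  expect_equal(tt$y, 2 * tt$x + 1, tolerance = 1e-12)
  expect_equal(tt$y_raw, 10^tt$y, tolerance = 1e-12)
})

test_that("traits error when a tip lacks a group label", {
  cfg <- simulation_config(n_tips = 6, seed = 2)
  tr <- simulate_tree(cfg)
  grp <- setNames(rep("endotherm", 5), tr$tip.label[1:5])
  expect_error(simulate_allometric_traits(tr, cfg, groups = grp),
               class = "nasallom_error_config")
})

test_that("star-tree trait variance matches the Brownian closed form", {
  # on a star tree of depth T, tip values are iid N(root, sigma2 * T)
  n <- 16; depth <- 50; sigma2 <- 0.004
  star <- ape::stree(n, "star")
  star$edge.length <- rep(depth, n)
  star$root.edge <- 0   # mark the basal polytomy as a true root
  cfg <- simulation_config(n_tips = n, sigma_x2 = sigma2, sigma_e2 = 0,
                           tree_depth = depth, seed = 1)
  grp <- setNames(rep("ectotherm", n), star$tip.label)
  xs <- unlist(lapply(1:125, function(s) {
    cfg$seed <- s
    simulate_allometric_traits(star, cfg, groups = grp)$x
  }))
  expect_equal(var(xs), sigma2 * depth, tolerance = 0.05)
})

test_that("residual covariance of sister tips matches shared path length", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  cfg <- simulation_config(n_tips = 4, sigma_x2 = 0, sigma_e2 = 1,
                           tree_depth = 3, seed = 1)
  grp <- setNames(rep("ectotherm", 4), tr$tip.label)
  E <- t(vapply(1:1500, function(s) {
    cfg$seed <- s
    tt <- simulate_allometric_traits(tr, cfg, groups = grp)
    setNames(tt$e, tt$species)
  }, numeric(4)))
  emp <- stats::cov(E)
  oracle <- bm_covariance(tr)   # sigma_e2 = 1
  # sisters share 2 units of path, non-sisters none
  expect_equal(emp["A", "B"], oracle["A", "B"], tolerance = 0.15)
  expect_lt(abs(emp["A", "C"]), 3 * sqrt(oracle["A", "A"]^2 / 1500) + 0.15)
  expect_gt(emp["A", "B"], emp["A", "C"])
})

test_that("the same seed reproduces the full specimen table bit for bit", {
  cfg <- simulation_config(n_tips = 15, seed = 11, n_conspecific = 2)
  s1 <- simulate_specimen_table(cfg)
  s2 <- simulate_specimen_table(cfg)
  expect_identical(s1$records, s2$records)
  expect_identical(ape::write.tree(s1$specimen_tree),
                   ape::write.tree(s2$specimen_tree))
})

test_that("specimen table carries the designed group structure", {
  st <- simulate_specimen_table(simulation_config(n_tips = 30, seed = 5,
                                                  n_conspecific = 3))
  rec <- st$records
  expect_true(all(rec$thermo_class %in% c("endotherm", "ectotherm")))
  expect_true(all(rec$clade[rec$thermo_class == "ectotherm"] ==
                    "Lepidosauria"))
  expect_true(all(rec$clade[rec$thermo_class == "endotherm"] %in%
                    c("Aves", "Mammalia")))
  expect_true(all(rec$hull_vol_mm3 > rec$skull_vol_mm3))
  expect_true(all(rec$resp_vol_mm3 < rec$nasal_vol_mm3))
  counts <- table(rec$species)
  expect_equal(sort(unique(as.integer(counts))), c(1L, 3L))
  expect_true(is_ultrametric(st$specimen_tree))
})

test_that("the packaged taxon table reproduces the study inventory", {
  tab <- taxon_fixture()
  expect_equal(nrow(tab), 47)
  expect_equal(sum(tab$clade == "Aves"), 21)
  expect_equal(sum(tab$n_specimens), 51)
  expect_true(all(tab$thermo_class %in% c("endotherm", "ectotherm")))
  expect_true(all(tab$clade[tab$thermo_class == "endotherm"] %in%
                    c("Aves", "Mammalia")))
  expect_true(all(tab$clade[tab$thermo_class == "ectotherm"] %in%
                    c("Crocodylia", "Testudines", "Lepidosauria")))
  expect_setequal(tab$species[tab$multi_specimen],
                  c("Struthio camelus", "Larus crassirostris",
                    "Alligator mississippiensis"))
  withf <- taxon_fixture(include_fossil = TRUE)
  expect_equal(nrow(withf), 48)
  expect_true(is.na(withf$thermo_class[withf$clade == "Dinosauria"]))
})
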