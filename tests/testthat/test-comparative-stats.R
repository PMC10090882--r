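# Regression machinery: transforms, tree covariance, the three fitters.

test_that("log transform is base 10 and rejects non-positive values", {
  d <- tibble::tibble(species = c("a", "b"), v = c(1000, 1))
  expect_equal(log_transform(d, "v")$v, c(3, 0))
  d$v <- c(1000, 0)
  err <- expect_error(log_transform(d, "v"), class = "nasallom_error_domain")
  expect_match(conditionMessage(err), "row 2")
})

test_that("Brownian covariance matches hand-read and star-tree cases", {
  star <- ape::stree(5, "star")
  star$edge.length <- rep(7, 5)
  star$root.edge <- 0
  expect_equal(unname(bm_covariance(star)), 7 * diag(5))
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  C <- bm_covariance(tr)
  expect_equal(C["A", "B"], 2)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), rep(3, 3))
})

test_that("Brownian covariance equals path enumeration on random trees", {
  withr::with_seed(99, {
    for (k in 1:30) {
      tr <- random_ultrametric_tree(sample(4:12, 1))
      expect_equal(bm_covariance(tr), oracle_path_covariance(tr),
                   tolerance = 1e-12)
    }
  })
})

test_that("Brownian covariance agrees with the ape reference", {
  withr::with_seed(123, {
    tr <- random_ultrametric_tree(10)
  })
  expect_equal(bm_covariance(tr), ape::vcv(tr), tolerance = 1e-12)
})

test_that("unrooted or lengthless trees are rejected", {
  tr <- ape::rtree(5)
  tru <- ape::unroot(tr)
  expect_error(bm_covariance(tru), class = "nasallom_error_tree")
  tr$edge.length <- NULL
  expect_error(bm_covariance(tr), class = "nasallom_error_tree")
})

test_that("conspecific expansion preserves depths and shared paths", {
  tr <- ape::read.tree(text = "((A:5,B:5):5,C:10);")
  single <- data.frame(species = c("A", "B", "C"),
                       specimen_id = c("A", "B", "C"))
  expect_identical(ape::write.tree(expand_conspecific_tips(tr, single)),
                   ape::write.tree(tr))
  sp <- data.frame(species = c("A", "A", "A", "B", "C"),
                   specimen_id = c("a1", "a2", "a3", "B", "C"))
  te <- expand_conspecific_tips(tr, sp)
  expect_equal(ape::Ntip(te), 5)
  expect_true(is_ultrametric(te))
  C <- bm_covariance(te)
  expect_equal(C["a1", "a2"], 9)      # depth 10 minus the 1 Ma pendants
  expect_equal(unname(diag(C)), rep(10, 5))
  shallow <- ape::read.tree(text = "((A:0.5,B:0.5):5,C:5.5);")
  expect_error(expand_conspecific_tips(shallow, sp),
               class = "nasallom_error_tree")
})

test_that("OLS recovers exact lines and matches the normal equations", {
  x <- c(-2, -1, 0, 1, 2, 3)
  f <- fit_ols(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  withr::with_seed(8, {
    x <- rnorm(20); y <- 0.5 + 0.8 * x + rnorm(20, 0, 0.3)
  })
  f <- fit_ols(x, y)
  o <- oracle_ols(x, y)
  expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
  expect_error(fit_ols(rep(1, 5), rnorm(5)),
               class = "nasallom_error_degenerate")
})

test_that("SMA slope is the sd ratio and the fit is axis-symmetric", {
  withr::with_seed(2, {
    x <- rnorm(40)
    y <- 0.3 + x + rnorm(40, 0, 0.6)
  })
  f <- fit_sma(x, y)
  expect_equal(f$slope, sign(stats::cor(x, y)) * sd(y) / sd(x),
               tolerance = 1e-12)
  b_rev <- fit_sma(y, x)$slope
  expect_equal(f$slope * b_rev, 1, tolerance = 1e-12)
  # collinear data: SMA equals OLS
  yc <- 2 * x + 1
  expect_equal(fit_sma(x, yc)$slope, fit_ols(x, yc)$slope, tolerance = 1e-12)
  expect_error(fit_sma(x, rep(1, 40)), class = "nasallom_error_degenerate")
})

test_that("SMA slope magnitude is never below the OLS magnitude", {
  withr::with_seed(31, {
    for (k in 1:10) {
      x <- rnorm(25); y <- 0.4 * x + rnorm(25, 0, 0.5)
      expect_gte(abs(fit_sma(x, y)$slope) + 1e-12, abs(fit_ols(x, y)$slope))
    }
  })
})

test_that("PGLS with identity covariance reduces exactly to OLS", {
  withr::with_seed(3, {
    x <- rnorm(15); y <- 1 + 0.7 * x + rnorm(15, 0, 0.2)
  })
  fo <- fit_ols(x, y)
  fp <- fit_pgls(x, y, diag(15))
  expect_equal(fp$slope, fo$slope, tolerance = 1e-14)
  expect_equal(fp$intercept, fo$intercept, tolerance = 1e-14)
  expect_equal(fp$vcov, fo$vcov, tolerance = 1e-12)
})

test_that("PGLS estimates are invariant to rescaling the covariance", {
  withr::with_seed(4, {
    tr <- random_ultrametric_tree(12)
    C <- bm_covariance(tr)
    x <- rnorm(12); y <- 2 - 0.5 * x + rnorm(12, 0, 0.4)
  })
  f1 <- fit_pgls(x, y, C)
  f2 <- fit_pgls(x, y, 1000 * C)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-12)
})

test_that("PGLS matches the explicit-inverse GLS oracle on a 5-taxon tree", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,(D:2,E:2):1);")
  C <- bm_covariance(tr)
  withr::with_seed(5, {
    x <- rnorm(5); y <- 1 + x + rnorm(5, 0, 0.3)
  })
  f <- fit_pgls(x, y, C)
  o <- oracle_gls(x, y, C)
  expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-8)
  expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-8)
})

test_that("PGLS agrees with the nlme + ape reference implementation", {
  skip_if_not_installed("nlme")
  withr::with_seed(17, {
    tr <- random_ultrametric_tree(20)
    cfg <- simulation_config(n_tips = 20, seed = 17)
    grp <- setNames(rep("ectotherm", 20), tr$tip.label)
    tt <- simulate_allometric_traits(tr, cfg, groups = grp)
  })
  f <- fit_pgls(tt$x, tt$y, bm_covariance(tr))
  dat <- data.frame(x = tt$x, y = tt$y, species = tt$species)
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corBrownian(form = ~species, phy = tr))
  expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("a singular covariance produces an instructive error", {
  C <- matrix(1, 4, 4)
  expect_error(fit_pgls(rnorm(4) + 1:4, rnorm(4), C),
               class = "nasallom_error_singular")
})

test_that("noise-free data are recovered exactly by all three fitters", {
  cfg <- simulation_config(n_tips = 18, sigma_e2 = 0, slope_endo = 1.4,
                           slope_ecto = 1.4, intercept_endo = 2.5,
                           intercept_ecto = 2.5, seed = 21)
  tr <- simulate_tree(cfg)
  tt <- simulate_allometric_traits(tr, cfg)
  C <- bm_covariance(tr)
  for (f in list(fit_ols(tt$x, tt$y), fit_sma(tt$x, tt$y),
                 fit_pgls(tt$x, tt$y, C))) {
    expect_equal(f$slope, 1.4, tolerance = 1e-10)
    expect_equal(f$intercept, 2.5, tolerance = 1e-10)
  }
})

test_that("PGLS slope estimates are unbiased under Brownian residuals", {
  cfg <- simulation_config(n_tips = 30, seed = 6)
  tr <- simulate_tree(cfg)
  C <- bm_covariance(tr)
  Lx <- chol(C * cfg$sigma_x2)
  Le <- chol(C * cfg$sigma_e2)
  withr::with_seed(606, {
    slopes <- vapply(1:400, function(s) {
      x <- drop(crossprod(Lx, rnorm(30)))
      y <- 1 + 0.9 * x + drop(crossprod(Le, rnorm(30)))
      fit_pgls(x, y, C)$slope
    }, numeric(1))
  })
  bias <- mean(slopes) - 0.9
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(bias), 2 * mc_se + 1e-12)
})

test_that("fit accessors present tidy summaries", {
  withr::with_seed(9, {
    x <- rnorm(12); y <- 1 + x + rnorm(12, 0, 0.1)
  })
  f <- fit_ols(x, y)
  td <- tidy(f)
  expect_equal(td$term, c("intercept", "slope"))
  expect_true(all(td$std.error > 0))
  gl <- glance(f)
  expect_equal(gl$n, 12)
  expect_true(gl$r.squared <= 1 && gl$r.squared >= 0)
  expect_equal(predict(f, 2), f$intercept + 2 * f$slope)
})
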