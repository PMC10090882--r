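# Simulation experiments that characterise the testing scheme itself:
# type-I calibration of the slope/intercept tests and replication of the
# head-size-versus-body-mass contrast on synthetic data.

#' Type-I error calibration of the group tests
#'
#' Simulates data under the no-difference null on a fixed Yule tree with a
#' clade-structured group assignment and records how often each test
#' rejects at `alpha`. Each estimator is evaluated under its own model:
#' OLS and SMA tests get independent residuals, the PGLS tests get
#' Brownian residuals on the tree (evaluating OLS under phylogenetically
#' correlated residuals would measure the well-known confounding of
#' non-phylogenetic tests, not their calibration).
#'
#' @param n_sims number of null simulations per test.
#' @param n_tips tips on the simulated tree.
#' @param alpha nominal level.
#' @param seed RNG seed fixing the tree and all simulations.
#' @param config optional [simulation_config()] overriding the default
#'   rates.
#' @return tibble with `method`, `test`, `rate` (empirical type-I error)
#'   and `n_sims`.
#' @export
type1_calibration <- function(n_sims = 1000, n_tips = 50, alpha = 0.05,
                              seed = 1L, config = NULL) {
  if (is.null(config)) {
    config <- simulation_config(n_tips = n_tips, seed = seed)
  }
  tree <- simulate_tree(config)
  groups <- assign_groups(tree, "by_clade")
  C <- bm_covariance(tree)
  Lx <- chol(C * config$sigma_x2)
  Le <- chol(C * config$sigma_e2)
  n <- ape::Ntip(tree)
  sd_iid <- sqrt(config$sigma_e2 * config$tree_depth)
  base <- tibble::tibble(species = tree$tip.label,
                         thermo_class = unname(groups[tree$tip.label]))
  withr::local_seed(config$seed + 1000L)
  hits <- matrix(0, n_sims, 6)
  colnames(hits) <- c("ols_slope", "ols_intercept", "sma_slope",
                      "sma_intercept", "pgls_slope", "pgls_intercept")
  for (s in seq_len(n_sims)) {
    x <- 3 + drop(crossprod(Lx, rnorm(n)))
    d <- base
    d$x <- x
    d$y_iid <- 1 + 0.9 * x + rnorm(n, 0, sd_iid)
    d$y_bm <- 1 + 0.9 * x + drop(crossprod(Le, rnorm(n)))
    hits[s, ] <- c(
      test_slope_difference(d, "x", "y_iid", "ols")$p_value,
      test_intercept_difference(d, "x", "y_iid", "ols",
                                check_slopes = FALSE)$p_value,
      test_slope_difference(d, "x", "y_iid", "sma")$p_value,
      test_intercept_difference(d, "x", "y_iid", "sma",
                                check_slopes = FALSE)$p_value,
      test_slope_difference(d, "x", "y_bm", "pgls", tree = C)$p_value,
      test_intercept_difference(d, "x", "y_bm", "pgls", tree = C,
                                check_slopes = FALSE)$p_value) < alpha
  }
  tibble::tibble(
    method = rep(c("OLS", "SMA", "PGLS"), each = 2),
    test = rep(c("slope", "intercept"), 3),
    rate = colMeans(hits)[c("ols_slope", "ols_intercept", "sma_slope",
                            "sma_intercept", "pgls_slope", "pgls_intercept")],
    n_sims = n_sims)
}

#' Replicate the head-size versus body-mass contrast on synthetic data
#'
#' Repeatedly generates a full synthetic study (head-size-linked clade
#' offset, body-mass relations null by construction), runs the PGLS
#' comparison grid, and scores each run: `head_ok` when every head-size
#' cell (skull and hull, surface area and volume) shows a significant
#' difference, `mass_ok` when no body-mass cell does (neither slope nor
#' conditional intercept test rejects).
#'
#' @param n_runs number of independent synthetic studies.
#' @param n_tips species per study.
#' @param seed base seed; run `i` uses `seed + i`.
#' @param head_offset clade offset of log10 skull volume at a given mass.
#' @param alpha significance level.
#' @return tibble with one row per run: `head_ok`, `mass_ok`, and the
#'   counts of significant head and mass cells.
#' @export
qualitative_contrast <- function(n_runs = 200, n_tips = 50, seed = 1L,
                                 head_offset = -0.3, alpha = 0.05) {
  purrr::map_dfr(seq_len(n_runs), function(i) {
    st <- simulate_specimen_table(
      simulation_config(n_tips = n_tips, seed = seed + i),
      head_offset = head_offset)
    rep <- run_full_analysis(st$records, st$tree,
                             analysis_config(methods = "pgls",
                                             alpha = alpha))
    cmp <- rep$comparisons
    sig <- cmp$slope_p < alpha |
      (cmp$intercept_tested & cmp$intercept_p < alpha)
    is_mass <- cmp$size_var == "body_mass_g"
    tibble::tibble(
      run = i,
      n_head_sig = sum(sig[!is_mass]),
      n_head = sum(!is_mass),
      n_mass_sig = sum(sig[is_mass]),
      n_mass = sum(is_mass),
      head_ok = all(sig[!is_mass]),
      mass_ok = !any(sig[is_mass]))
  })
}
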