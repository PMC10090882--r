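#' Configuration for the synthetic allometry generator
#'
#' Bundles the generative conditions for the synthetic comparative data:
#' a Yule tree of `n_tips` species rescaled to `tree_depth`, a Brownian
#' size trait with rate `sigma_x2`, and group-specific log--log allometries
#' `y = intercept_g + slope_g * x + e` with residuals that are either
#' Brownian (rate `sigma_e2`, the PGLS model assumption, the default) or
#' i.i.d. normal with the same tip variance.
#'
#' Defaults mirror an amniote-scale study: 47 species, 300 Ma deep tree,
#' a size trait spanning roughly three orders of magnitude
#' (`sigma_x2 * tree_depth` close to 2 log10 units squared), tight residual
#' scatter (`sigma_e2 * tree_depth` around 0.0015, residual s.d. near 0.04
#' log10 units), and a single endothermic subclade.
#'
#' @param n_tips number of species (at least 4 for group comparisons).
#' @param birth_rate Yule speciation rate per Ma (shape only; depth is
#'   rescaled).
#' @param tree_depth root-to-tip depth in Ma.
#' @param group_assignment `"by_clade"` (one subclade, sized as close to
#'   half the tips as possible, forms the endotherm group: the hard,
#'   phylogenetically confounded case) or `"random"`.
#' @param slope_endo,slope_ecto dimensionless log--log slopes.
#' @param intercept_endo,intercept_ecto intercepts in log10 units.
#' @param sigma_x2,sigma_e2 Brownian rates (log10-units squared per Ma) of
#'   the size trait and the residual.
#' @param residuals `"bm"` or `"iid"`.
#' @param n_conspecific specimens per species (applied to every species when
#'   > 1; see [simulate_specimen_table()] for partial expansion).
#' @param seed integer seed fixing all randomness end-to-end.
#' @return a list of class `nasallom_sim_config`.
#' @export
simulation_config <- function(n_tips = 47,
                              birth_rate = 0.05,
                              tree_depth = 300,
                              group_assignment = c("by_clade", "random"),
                              slope_endo = 0.9,
                              slope_ecto = 0.9,
                              intercept_endo = 3.9,
                              intercept_ecto = 3.6,
                              sigma_x2 = 0.007,
                              sigma_e2 = 5e-6,
                              residuals = c("bm", "iid"),
                              n_conspecific = 1,
                              seed = 1L) {
  if (!is.numeric(n_tips) || n_tips < 4) {
    abort("`n_tips` must be at least 4", class = "nasallom_error_config")
  }
  assert_positive_scalar(birth_rate, "birth_rate")
  assert_positive_scalar(tree_depth, "tree_depth")
  assert_nonnegative(sigma_x2, "sigma_x2")
  assert_nonnegative(sigma_e2, "sigma_e2")
  if (n_conspecific < 1) {
    abort("`n_conspecific` must be at least 1", class = "nasallom_error_config")
  }
  structure(list(
    n_tips = as.integer(n_tips),
    birth_rate = birth_rate,
    tree_depth = tree_depth,
    group_assignment = match.arg(group_assignment),
    slope_endo = slope_endo, slope_ecto = slope_ecto,
    intercept_endo = intercept_endo, intercept_ecto = intercept_ecto,
    sigma_x2 = sigma_x2, sigma_e2 = sigma_e2,
    residuals = match.arg(residuals),
    n_conspecific = as.integer(n_conspecific),
    seed = as.integer(seed)
  ), class = "nasallom_sim_config")
}

#' Assign endotherm/ectotherm groups to tree tips
#'
#' `"by_clade"` picks the internal node whose clade size is closest to half
#' the tips (ties broken toward the shallower node) and calls its tips
#' endotherms, mimicking the single phylogenetic origin of endothermy --
#' the hardest case for between-group tests. `"random"` assigns half the
#' tips at random.
#'
#' @param tree a `phylo` tree.
#' @param method `"by_clade"` or `"random"`.
#' @return character vector `"endotherm"`/`"ectotherm"` named by tip label.
#' @export
assign_groups <- function(tree, method = c("by_clade", "random")) {
  method <- match.arg(method)
  ntip <- ape::Ntip(tree)
  if (method == "random") {
    pick <- sample(ntip, floor(ntip / 2))
  } else {
    nodes <- (ntip + 2L):(ntip + tree$Nnode)   # internal nodes except root
    sizes <- vapply(nodes, function(nd) length(tips_under(tree, nd)), 1L)
    depth <- node_depths(tree)
    best <- nodes[order(abs(sizes - ntip / 2), depth[nodes])][1]
    pick <- tips_under(tree, best)
  }
  grp <- rep("ectotherm", ntip)
  grp[pick] <- "endotherm"
  setNames(grp, tree$tip.label)
}

# tip indices descending from node `nd`
tips_under <- function(tree, nd) {
  ntip <- ape::Ntip(tree)
  if (nd <= ntip) return(nd)
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Simulate group-specific allometric traits on a tree
#'
#' Per tip, the size trait `x` evolves by Brownian motion with rate
#' `sigma_x2` from a root value; an independent residual `e` is Brownian
#' with rate `sigma_e2` (or i.i.d. with the same tip variance), and
#' `y = intercept_g + slope_g * x + e` for the tip's group. Both the log10
#' values and the back-transformed raw values are returned.
#'
#' @param tree an ultrametric `phylo` tree.
#' @param config a [simulation_config()].
#' @param groups optional named group vector as from [assign_groups()];
#'   generated from `config$group_assignment` when `NULL`.
#' @param x_root root value of the size trait (log10 units).
#' @return tibble with columns `species`, `group`, `x`, `e`, `y`, `x_raw`,
#'   `y_raw`.
#' @export
simulate_allometric_traits <- function(tree, config, groups = NULL,
                                       x_root = 3) {
  withr::local_seed(config$seed + 1L)
  if (is.null(groups)) groups <- assign_groups(tree, config$group_assignment)
  if (!all(tree$tip.label %in% names(groups))) {
    abort("every tip needs a group label", class = "nasallom_error_config")
  }
  groups <- groups[tree$tip.label]
  if (anyNA(groups)) {
    abort("every tip needs a group label", class = "nasallom_error_config")
  }
  x <- simulate_bm(tree, config$sigma_x2, root = x_root)
  depth <- max(node_depths(tree)[seq_len(ape::Ntip(tree))])
  e <- if (config$residuals == "bm") {
    simulate_bm(tree, config$sigma_e2, root = 0)
  } else {
    setNames(rnorm(ape::Ntip(tree), 0, sqrt(config$sigma_e2 * depth)),
             tree$tip.label)
  }
  slope <- ifelse(groups == "endotherm", config$slope_endo, config$slope_ecto)
  intercept <- ifelse(groups == "endotherm", config$intercept_endo,
                      config$intercept_ecto)
  y <- intercept + slope * x + e
  tibble::tibble(
    species = tree$tip.label,
    group = unname(groups),
    x = unname(x), e = unname(e), y = unname(y),
    x_raw = 10^unname(x), y_raw = 10^unname(y)
  )
}

#' Simulate a full specimen measurement table
#'
#' Emulates the empirical design of a nasal-allometry study: body mass
#' evolves by Brownian motion; skull volume follows mass isometrically with
#' a clade-linked offset (`head_offset`, endotherm minus ectotherm, log10
#' units -- endotherm heads are smaller for their mass when negative, which
#' makes the nasal cavity relatively larger for their head); the convex-hull
#' head model sits a fixed amount above the skull; nasal surface area and
#' volume follow body mass with *no* group term, so all mass comparisons
#' are null by construction while head-size comparisons carry the offset;
#' and the respiratory region is a roughly constant fraction of the whole
#' cavity. Surface-area and volume residuals are strongly coupled (area
#' deviations are 2/3 of volume deviations plus a small independent part),
#' as they are when both are measured on one segmented cavity.
#'
#' A subclade of the endotherm group is labelled `Mammalia` (the rest
#' `Aves`; ectotherms `Lepidosauria`) so that clade-exclusion rules can be
#' exercised.
#'
#' @param config a [simulation_config()]; `slope_endo`/`intercept_endo`
#'   fields are not used here (this generator has its own response
#'   parameters, below).
#' @param head_offset clade offset of log10 skull volume at a given mass
#'   (default -0.3).
#' @param beta_vol,beta_sa log--log slopes of nasal volume and surface area
#'   against body mass (defaults 0.9, 0.6).
#' @param alpha_vol,alpha_sa intercepts at the root mass (log10 mm^3 / mm^2).
#' @param resp_fraction typical respiratory share of the whole cavity volume.
#' @param n_multi number of species given `config$n_conspecific` specimens
#'   (the rest get one); default 0 unless `n_conspecific > 1`, then 3.
#' @return list with `records` (tibble in the measurement-table schema plus
#'   `group`), `tree` (species-level tree), `specimen_tree` (after
#'   [expand_conspecific_tips()]), and `groups`.
#' @export
simulate_specimen_table <- function(config = simulation_config(),
                                    head_offset = -0.3,
                                    beta_vol = 0.9, beta_sa = 0.6,
                                    alpha_vol = 3.6, alpha_sa = 3.3,
                                    resp_fraction = 0.55,
                                    n_multi = if (config$n_conspecific > 1) 3 else 0) {
  tree <- simulate_tree(config)
  withr::local_seed(config$seed + 2L)
  groups <- assign_groups(tree, config$group_assignment)
  n <- ape::Ntip(tree)
  x_root <- 3
  mass <- simulate_bm(tree, config$sigma_x2, root = x_root)
  e_vol <- simulate_bm(tree, config$sigma_e2)
  e_sa <- (2 / 3) * e_vol + simulate_bm(tree, config$sigma_e2 / 25)
  u_skull <- simulate_bm(tree, config$sigma_e2 / 4)
  u_hull <- simulate_bm(tree, config$sigma_e2 / 25)
  u_resp <- simulate_bm(tree, config$sigma_e2 / 25)

  endo <- groups[tree$tip.label] == "endotherm"
  gamma <- ifelse(endo, head_offset, 0)
  log_skull <- 5 + gamma + 1.0 * (mass - x_root) + u_skull
  log_hull <- log_skull + 0.18 + u_hull
  log_nv <- alpha_vol + beta_vol * (mass - x_root) + e_vol
  log_ns <- alpha_sa + beta_sa * (mass - x_root) + e_sa
  log_rv <- log_nv + log10(resp_fraction) + u_resp
  log_rs <- log_ns + log10(resp_fraction + 0.05) + u_resp

  # clade labels: a subclade of the endotherms becomes Mammalia
  clade <- ifelse(endo, "Aves", "Lepidosauria")
  if (sum(endo) >= 4) {
    endo_tips <- which(endo)
    sub <- assign_groups(ape::keep.tip(tree, endo_tips), "by_clade")
    mam <- names(sub)[sub == "endotherm"]
    clade[match(mam, tree$tip.label)] <- "Mammalia"
  }

  species <- tree$tip.label
  rec <- tibble::tibble(
    species = species,
    clade = clade,
    thermo_class = unname(groups[species]),
    log_mass = unname(mass),
    log_skull = unname(log_skull), log_hull = unname(log_hull),
    log_nasal_sa = unname(log_ns), log_nasal_vol = unname(log_nv),
    log_resp_sa = unname(log_rs), log_resp_vol = unname(log_rv)
  )

  # conspecific expansion: first `n_multi` species get extra specimens with
  # specimen-level deviations matching 1 Ma of Brownian divergence
  k <- config$n_conspecific
  multi_sp <- head(species, if (k > 1) n_multi else 0)
  rec$n_copies <- ifelse(rec$species %in% multi_sp, k, 1L)
  rec <- tidyr::uncount(rec, .data$n_copies)
  rec <- dplyr::group_by(rec, .data$species)
  rec <- dplyr::mutate(rec,
    specimen_id = if (dplyr::n() > 1) paste0(.data$species, "_s", dplyr::row_number())
                  else .data$species)
  rec <- dplyr::ungroup(rec)
  dev_cols <- c("log_mass", "log_skull", "log_hull", "log_nasal_sa",
                "log_nasal_vol", "log_resp_sa", "log_resp_vol")
  multi_rows <- rec$species %in% multi_sp
  if (any(multi_rows)) {
    sdev <- sqrt(config$sigma_e2 * 1)   # 1 Ma of divergence
    for (cl in dev_cols) {
      rec[[cl]][multi_rows] <- rec[[cl]][multi_rows] +
        rnorm(sum(multi_rows), 0, sdev)
    }
  }

  records <- tibble::tibble(
    species = rec$species,
    specimen_id = rec$specimen_id,
    clade = rec$clade,
    thermo_class = rec$thermo_class,
    body_mass_g = 10^rec$log_mass,
    skull_vol_mm3 = 10^rec$log_skull,
    hull_vol_mm3 = 10^rec$log_hull,
    nasal_sa_mm2 = 10^rec$log_nasal_sa,
    nasal_vol_mm3 = 10^rec$log_nasal_vol,
    resp_sa_mm2 = 10^rec$log_resp_sa,
    resp_vol_mm3 = 10^rec$log_resp_vol
  )
  spec_tree <- expand_conspecific_tips(
    tree, records[, c("species", "specimen_id")])
  list(records = records, tree = tree, specimen_tree = spec_tree,
       groups = groups)
}
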