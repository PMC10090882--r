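#' Simulate an ultrametric pure-birth tree
#'
#' Generates a Yule (pure-birth) tree conditioned on the number of extant
#' tips and rescales it so every root-to-tip path equals `tree_depth`.
#' This is the stand-in for a time-calibrated phylogeny: depth is controlled
#' directly, the topology and relative node heights come from the Yule
#' process.
#'
#' @param config a [simulation_config()] list; `n_tips`, `birth_rate`,
#'   `tree_depth` and `seed` are used.
#' @return an ultrametric `phylo` tree with tips `t1 ... tn`, branch lengths
#'   in Ma.
#' @examples
#' tr <- simulate_tree(simulation_config(n_tips = 8, seed = 1))
#' @export
simulate_tree <- function(config) {
  n <- config$n_tips
  if (!is.numeric(n) || n < 2) {
    abort("`n_tips` must be at least 2 to form a tree",
          class = "nasallom_error_config")
  }
  withr::local_seed(config$seed)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);", config$tree_depth,
                                        config$tree_depth))
    return(tr)
  }
  tr <- ape::rphylo(n, birth = config$birth_rate, death = 0)
  depth <- max(node_depths(tr)[seq_len(ape::Ntip(tr))])
  tr$edge.length <- tr$edge.length * (config$tree_depth / depth)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

#' Root-to-node path lengths
#'
#' @param tree a rooted `phylo` tree.
#' @return numeric vector over all nodes (tips first, in `tip.label` order),
#'   giving the summed branch length from the root.
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(nnode)
  root <- ape::Ntip(tree) + 1L
  depth[root] <- 0
  for (i in seq_len(nrow(tree$edge))) {
    depth[tree$edge[i, 2]] <- depth[tree$edge[i, 1]] + tree$edge.length[i]
  }
  depth
}

#' Is a tree ultrametric?
#'
#' All root-to-tip path lengths equal within `tol * depth` (relative).
#'
#' @param tree a rooted `phylo` tree.
#' @param tol relative tolerance.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol * max(d)
}

#' Brownian-motion trait covariance implied by a tree
#'
#' Under Brownian motion with unit rate, the covariance of trait values at
#' two tips equals the branch length shared by their root-to-tip paths, i.e.
#' the depth of their most recent common ancestor; the variance at a tip is
#' its root-to-tip depth.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return symmetric positive semidefinite matrix (tips x tips), dimnames
#'   from `tip.label`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
#' bm_covariance(tr)  # shared path of A,B is 2; of A,C is 0
#' @export
bm_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be a `phylo` object", class = "nasallom_error_tree")
  }
  if (is.null(tree$edge.length)) {
    abort("`tree` has no branch lengths", class = "nasallom_error_tree")
  }
  if (!ape::is.rooted(tree)) {
    abort("`tree` must be rooted", class = "nasallom_error_tree")
  }
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  anc <- ape::mrca(tree)           # tip x tip matrix of MRCA node ids
  C <- matrix(depth[anc], ntip, ntip)
  diag(C) <- depth[seq_len(ntip)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

#' Expand multi-specimen species into 1-Ma polytomies
#'
#' PGLS accommodates one operational taxonomic unit per tip, so species
#' represented by several specimens are expanded: the species tip is replaced
#' by a polytomy whose pendant branches to the individual specimens are 1 Ma
#' long, and the stem is shortened by 1 Ma so all tip depths (and therefore
#' ultrametricity) are preserved.
#'
#' @param tree a `phylo` tree whose tips are species names.
#' @param specimens data frame with columns `species` and `specimen_id`.
#'   Species appearing once keep their original tip untouched.
#' @param pendant_length branch length (Ma) assigned to each specimen,
#'   default 1.
#' @return a `phylo` tree; tips of expanded species are the specimen ids.
#' @export
expand_conspecific_tips <- function(tree, specimens, pendant_length = 1) {
  stopifnot(inherits(tree, "phylo"))
  specimens <- tibble::as_tibble(specimens)
  if (!all(c("species", "specimen_id") %in% names(specimens))) {
    abort("`specimens` needs columns `species` and `specimen_id`",
          class = "nasallom_error_config")
  }
  counts <- table(specimens$species)
  multi <- names(counts)[counts > 1]
  missing <- setdiff(multi, tree$tip.label)
  if (length(missing)) {
    abort(paste("multi-specimen species not on the tree:",
                paste(missing, collapse = ", ")),
          class = "nasallom_error_tree")
  }
  for (sp in multi) {
    tip <- match(sp, tree$tip.label)
    term_edge <- which(tree$edge[, 2] == tip)
    stem <- tree$edge.length[term_edge]
    if (stem <= pendant_length) {
      abort(sprintf(
        "terminal branch of '%s' (%.3g Ma) is not longer than the pendant length (%g Ma)",
        sp, stem, pendant_length), class = "nasallom_error_tree")
    }
    ids <- specimens$specimen_id[specimens$species == sp]
    txt <- sprintf("(%s);",
                   paste(sprintf("%s:%.10g", ids, pendant_length),
                         collapse = ","))
    sub <- ape::read.tree(text = txt)
    # bind.tree grafts after the full terminal edge, so shorten it first
    tree$edge.length[term_edge] <- stem - pendant_length
    tree <- ape::bind.tree(tree, sub, where = tip)
  }
  tree
}

# simulate one Brownian trait on the tips of `tree`, rate sigma2, from
# root value `root`; assumes the caller manages the RNG seed
simulate_bm <- function(tree, sigma2, root = 0) {
  n <- ape::Ntip(tree)
  if (sigma2 == 0) {
    return(setNames(rep(root, n), tree$tip.label))
  }
  C <- bm_covariance(tree) * sigma2
  L <- chol(C + diag(1e-12 * max(diag(C)), n))
  setNames(root + drop(crossprod(L, rnorm(n))), tree$tip.label)
}
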