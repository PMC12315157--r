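# Variation operators: tournament selection, typed subtree crossover,
# typed mutation.

#' @noRd
is_concat_root <- function(node) node$name %in% c("root2", "root3", "root4")

#' Tournament selection
#'
#' Best of `k` uniform draws with replacement; fitness ties are broken in
#' favour of the smaller tree.
#'
#' @param population list of individuals (`$tree`, `$fitness`).
#' @param k tournament size.
#' @param fitness_fn `"R2"` (maximised) or `"MSE"` (minimised).
#' @return the winning individual.
#' @export
gp_tournament <- function(population, k = 4, fitness_fn = "R2") {
  idx <- sample.int(length(population), k, replace = TRUE)
  best <- NULL
  for (i in idx) {
    cand <- population[[i]]
    if (is.null(best) ||
        fitness_better(cand$fitness, best$fitness, fitness_fn) ||
        (cand$fitness == best$fitness &&
         tree_size(cand$tree) < tree_size(best$tree))) {
      best <- cand
    }
  }
  best
}

#' Typed subtree crossover
#'
#' Swaps subtrees rooted at two non-leaf nodes of identical output type.
#' Concatenation roots only pair with concatenation roots (so roots never
#' nest). Offspring exceeding the depth cap cause a retry (up to
#' `max_tries`); if no legal swap is found the parents are returned
#' unchanged.
#'
#' @param tree_a,tree_b parent trees (same structure).
#' @param fset the [gp_function_set()].
#' @param max_depth depth cap for offspring.
#' @param max_tries retry budget.
#' @return list of two trees.
#' @export
gp_crossover <- function(tree_a, tree_b, fset, max_depth, max_tries = 5) {
  # identical parents carry identical genetic material: exchanging it is a
  # no-op, so return them unchanged (and save the search for swap points)
  if (identical(tree_a, tree_b)) return(list(tree_a, tree_b))
  nodes_a <- Filter(function(r) !is_leaf(r$node), tree_nodes(tree_a))
  nodes_b <- Filter(function(r) !is_leaf(r$node), tree_nodes(tree_b))
  # a node is legal at the root only if it is a concatenation/conversion
  # primitive, and legal in an interior slot only if it is not an
  # arity-2..4 concatenation
  fits_slot <- function(node, at_root) {
    if (at_root) node$name %in% fset$roots else !is_concat_root(node)
  }
  for (try in seq_len(max_tries)) {
    ra <- nodes_a[[sample.int(length(nodes_a), 1L)]]
    at_root_a <- !length(ra$path)
    compat <- Filter(function(r)
      r$node$type == ra$node$type &&
        fits_slot(r$node, at_root_a) &&
        fits_slot(ra$node, !length(r$path)), nodes_b)
    if (!length(compat)) next
    rb <- compat[[sample.int(length(compat), 1L)]]
    child_a <- tree_set(tree_a, ra$path, rb$node)
    child_b <- tree_set(tree_b, rb$path, ra$node)
    if (tree_depth(child_a) <= max_depth && tree_depth(child_b) <= max_depth)
      return(list(child_a, child_b))
  }
  list(tree_a, tree_b)
}

#' Typed mutation
#'
#' With probability `p_nonleaf` (0.75) a non-leaf node is chosen and its
#' subtree regrown with the grow method inside the remaining depth budget;
#' otherwise a leaf is chosen and, if it is a parameter terminal, its
#' value is re-sampled within the terminal's range (the input leaf is left
#' as is).
#'
#' @param tree parent tree.
#' @param fset the [gp_function_set()].
#' @param max_depth depth cap.
#' @param p_nonleaf probability of picking a non-leaf mutation point.
#' @return mutated tree (type-correct, depth-legal).
#' @export
gp_mutate <- function(tree, fset, max_depth, p_nonleaf = 0.75) {
  recs <- tree_nodes(tree)
  nonleaf <- Filter(function(r) !is_leaf(r$node), recs)
  leaf <- Filter(function(r) is_leaf(r$node), recs)
  use_nonleaf <- runif(1L) < p_nonleaf || !length(leaf)
  if (use_nonleaf) {
    r <- nonleaf[[sample.int(length(nonleaf), 1L)]]
    if (!length(r$path)) {
      # regrowing at the root: draw a whole fresh tree
      return(gp_generate(fset, "grow", c(fset$min_root_depth, max_depth)))
    }
    budget <- max_depth - r$level + 1L
    lo <- unname(fset$min_depth[r$node$type])
    target <- if (budget <= lo) lo else sample(lo:budget, 1L)
    sub <- gp_grow_subtree(r$node$type, 1L, target, fset, "grow")
    tree_set(tree, r$path, sub)
  } else {
    r <- leaf[[sample.int(length(leaf), 1L)]]
    if (r$node$kind != "term") return(tree)        # input leaf: unchanged
    tree_set(tree, r$path, gp_sample_terminal(r$node$type, fset))
  }
}
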