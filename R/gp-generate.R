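# Tree generation: ramped half-and-half under per-type depth budgets.
#
# Depth is counted in levels with the root at level 1; a tree of target
# depth d places leaves at level d (grow: at most d). Each recursive call
# knows how many levels remain and only picks primitives whose argument
# types can still be completed within that budget (the per-type height
# budget), which forces every branch to transition toward the input and
# parameter terminals before the limit. For the full method, primitives
# that consume the program input (interval selection on the raw input,
# mean-spectrum extraction) are only eligible at level target - 1, keeping
# the tree as full as the type system allows.

#' Generate a random typed program tree
#'
#' @param fset a [gp_function_set()].
#' @param method `"grow"` or `"full"`.
#' @param depth_range integer (min, max) target depth; the target is drawn
#'   uniformly from it (ramping).
#' @param target optional fixed target depth (overrides `depth_range`).
#' @return a type-correct GP tree of depth `<=` the sampled target.
#' @export
gp_generate <- function(fset, method = c("grow", "full"),
                        depth_range = c(3, 6), target = NULL) {
  method <- match.arg(method)
  if (is.null(target))
    target <- sample(depth_range[1L]:depth_range[2L], 1L)
  roots <- Filter(function(nm) {
    p <- fset$prims[[nm]]
    all(fset$min_depth[p$args] <= target - 1L)
  }, fset$roots)
  if (!length(roots))
    stop("no root primitive can complete a tree of depth ", target)
  nm <- if (length(roots) == 1L) roots else sample(roots, 1L)
  p <- fset$prims[[nm]]
  children <- lapply(p$args, function(t)
    gp_grow_subtree(t, 2L, target, fset, method))
  list(kind = "prim", name = nm, type = p$ret, value = NULL,
       children = children)
}

#' @noRd
gp_grow_subtree <- function(type, level, target, fset, method) {
  if (type %in% GP_PARAM_TYPES) return(gp_sample_terminal(type, fset))
  if (type == fset$input_type) return(gp_input_node(fset))
  rem <- target - level + 1L
  cands <- Filter(function(nm) {
    p <- fset$prims[[nm]]
    1L + max(fset$min_depth[p$args]) <= rem
  }, fset$by_ret[[type]])
  if (!length(cands))
    stop("no primitive of type ", type, " fits in ", rem, " levels")
  if (method == "full") {
    # keep fullness: before the pre-terminal level avoid input-consuming
    # primitives and require an argument chain able to reach the target
    preferred <- Filter(function(nm) {
      p <- fset$prims[[nm]]
      if (level < target - 1L && p$input_consuming) return(FALSE)
      any(fset$max_reach[p$args] >= rem - 1L)
    }, cands)
    if (length(preferred)) cands <- preferred
  }
  nm <- if (length(cands) == 1L) cands else sample(cands, 1L)
  p <- fset$prims[[nm]]
  children <- lapply(p$args, function(t)
    gp_grow_subtree(t, level + 1L, target, fset, method))
  list(kind = "prim", name = nm, type = p$ret, value = NULL,
       children = children)
}

#' Ramped half-and-half population initialisation
#'
#' Each individual uses the full or grow method with equal probability and
#' a target depth drawn uniformly from `depth_range`.
#'
#' @param n population size.
#' @param fset a [gp_function_set()].
#' @param depth_range integer (min, max) initial depth.
#' @return list of `n` trees.
#' @export
gp_init_population <- function(n, fset, depth_range = c(3, 6)) {
  lapply(seq_len(n), function(i) {
    m <- if (runif(1L) < 0.5) "full" else "grow"
    gp_generate(fset, m, depth_range)
  })
}
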