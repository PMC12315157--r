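# Tree utilities: traversal, depth/size, type checking, serialisation.

#' @noRd
is_leaf <- function(node) is.null(node$children) || !length(node$children)

#' Depth of a program tree in levels (root = 1)
#' @param tree a GP tree node.
#' @return integer depth.
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + max(vapply(tree$children, tree_depth, 0L))
}

#' Number of nodes in a program tree
#' @param tree a GP tree node.
#' @return integer node count.
#' @export
tree_size <- function(tree) {
  if (is_leaf(tree)) return(1L)
  1L + sum(vapply(tree$children, tree_size, 0L))
}

# Flatten a tree into a list of records (node, path, level); path is an
# integer vector of child indices from the root (length 0 = root).
#' @noRd
tree_nodes <- function(tree, path = integer(), level = 1L) {
  rec <- list(list(node = tree, path = path, level = level))
  if (!is_leaf(tree)) {
    for (i in seq_along(tree$children)) {
      rec <- c(rec, tree_nodes(tree$children[[i]], c(path, i), level + 1L))
    }
  }
  rec
}

#' @noRd
tree_get <- function(tree, path) {
  for (i in path) tree <- tree$children[[i]]
  tree
}

#' @noRd
tree_set <- function(tree, path, sub) {
  if (!length(path)) return(sub)
  tree$children[[path[1L]]] <- tree_set(tree$children[[path[1L]]],
                                        path[-1L], sub)
  tree
}

#' Type-check a program tree
#'
#' Verifies that every node's children match its primitive signature, that
#' terminal values lie within their ranges, that concatenation roots
#' (root2/3/4) appear only at the root, and that the tree's return type is
#' FV.
#'
#' @param tree a GP tree.
#' @param fset the [gp_function_set()] it was built from.
#' @param max_depth optional depth cap to verify.
#' @return TRUE, or FALSE with attribute `"reason"`.
#' @export
gp_typecheck <- function(tree, fset, max_depth = NULL) {
  fail <- function(why) structure(FALSE, reason = why)
  if (tree$type != "FV") return(fail("root type is not FV"))
  if (!(tree$name %in% fset$roots) )
    return(fail("root is not a concatenation/conversion primitive"))
  if (!is.null(max_depth) && tree_depth(tree) > max_depth)
    return(fail("depth exceeds maximum"))
  check <- function(node, at_root) {
    if (node$kind == "input") {
      if (node$type != fset$input_type) return(fail("wrong input type"))
      return(TRUE)
    }
    if (node$kind == "term") {
      ok <- switch(node$type,
        LAMBDA = node$value >= 1 && node$value <= fset$n_bands &&
          node$value == round(node$value),
        W = node$value %in% VALID_WIDTHS,
        SIGMA = node$value > 0 && node$value <= 5,
        K = node$value %in% VALID_KERNELS,
        THETA = min(abs(node$value - GABOR_THETAS)) < 1e-8,
        F = min(abs(node$value - GABOR_FREQS)) < 1e-8,
        THETAG = min(abs(node$value - GLCM_ANGLES)) < 1e-8,
        D = node$value %in% GLCM_DISTANCES,
        FALSE)
      if (!isTRUE(ok)) return(fail(paste("terminal out of range:",
                                         node$type)))
      return(TRUE)
    }
    p <- fset$prims[[node$name]]
    if (is.null(p)) return(fail(paste("unknown primitive:", node$name)))
    if (!at_root && node$name %in% setdiff(fset$roots, "to_fv"))
      return(fail("nested concatenation root"))
    if (p$ret != node$type) return(fail("node type != primitive return"))
    if (length(node$children) != length(p$args))
      return(fail(paste("arity mismatch at", node$name)))
    for (i in seq_along(p$args)) {
      ch <- node$children[[i]]
      if (ch$type != p$args[i])
        return(fail(sprintf("arg %d of %s: %s != %s", i, node$name,
                            ch$type, p$args[i])))
      r <- check(ch, at_root = FALSE)
      if (!isTRUE(r)) return(r)
    }
    TRUE
  }
  check(tree, at_root = TRUE)
}

#' Serialise a program tree as an s-expression
#'
#' @param tree a GP tree.
#' @param digits significant digits for real-valued terminals.
#' @return character scalar, e.g.
#'   `"to_fv(s_int_mean(input_spectra, lambda=42, w=5))"`.
#' @export
tree_to_string <- function(tree, digits = 4) {
  if (tree$kind == "input") return(tree$name)
  if (tree$kind == "term") {
    lab <- tolower(tree$type)
    v <- if (tree$type %in% c("SIGMA", "THETA", "F", "THETAG"))
      signif(tree$value, digits) else tree$value
    return(paste0(lab, "=", v))
  }
  paste0(tree$name, "(",
         paste(vapply(tree$children, tree_to_string, "", digits = digits),
               collapse = ", "), ")")
}
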