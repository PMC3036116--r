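#' Trees of normal individuals
#'
#' A normal tree is a rooted tree of phenotypically normal individuals: the
#' root is a normal child of an obligate carrier, its children are the root's
#' own offspring, and so on; leaves are childless.  Its likelihood
#' contribution is a polynomial in the penetrance K computed by the recursion
#' in [tree_term()].
#'
#' @param children list of \code{normal_tree} nodes (empty for a leaf).
#' @param id optional individual id carried for reporting; trees read from a
#'   counts file are anonymous.
#' @return an object of class \code{normal_tree}.
#' @export
#' @examples
#' # a 2-generation tree with three children
#' two_gen_tree(3)
#' # a ragged 3-generation tree
#' normal_tree(list(two_gen_tree(2), normal_tree()))
normal_tree <- function(children = list(), id = NA_character_) {
  stopifnot(is.list(children))
  for (ch in children) {
    if (!inherits(ch, "normal_tree")) stop("children must be normal_tree nodes")
  }
  structure(list(id = as.character(id), children = children),
            class = "normal_tree")
}

#' @rdname normal_tree
#' @param n number of (childless) second-generation individuals.
#' @export
two_gen_tree <- function(n, id = NA_character_) {
  stopifnot(n >= 1L)
  normal_tree(replicate(n, normal_tree(), simplify = FALSE), id = id)
}

#' @rdname normal_tree
#' @param tree a \code{normal_tree}.
#' @export
tree_depth <- function(tree) {
  if (length(tree$children) == 0L) return(1L)
  1L + max(vapply(tree$children, tree_depth, integer(1)))
}

#' @rdname normal_tree
#' @export
tree_size <- function(tree) {
  1L + sum(vapply(tree$children, tree_size, integer(1)))
}

tree_member_ids <- function(tree) {
  c(tree$id, unlist(lapply(tree$children, tree_member_ids)))
}

# Compact serialization used by the counts dialect: a node whose children are
# all leaves is written as the integer count of its children (0 = leaf);
# otherwise as a parenthesized comma-separated list of its children.
tree_to_string <- function(tree) {
  if (length(tree$children) == 0L) return("0")
  if (all(vapply(tree$children, function(c) length(c$children) == 0L,
                 logical(1)))) {
    return(as.character(length(tree$children)))
  }
  paste0("(", paste(vapply(tree$children, tree_to_string, character(1)),
                    collapse = ","), ")")
}

tree_from_string <- function(s) {
  s <- gsub("\\s", "", s)
  pos <- 1L
  peek <- function() if (pos <= nchar(s)) substr(s, pos, pos) else ""
  parse_node <- function() {
    ch <- peek()
    if (ch == "(") {
      pos <<- pos + 1L
      children <- list()
      repeat {
        children[[length(children) + 1L]] <- parse_node()
        ch <- peek()
        if (ch == ",") { pos <<- pos + 1L; next }
        if (ch == ")") { pos <<- pos + 1L; break }
        stop("tree parse error in '", s, "' at position ", pos)
      }
      normal_tree(children)
    } else if (grepl("[0-9]", ch)) {
      m <- regmatches(substr(s, pos, nchar(s)),
                      regexpr("^[0-9]+", substr(s, pos, nchar(s))))
      pos <<- pos + nchar(m)
      n <- as.integer(m)
      if (n == 0L) normal_tree() else two_gen_tree(n)
    } else {
      stop("tree parse error in '", s, "' at position ", pos)
    }
  }
  node <- parse_node()
  if (pos <= nchar(s)) stop("tree parse error: trailing input in '", s, "'")
  node
}

#' @export
print.normal_tree <- function(x, ...) {
  cat("Normal tree (depth ", tree_depth(x), ", ", tree_size(x),
      " individuals): ", tree_to_string(x), "\n", sep = "")
  invisible(x)
}
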