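## Species-tree input, validation, rooting and depth geometry.
##
## Trees are represented as ape "phylo" objects with branch lengths in
## nucleotide substitutions per site. Downstream inference requires a rooted
## tree; unrooted input can be rooted with midpoint_root_ls().

#' Parse a Newick string into a validated tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' rest of the pipeline relies on: every edge must carry a finite,
#' non-negative branch length and tip labels must be unique. Square-bracket
#' comments are stripped before parsing. Malformed strings raise an error
#' naming the character offset of the first unbalanced bracket (or the
#' missing terminal semicolon).
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an object of class `phylo`.
#' @seealso [read_newick()], [write_newick()], [midpoint_root_ls()]
#' @examples
#' tr <- parse_newick("((A:0.01,B:0.02):0.005,C:0.03);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("\\[[^]]*\\]", "", text)  # comments are not supported: strip
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unbalanced ')' at character offset ", i)
    }
  }
  if (depth > 0L)
    stop("malformed Newick: ", depth, " unclosed '(' by character offset ",
         length(chars))
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: no terminal ';' by character offset ",
         length(chars))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed Newick: ape could not parse the string")
  validate_tree(tree)
  tree
}

#' @rdname parse_newick
#' @param path path to a Newick file.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree, digits = 17)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

## Shared structural checks; branch lengths must exist, be finite and >= 0.
validate_tree <- function(tree, require_rooted = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("validation error: duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("validation error: tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("validation error: missing branch length on one or more edges")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("validation error: branch lengths must be finite and non-negative")
  if (require_rooted && !ape::is.rooted(tree))
    stop("a rooted tree is required; see midpoint_root_ls()")
  invisible(tree)
}

## Undirected adjacency list: for each node, matrix of (neighbour, length).
tree_adjacency <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]; len <- tree$edge.length[i]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  adj
}

## Distances from `from` to all nodes, optionally with one edge blocked
## (blocked = c(u, v) meaning the u--v edge may not be crossed).
node_distances <- function(adj, from, blocked = NULL) {
  d <- rep(NA_real_, length(adj))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1]
      if (!is.null(blocked) &&
          ((v == blocked[1] && w == blocked[2]) ||
           (v == blocked[2] && w == blocked[1]))) next
      if (is.na(d[w])) {
        d[w] <- d[v] + nb[k, 2]
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Root a tree at the least-squares midpoint
#'
#' Places the root at the point on the tree (possibly in the interior of an
#' edge, which is then split) that minimises the variance of root-to-leaf
#' path lengths -- a least-squares variant of midpoint rooting. The optimal
#' position within each edge is the minimiser of a quadratic in the position
#' and is found in closed form, then clamped to the edge; ties between edges
#' are broken toward the edge encountered first in post-order. Leaf-to-leaf
#' path lengths are unchanged by rooting.
#'
#' @param tree a `phylo` object, rooted or unrooted, with branch lengths.
#' @return a rooted `phylo` object. On an ultrametric tree the root-to-leaf
#'   variance of the result is 0.
#' @examples
#' tr <- parse_newick("(A:1,B:1,C:4);")
#' rooted <- midpoint_root_ls(tr)
#' @export
midpoint_root_ls <- function(tree) {
  validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  if (n_tip < 2) stop("at least 2 leaves are required")
  if (sum(tree$edge.length) <= 0)
    stop("all branch lengths are zero: root position undefined")
  po <- ape::reorder.phylo(tree, "postorder")
  adj <- tree_adjacency(po)
  ## distance from every node to every leaf
  dl <- vapply(seq_len(n_tip), function(leaf) node_distances(adj, leaf),
               numeric(length(adj)))       # nodes x leaves
  best <- NULL
  for (i in seq_len(nrow(po$edge))) {
    u <- po$edge[i, 1]; v <- po$edge[i, 2]; len <- po$edge.length[i]
    ## leaves on the child (v) side of the edge
    reach <- node_distances(adj, v, blocked = c(u, v))
    side_v <- which(!is.na(reach[seq_len(n_tip)]))
    side_u <- setdiff(seq_len(n_tip), side_v)
    ## distance from a point at offset x from v: d_v + x (v side),
    ## d_u + len - x (u side); variance is quadratic in x
    cvec <- c(dl[v, side_v], dl[u, side_u] + len)
    svec <- c(rep(1, length(side_v)), rep(-1, length(side_u)))
    cc <- cvec - mean(cvec)
    ss <- svec - mean(svec)
    B <- mean(cc * ss); C <- mean(ss * ss)
    x <- if (C > 0) max(0, min(len, -B / C)) else 0
    vr <- mean((cc + ss * x)^2)
    if (is.null(best) || vr < best$var - 1e-15) {
      best <- list(edge = i, u = u, v = v, len = len, x = x, var = vr)
    }
  }
  reroot_at_point(po, best$u, best$v, best$len, best$x, adj)
}

## Build a rooted phylo with the root at offset x from node v on edge u--v
## (x in [0, len], measured toward u). Emits Newick and re-parses: simple
## and immune to edge-matrix bookkeeping mistakes.
reroot_at_point <- function(tree, u, v, len, x, adj = NULL) {
  if (is.null(adj)) adj <- tree_adjacency(tree)
  n_tip <- ape::Ntip(tree)
  lab <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else ""
  }
  emit <- function(node, parent) {
    nb <- adj[[node]]
    kids <- nb[nb[, 1] != parent, , drop = FALSE]
    if (nrow(kids) == 0) return(lab(node))
    inner <- vapply(seq_len(nrow(kids)), function(k) {
      paste0(emit(kids[k, 1], node), ":",
             sprintf("%.17g", kids[k, 2]))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", lab(node))
  }
  eps <- 1e-12
  at_v <- x <= eps && v > n_tip
  at_u <- (len - x) <= eps && u > n_tip
  if (at_v || at_u) {
    node <- if (at_v) v else u
    nb <- adj[[node]]
    parts <- vapply(seq_len(nrow(nb)), function(k) {
      paste0(emit(nb[k, 1], node), ":", sprintf("%.17g", nb[k, 2]))
    }, character(1))
    txt <- paste0("(", paste(parts, collapse = ","), ");")
  } else {
    txt <- paste0("(",
                  emit(v, u), ":", sprintf("%.17g", x), ",",
                  emit(u, v), ":", sprintf("%.17g", len - x), ");")
  }
  out <- ape::read.tree(text = txt)
  validate_tree(out)
  out
}

#' Depth of a branch midpoint
#'
#' The phylogenetic depth of a branch is the distance from the root to the
#' branch's parent node plus half the branch's own length. Depths index the
#' depth-dependence diagnostics of the inferred event rates.
#'
#' @param tree a rooted `phylo` object.
#' @param branch edge index (row of `tree$edge`); vectorised.
#' @return numeric vector of depths, substitutions per site.
#' @export
branch_midpoint_depth <- function(tree, branch = seq_len(nrow(tree$edge))) {
  validate_tree(tree, require_rooted = TRUE)
  if (any(branch < 1 | branch > nrow(tree$edge)))
    stop("unknown edge id: ", paste(branch[branch < 1 | branch > nrow(tree$edge)],
                                    collapse = ", "))
  nd <- ape::node.depth.edgelength(tree)
  nd[tree$edge[branch, 1]] + tree$edge.length[branch] / 2
}

#' Mean root-to-leaf depth of a rooted tree
#'
#' @param tree a rooted `phylo` object.
#' @return arithmetic mean of the root-to-leaf path lengths.
#' @export
mean_root_to_leaf_depth <- function(tree) {
  validate_tree(tree, require_rooted = TRUE)
  nd <- ape::node.depth.edgelength(tree)
  mean(nd[seq_len(ape::Ntip(tree))])
}

#' Total tree length
#'
#' @param tree a `phylo` object.
#' @return sum of all branch lengths, substitutions per site.
#' @export
total_tree_length <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}
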