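#' Rooted time tree with branch rates
#'
#' The central state object of the sampler: a rooted binary tree whose nodes
#' carry ages (time before the youngest tip, which sits at age 0) and whose
#' non-root nodes carry the evolutionary rate of the branch above them, in
#' substitutions/site/time.  The product of a branch's rate and its time span
#' is its genetic distance in expected substitutions per site; the proposal
#' kernels in this package hold those products constant.
#'
#' Nodes are indexed `1..2n-1` with tips `1..n` (in the order of `taxa`) and
#' internal nodes `n+1..2n-1`.
#'
#' @param taxa character vector of tip labels (length `n`).
#' @param parent integer vector of length `2n-1`; `parent[i]` is the parent
#'   node of `i`, `NA` for the root.
#' @param times numeric vector of node ages, length `2n-1`.
#' @param rates numeric vector of branch rates (rate of the branch above each
#'   node), length `2n-1`; the root entry is `NA`.
#' @param validate check the invariants (binary topology, parent older than
#'   child, positive rates)?
#' @return An object of class `"timetree"`.
#' @export
timetree <- function(taxa, parent, times, rates, validate = TRUE) {
  n <- length(taxa)
  nnode <- 2L * n - 1L
  stopifnot(length(parent) == nnode, length(times) == nnode,
            length(rates) == nnode)
  parent <- as.integer(parent)
  root <- which(is.na(parent))
  children <- vector("list", nnode)
  for (i in seq_len(nnode)) children[[i]] <- integer(0)
  for (i in seq_len(nnode)) {
    p <- parent[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  tr <- structure(
    list(ntaxa = n, taxa = taxa, parent = parent, children = children,
         times = as.numeric(times), rates = as.numeric(rates),
         root = root),
    class = "timetree")
  if (validate) validate_timetree(tr)
  tr
}

#' Validate a time tree
#'
#' Checks the structural invariants: exactly one root, every internal node
#' with exactly two children, strictly positive time span and rate on every
#' branch (hence strictly positive genetic distances).
#'
#' @param tree a [timetree()].
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_timetree <- function(tree) {
  n <- tree$ntaxa
  nnode <- 2L * n - 1L
  if (length(tree$root) != 1L)
    stop("tree must have exactly one root (found ", length(tree$root), ")")
  ndesc <- vapply(tree$children, length, 1L)
  if (any(ndesc[seq_len(n)] != 0L))
    stop("tip nodes must have no children")
  if (n > 1L && any(ndesc[(n + 1L):nnode] != 2L))
    stop("every internal node must have exactly 2 children")
  for (i in seq_len(nnode)) {
    p <- tree$parent[i]
    if (is.na(p)) next
    if (!(tree$times[p] > tree$times[i]))
      stop("node ", i, " is not strictly younger than its parent")
    if (!(is.finite(tree$rates[i]) && tree$rates[i] > 0))
      stop("rate on the branch above node ", i, " must be > 0")
  }
  if (!is.na(tree$rates[tree$root]))
    stop("root carries no branch rate; rates[root] must be NA")
  invisible(TRUE)
}

#' Node classification helpers
#'
#' @param tree a [timetree()].
#' @param node node index.
#' @param include_root keep the root in the internal-node set?
#' @return `is_tip()`: logical; `internal_nodes()`: integer node indices.
#' @export
is_tip <- function(tree, node) node <= tree$ntaxa

#' @rdname is_tip
#' @export
internal_nodes <- function(tree, include_root = TRUE) {
  out <- (tree$ntaxa + 1L):(2L * tree$ntaxa - 1L)
  if (!include_root) out <- setdiff(out, tree$root)
  out
}

#' @export
print.timetree <- function(x, ...) {
  cat("Time tree with", x$ntaxa, "taxa; root age",
      format(x$times[x$root], digits = 6), "\n")
  cat("Tree length (time):", format(tree_length(x), digits = 6),
      "; total genetic distance:",
      format(sum(branch_distances(x)), digits = 6), "\n")
  invisible(x)
}

#' Age of the root
#' @param tree a [timetree()].
#' @return Root age (height of the tree in time units).
#' @export
tree_height <- function(tree) tree$times[tree$root]

#' Sum of branch time spans
#' @param tree a [timetree()].
#' @return Total branch length of the tree in time units.
#' @export
tree_length <- function(tree) {
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  sum(tree$times[tree$parent[nonroot]] - tree$times[nonroot])
}

#' Genetic distance of one branch
#'
#' The branch above `node` has genetic distance `d = r * (t_parent - t_node)`
#' in expected substitutions per site.
#'
#' @param tree a [timetree()].
#' @param node node index (must not be the root).
#' @return The branch's genetic distance (> 0).
#' @export
branch_distance <- function(tree, node) {
  if (node == tree$root) stop("root has no branch")
  tree$rates[node] * (tree$times[tree$parent[node]] - tree$times[node])
}

#' Genetic distances of all branches
#'
#' @param tree a [timetree()].
#' @return Named numeric vector over non-root nodes: the distance of the
#'   branch above each.
#' @export
branch_distances <- function(tree) {
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  d <- tree$rates[nonroot] * (tree$times[tree$parent[nonroot]] - tree$times[nonroot])
  names(d) <- nonroot
  d
}

#' Patristic distance matrix
#'
#' Tip-to-tip path distances in expected substitutions per site.  This is the
#' quantity all four constant-distance proposals conserve: for the pulley
#' moves the rooted tree changes but this matrix does not.
#'
#' @param tree a [timetree()] or an [unrooted_tree()].
#' @return A symmetric `n x n` matrix with zero diagonal, labelled by taxa.
#' @export
pairwise_distances <- function(tree) UseMethod("pairwise_distances")

#' @export
pairwise_distances.timetree <- function(tree) {
  n <- tree$ntaxa
  # distance from the root down to every node
  nnode <- 2L * n - 1L
  dd <- numeric(nnode)
  ord <- preorder_nodes(tree)
  for (v in ord) {
    p <- tree$parent[v]
    if (!is.na(p))
      dd[v] <- dd[p] + tree$rates[v] * (tree$times[p] - tree$times[v])
  }
  out <- matrix(0, n, n, dimnames = list(tree$taxa, tree$taxa))
  for (i in seq_len(n)) {
    anc_i <- ancestors_of(tree, i)
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- j
      while (!(a %in% anc_i)) a <- tree$parent[a]
      out[i, j] <- out[j, i] <- dd[i] + dd[j] - 2 * dd[a]
    }
  }
  out
}

# node itself plus all its ancestors up to the root
ancestors_of <- function(tree, node) {
  out <- node
  while (!is.na(tree$parent[node])) {
    node <- tree$parent[node]
    out <- c(out, node)
  }
  out
}

# nodes in root-first order (every parent before its children)
preorder_nodes <- function(tree) {
  out <- integer(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, tree$children[[v]])
  }
  out
}

# children-first order (every child before its parent)
postorder_nodes <- function(tree) rev(preorder_nodes(tree))

#' Unrooted tree with substitution branch lengths
#'
#' A thin wrapper around an unrooted `ape::phylo` whose edge lengths are in
#' expected substitutions per site.  Used as the *data* in the
#' fixed-unrooted-tree dating mode.
#'
#' @param phy an unrooted [ape::phylo] (or a rooted one, which is unrooted
#'   first) with positive edge lengths.
#' @return An object of class `"unrooted_tree"` (also an `ape::phylo`).
#' @export
unrooted_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (is.null(phy$edge.length) || any(phy$edge.length <= 0))
    stop("unrooted tree needs strictly positive branch lengths")
  class(phy) <- c("unrooted_tree", "phylo")
  phy
}

#' @export
pairwise_distances.unrooted_tree <- function(tree) {
  phy <- tree
  class(phy) <- "phylo"
  m <- stats::cophenetic(phy)
  m[phy$tip.label, phy$tip.label]
}

#' Convert a time tree to an ape phylo
#'
#' Edge lengths are time spans by default, or genetic distances with
#' `lengths = "distance"`.
#'
#' @param tree a [timetree()].
#' @param lengths `"time"` or `"distance"`.
#' @return An [ape::phylo].
#' @export
timetree_to_phylo <- function(tree, lengths = c("time", "distance")) {
  lengths <- match.arg(lengths)
  n <- tree$ntaxa
  nnode <- 2L * n - 1L
  # ape wants internal ids n+1.. with root first among internals
  ord <- preorder_nodes(tree)
  int <- ord[ord > n]
  newid <- integer(nnode)
  newid[seq_len(n)] <- seq_len(n)
  newid[int] <- n + seq_along(int)
  nonroot <- setdiff(seq_len(nnode), tree$root)
  edge <- cbind(newid[tree$parent[nonroot]], newid[nonroot])
  span <- tree$times[tree$parent[nonroot]] - tree$times[nonroot]
  len <- if (lengths == "time") span else span * tree$rates[nonroot]
  structure(list(edge = edge, edge.length = len, Nnode = n - 1L,
                 tip.label = tree$taxa),
            class = "phylo", order = "cladewise")
}
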