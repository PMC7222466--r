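#' Read a newick tree
#'
#' A small recursive-descent parser that, unlike most general readers, keeps
#' BEAST-style `[&rate=...]` branch annotations and reports the character
#' offset of any syntax error.  In `"time"` mode branch lengths are read as
#' time spans and a rooted binary [timetree()] is returned (node ages are
#' measured back from the youngest tip at age 0).  In `"substitution"` mode
#' lengths are expected substitutions per site and an [unrooted_tree()] is
#' returned.
#'
#' @param text a single newick string (terminating `;` optional).
#' @param mode `"time"` or `"substitution"`.
#' @param default_rate rate assigned to branches without a `[&rate=...]`
#'   annotation in `"time"` mode (a strict clock by default).
#' @return A [timetree()] or an [unrooted_tree()].
#' @export
read_newick <- function(text, mode = c("time", "substitution"),
                        default_rate = 1) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  pos <- 1L
  nmax <- nchar(s)
  peek <- function() if (pos > nmax) "" else substr(s, pos, pos)
  fail <- function(msg) stop("newick parse error at character ", pos, ": ",
                             msg, call. = FALSE)
  read_label <- function() {
    start <- pos
    while (pos <= nmax && !(peek() %in% c("(", ")", ",", ":", ";", "[")))
      pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_annotation <- function() {
    if (peek() != "[") return(NA_real_)
    close <- regexpr("]", substr(s, pos, nmax), fixed = TRUE)
    if (close < 0) fail("unterminated '[' comment")
    com <- substr(s, pos, pos + close - 1L)
    pos <<- pos + close
    m <- regmatches(com, regexec("^\\[&rate=([0-9eE.+-]+)\\]$", com))[[1]]
    if (length(m) == 2L) as.numeric(m[2]) else NA_real_
  }
  read_number <- function() {
    start <- pos
    while (pos <= nmax && grepl("[0-9eE.+-]", peek())) pos <<- pos + 1L
    if (pos == start) fail("expected a branch length")
    x <- suppressWarnings(as.numeric(substr(s, start, pos - 1L)))
    if (is.na(x)) fail("malformed branch length")
    x
  }
  # returns list(label, length, rate, kids)
  read_clade <- function() {
    node <- list(label = "", length = NA_real_, rate = NA_real_,
                 kids = list())
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        node$kids[[length(node$kids) + 1L]] <- read_clade()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      node$label <- read_label()
    } else {
      node$label <- read_label()
      if (node$label == "") fail("expected a taxon label")
    }
    r <- read_annotation()
    if (!is.na(r)) node$rate <- r
    if (peek() == ":") {
      pos <<- pos + 1L
      r <- read_annotation()
      if (!is.na(r)) node$rate <- r
      node$length <- read_number()
    }
    node
  }
  tree <- read_clade()
  if (peek() == ";") pos <- pos + 1L
  if (pos <= nmax) fail("trailing characters after tree")

  # flatten
  tips <- list(); internals <- list()
  walk <- function(nd) {
    if (length(nd$kids) == 0L) {
      tips[[length(tips) + 1L]] <<- nd
      list(tip = length(tips))
    } else {
      ks <- lapply(nd$kids, walk)
      internals[[length(internals) + 1L]] <<- nd
      list(int = length(internals), kids = ks)
    }
  }
  shape <- walk(tree)
  n <- length(tips)
  if (n < 2L) stop("need at least 2 taxa")
  if (mode == "time" && length(internals) != n - 1L)
    stop("non-binary rooted tree not supported in time mode")

  taxa <- vapply(tips, `[[`, "", "label")
  nnode <- n + length(internals)
  parent <- rep(NA_integer_, nnode)
  span <- rep(NA_real_, nnode)
  rate <- rep(NA_real_, nnode)
  assign_edges <- function(sh, nd_meta) {
    id <- if (!is.null(sh$tip)) sh$tip else n + sh$int
    meta <- if (!is.null(sh$tip)) tips[[sh$tip]] else internals[[sh$int]]
    span[id] <<- meta$length
    rate[id] <<- meta$rate
    if (!is.null(sh$kids))
      for (k in sh$kids) {
        kid <- if (!is.null(k$tip)) k$tip else n + k$int
        parent[kid] <<- id
        assign_edges(k, NULL)
      }
    id
  }
  root <- assign_edges(shape, NULL)

  if (mode == "substitution") {
    phy <- edges_to_phylo(taxa, parent, span, root)
    return(unrooted_tree(phy))
  }

  # node ages from spans: depth from root, then flip so youngest tip is 0
  depth <- numeric(nnode)
  ord <- order_preorder(parent, root)
  for (v in ord) if (!is.na(parent[v])) {
    if (is.na(span[v])) stop("branch above node ", v, " has no length")
    depth[v] <- depth[parent[v]] + span[v]
  }
  H <- max(depth[seq_len(n)])
  times <- H - depth
  rate[-root][is.na(rate[-root])] <- default_rate
  rate[root] <- NA_real_
  timetree(taxa, parent, times, rate)
}

order_preorder <- function(parent, root) {
  nnode <- length(parent)
  kids <- vector("list", nnode)
  for (i in seq_len(nnode)) if (!is.na(parent[i]))
    kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  out <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v); stack <- c(stack, kids[[v]])
  }
  out
}

edges_to_phylo <- function(taxa, parent, span, root) {
  n <- length(taxa)
  nnode <- length(parent)
  ord <- order_preorder(parent, root)
  int <- ord[ord > n]
  newid <- integer(nnode)
  newid[seq_len(n)] <- seq_len(n)
  newid[int] <- n + seq_along(int)
  nonroot <- setdiff(seq_len(nnode), root)
  structure(list(edge = cbind(newid[parent[nonroot]], newid[nonroot]),
                 edge.length = span[nonroot],
                 Nnode = nnode - n, tip.label = taxa),
            class = "phylo", order = "cladewise")
}

#' Write a tree as newick
#'
#' For a [timetree()] branch lengths are time spans and, when
#' `annotate_rates` is set, each branch carries its rate as a BEAST-style
#' `[&rate=...]` comment so that `read_newick()` round-trips the full state.
#'
#' @param tree a [timetree()] or [unrooted_tree()].
#' @param annotate_rates include `[&rate=...]` annotations (timetree only)?
#' @param digits significant digits for lengths.
#' @return A newick string ending in `;`.
#' @export
write_newick <- function(tree, annotate_rates = TRUE, digits = 15) {
  if (inherits(tree, "unrooted_tree")) {
    phy <- tree; class(phy) <- "phylo"
    return(ape::write.tree(phy))
  }
  stopifnot(inherits(tree, "timetree"))
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(v) {
    lab <- if (is_tip(tree, v)) tree$taxa[v] else {
      paste0("(", paste(vapply(tree$children[[v]], rec, ""), collapse = ","),
             ")")
    }
    if (v == tree$root) return(lab)
    ann <- if (annotate_rates)
      paste0("[&rate=", fmt(tree$rates[v]), "]") else ""
    paste0(lab, ann, ":", fmt(tree$times[tree$parent[v]] - tree$times[v]))
  }
  paste0(rec(tree$root), ";")
}

#' Write a NEXUS trees block
#'
#' Minimal NEXUS tree log (one `tree` statement per sampled tree), the
#' format used for posterior tree samples.
#'
#' @param trees list of [timetree()] objects (all on the same taxa).
#' @param file output path.
#' @param annotate_rates include rate annotations?
#' @export
write_nexus_trees <- function(trees, file, annotate_rates = TRUE) {
  stopifnot(length(trees) > 0)
  taxa <- trees[[1]]$taxa
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "Begin taxa;",
               paste0("  Dimensions ntax=", length(taxa), ";"),
               "  Taxlabels", paste0("    ", taxa), "  ;", "End;",
               "Begin trees;"), con)
  for (i in seq_along(trees))
    writeLines(paste0("  tree STATE_", i - 1L, " = ",
                      write_newick(trees[[i]], annotate_rates)), con)
  writeLines("End;", con)
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path of an
#' unrooted substitution tree.  Ties among diameter paths are broken
#' deterministically by the lexicographically smallest taxon pair.  All
#' original branch lengths are preserved; the branch containing the midpoint
#' is split in two.
#'
#' @param utree an [unrooted_tree()].
#' @return A rooted substitution-length tree of class `"subst_tree"`: fields
#'   `taxa`, `parent`, `children`, `lengths` (substitution length of the
#'   branch above each node), `root`.
#' @export
midpoint_root <- function(utree) {
  stopifnot(inherits(utree, "unrooted_tree"))
  m <- pairwise_distances(utree)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  dmax <- max(m)
  cand <- which(m >= dmax - 1e-12 * max(dmax, 1), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  labs <- rownames(m)
  keys <- apply(cand, 1L, function(ij) {
    p <- sort(c(labs[ij[1]], labs[ij[2]])); paste(p, collapse = "\r")
  })
  pick <- cand[order(keys)[1L], ]
  a <- pick[1]; b <- pick[2]

  phy <- utree; class(phy) <- "phylo"
  nv <- n + phy$Nnode
  adj <- vector("list", nv)
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]; w <- phy$edge.length[e]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  # path a -> b by DFS
  prev <- rep(NA_integer_, nv); prev[a] <- a
  stack <- a
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u == b) break
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]
      if (is.na(prev[v])) { prev[v] <- u; stack <- c(stack, v) }
    }
  }
  path <- b
  while (path[1] != a) path <- c(prev[path[1]], path)
  # walk until the half-diameter point
  half <- dmax / 2
  cum <- 0
  for (i in seq_len(length(path) - 1L)) {
    u <- path[i]; v <- path[i + 1L]
    w <- adj[[u]][match(v, adj[[u]][, 1]), 2]
    if (cum + w >= half - 1e-15) {
      split_u <- u; split_v <- v; pos_u <- half - cum; len_uv <- w
      break
    }
    cum <- cum + w
  }
  if (pos_u <= 0 || pos_u >= len_uv)
    stop("midpoint falls exactly on a vertex; cannot place a binary root")
  root_subst_tree(phy, split_u, split_v, pos_u)
}

# Root an unrooted phylo on the edge (u, v), at distance pos_u from u.
root_subst_tree <- function(phy, u, v, pos_u) {
  n <- length(phy$tip.label)
  nv_old <- n + phy$Nnode
  adj <- vector("list", nv_old)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]; w <- phy$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  len_uv <- adj[[u]][match(v, adj[[u]][, 1]), 2]
  nnode <- 2L * n - 1L           # old vertices (n + n - 2) + new root
  root <- nnode
  parent <- rep(NA_integer_, nnode)
  lengths <- rep(NA_real_, nnode)
  parent[u] <- root; lengths[u] <- pos_u
  parent[v] <- root; lengths[v] <- len_uv - pos_u
  # orient remaining edges away from the root
  grow <- function(w) {
    for (k in seq_len(NROW(adj[[w]]))) {
      x <- adj[[w]][k, 1]
      if (is.na(parent[x]) && x != root &&
          !(identical(sort(c(w, x)), sort(c(u, v))))) {
        if (x == parent[w]) next
        parent[x] <<- w; lengths[x] <<- adj[[w]][k, 2]
        grow(x)
      }
    }
  }
  grow(u); grow(v)
  children <- vector("list", nnode)
  for (i in seq_len(nnode)) children[[i]] <- integer(0)
  for (i in seq_len(nnode)) if (!is.na(parent[i]))
    children[[parent[i]]] <- c(children[[parent[i]]], i)
  structure(list(ntaxa = n, taxa = phy$tip.label, parent = parent,
                 children = children, lengths = lengths, root = root),
            class = "subst_tree")
}

#' Time/rate initialization from a rooted substitution tree
#'
#' Turns a rooted tree with substitution branch lengths into a valid
#' [timetree()] whose branch products `r * dt` reproduce the input lengths
#' exactly.  Node ages are assigned proportionally to each node's depth rank
#' (maximum edge count down to a tip), scaled into `(0, height]`; rates are
#' then `length / dt`.  Any such consistent assignment is a valid chain
#' start; the distances, not the particular times, are the data.
#'
#' @param stree a `"subst_tree"` (for instance from [midpoint_root()]).
#' @param height root age of the initial time tree, in time units.
#' @return A [timetree()].
#' @export
init_times_rates_from_unrooted <- function(stree, height = 1) {
  stopifnot(inherits(stree, "subst_tree"), height > 0)
  nnode <- 2L * stree$ntaxa - 1L
  rank <- integer(nnode)
  for (v in rev(order_preorder(stree$parent, stree$root))) {
    k <- stree$children[[v]]
    rank[v] <- if (length(k)) 1L + max(rank[k]) else 0L
  }
  times <- height * rank / rank[stree$root]
  rates <- rep(NA_real_, nnode)
  nonroot <- setdiff(seq_len(nnode), stree$root)
  rates[nonroot] <- stree$lengths[nonroot] /
    (times[stree$parent[nonroot]] - times[nonroot])
  timetree(stree$taxa, stree$parent, times, rates)
}
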