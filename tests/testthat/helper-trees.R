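# Random valid time trees for property-style tests.
rand_timetree <- function(n, lambda = 1, rate_meanlog = -1,
                          rate_sdlog = 0.5) {
  tr <- simulate_yule_tree(n, lambda)
  nonroot <- setdiff(seq_along(tr$parent), tr$root)
  tr$rates[nonroot] <- stats::rlnorm(length(nonroot), rate_meanlog,
                                     rate_sdlog)
  tr
}

# Patristic matrix by explicit shortest-path search over the
# distance-weighted graph -- an oracle independent of the package's
# LCA-based computation.
graph_patristic <- function(tree) {
  n <- tree$ntaxa
  nonroot <- setdiff(seq_along(tree$parent), tree$root)
  el <- cbind(tree$parent[nonroot], nonroot)
  w <- tree$rates[nonroot] * (tree$times[tree$parent[nonroot]] -
                                tree$times[nonroot])
  g <- igraph::graph_from_edgelist(apply(el, 2, as.character),
                                   directed = FALSE)
  m <- igraph::distances(g, weights = w)
  tips <- as.character(seq_len(n))
  out <- m[tips, tips]
  dimnames(out) <- list(tree$taxa, tree$taxa)
  out
}

# finite-difference |det J| of an operator's deterministic map
fd_green_internal <- function(tr, X, a) {
  kids <- tr$children[[X]]
  f <- function(x) {
    t2 <- tr; t2$times[X] <- x[1]; t2$rates[X] <- x[2]
    t2$rates[kids[1]] <- x[3]; t2$rates[kids[2]] <- x[4]
    p <- propose_internal_node(t2, node = X, a = a)
    c(p$tree$times[X], p$tree$rates[X], p$tree$rates[kids[1]],
      p$tree$rates[kids[2]])
  }
  x0 <- c(tr$times[X], tr$rates[X], tr$rates[kids[1]], tr$rates[kids[2]])
  abs(det(pracma::jacobian(f, x0)))
}

fd_green_simple_distance <- function(tr, a) {
  X <- tr$root; kids <- tr$children[[X]]
  f <- function(x) {
    t2 <- tr; t2$times[X] <- x[1]
    t2$rates[kids[1]] <- x[2]; t2$rates[kids[2]] <- x[3]
    p <- propose_simple_distance(t2, a = a)
    c(p$tree$times[X], p$tree$rates[kids[1]], p$tree$rates[kids[2]])
  }
  abs(det(pracma::jacobian(f, c(tr$times[X], tr$rates[kids]))))
}

fd_green_small_pulley <- function(tr, b) {
  kids <- tr$children[[tr$root]]
  f <- function(x) {
    t2 <- tr; t2$rates[kids[1]] <- x[1]; t2$rates[kids[2]] <- x[2]
    propose_small_pulley(t2, b = b)$tree$rates[kids]
  }
  abs(det(pracma::jacobian(f, tr$rates[kids])))
}

# |det J| of the big-pulley map with the promoted node pinned
fd_green_big_pulley <- function(tr, a, a2, b, M) {
  pr <- propose_big_pulley(tr, a = a, a2 = a2, b = b, M = M)
  if (!pr$valid) return(NULL)
  X <- tr$root; C <- pr$info$C; N <- pr$info$N
  S <- setdiff(tr$children[[C]], M)
  f <- function(x) {
    t2 <- tr
    t2$times[X] <- x[1]; t2$times[C] <- x[2]
    t2$rates[C] <- x[3]; t2$rates[S] <- x[4]
    t2$rates[M] <- x[5]; t2$rates[N] <- x[6]
    p <- propose_big_pulley(t2, a = a, a2 = a2, b = b, M = M)
    if (!p$valid) return(rep(NA_real_, 6))
    c(p$tree$times[X], p$tree$times[C], p$tree$rates[C], p$tree$rates[S],
      p$tree$rates[M], p$tree$rates[N])
  }
  x0 <- c(tr$times[X], tr$times[C], tr$rates[C], tr$rates[S],
          tr$rates[M], tr$rates[N])
  J <- pracma::jacobian(f, x0)
  if (any(is.na(J))) return(NULL)
  list(fd = abs(det(J)), mu = pr$info$mu, green = exp(pr$log_green))
}

# a big-pulley proposal drawn with random displacements; NULL if invalid
draw_big_pulley <- function(tr, w = 0.3, v = 0.05) {
  X <- tr$root
  kids <- tr$children[[X]]
  ik <- kids[!vapply(kids, function(z) is_tip(tr, z), TRUE)]
  M <- if (length(ik) == 2L) {
    gc <- c(tr$children[[ik[1]]], tr$children[[ik[2]]])
    gc[sample.int(4L, 1L)]
  } else tr$children[[ik]][sample.int(2L, 1L)]
  list(a = stats::runif(1, -w, w), a2 = stats::runif(1, -w, w),
       b = stats::runif(1, -v, v), M = M)
}
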