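#' Proposal kernel configuration
#'
#' Window sizes for the constant-distance kernels: `w` is the half-width of
#' the uniform displacement on node times, `v` the half-width on genetic
#' distances.  The displacement kernel is pluggable; the uniform kernel is
#' the default (and the only one whose Green ratios are derived here --
#' any replacement must be symmetric).
#'
#' @param w time-window half-width (> 0).
#' @param v distance-window half-width (> 0).
#' @param kernel `"uniform"` or a function `f(halfwidth)` returning one
#'   symmetric random displacement.
#' @return An object of class `"operator_config"`.
#' @export
operator_config <- function(w = 1, v = 0.1, kernel = "uniform") {
  stopifnot(w > 0, v > 0)
  draw <- if (is.function(kernel)) kernel
  else switch(kernel,
              uniform = function(half) stats::runif(1, -half, half),
              stop("unknown displacement kernel"))
  structure(list(w = w, v = v, draw = draw), class = "operator_config")
}

#' Proposal result
#'
#' The contract every operator returns: the proposed state, the log Green
#' ratio (Hastings ratio times the Jacobian determinant of the deterministic
#' rate map), and a validity flag.  Out-of-bounds proposals come back with
#' `valid = FALSE` and count as rejected moves; their Green ratio is unused.
#'
#' @param tree proposed [timetree()] (the current one when invalid).
#' @param log_green log Green ratio.
#' @param valid logical.
#' @param changed_distances does the move alter any genetic distance (and
#'   hence the likelihood)?
#' @param info free-form bookkeeping (nodes touched, displacements, ...).
#' @return An object of class `"proposal_result"`.
#' @export
proposal_result <- function(tree, log_green, valid,
                            changed_distances = FALSE, info = list()) {
  structure(list(tree = tree, log_green = log_green, valid = valid,
                 changed_distances = changed_distances, info = info),
            class = "proposal_result")
}

reject_proposal <- function(tree, info = list())
  proposal_result(tree, -Inf, FALSE, FALSE, info)

#' Constant-distance move on an internal node
#'
#' Shifts the age of a non-root internal node `X` by `a ~ Uniform[-w, w]`
#' and rescales the three adjacent branch rates so that the genetic
#' distances of the branch above `X` and the two branches below it are
#' unchanged:
#' `r' = r * dt_old / dt_new` on each.  The proposal is rejected unless
#' `max(t_L, t_R) < t_X' < t_P`.  The Green ratio is the Jacobian
#' determinant of the map `(t_X, r_X, r_L, r_R) -> (t_X', r_X', r_L', r_R')`:
#' the product of the three span ratios.
#'
#' @param tree a [timetree()].
#' @param cfg an [operator_config()].
#' @param node internal non-root node to move (random if `NULL`).
#' @param a displacement (drawn from the kernel if `NULL`).
#' @return A [proposal_result()].
#' @export
propose_internal_node <- function(tree, cfg = operator_config(),
                                  node = NULL, a = NULL) {
  cand <- internal_nodes(tree, include_root = FALSE)
  if (length(cand) == 0L) stop("tree has no non-root internal node")
  if (is.null(node)) node <- cand[sample.int(length(cand), 1L)]
  if (is_tip(tree, node) || node == tree$root)
    stop("constant-distance internal move needs a non-root internal node")
  if (is.null(a)) a <- cfg$draw(cfg$w)
  X <- node; P <- tree$parent[X]
  kids <- tree$children[[X]]; L <- kids[1]; R <- kids[2]
  tX <- tree$times[X]; tP <- tree$times[P]
  tL <- tree$times[L]; tR <- tree$times[R]
  tXp <- tX + a
  if (!(tXp > max(tL, tR) && tXp < tP))
    return(reject_proposal(tree, list(op = "internal_node", node = X, a = a)))
  new <- tree
  new$times[X] <- tXp
  new$rates[X] <- tree$rates[X] * (tP - tX) / (tP - tXp)
  new$rates[L] <- tree$rates[L] * (tX - tL) / (tXp - tL)
  new$rates[R] <- tree$rates[R] * (tX - tR) / (tXp - tR)
  lg <- log((tP - tX) / (tP - tXp)) + log((tX - tL) / (tXp - tL)) +
    log((tX - tR) / (tXp - tR))
  proposal_result(new, lg, TRUE, FALSE,
                  list(op = "internal_node", node = X, a = a))
}

#' Simple-distance move on the root
#'
#' Shifts the root age by `a ~ Uniform[-w, w]` and rescales the two
#' root-adjacent rates so both root branch distances stay fixed.  Rejected
#' unless the new root age exceeds both child ages.  Green ratio: product of
#' the two span ratios.
#'
#' @inheritParams propose_internal_node
#' @return A [proposal_result()].
#' @export
propose_simple_distance <- function(tree, cfg = operator_config(),
                                    a = NULL) {
  X <- tree$root
  if (is.null(a)) a <- cfg$draw(cfg$w)
  kids <- tree$children[[X]]; L <- kids[1]; R <- kids[2]
  tX <- tree$times[X]; tL <- tree$times[L]; tR <- tree$times[R]
  tXp <- tX + a
  if (!(tXp > max(tL, tR)))
    return(reject_proposal(tree, list(op = "simple_distance", a = a)))
  new <- tree
  new$times[X] <- tXp
  new$rates[L] <- tree$rates[L] * (tX - tL) / (tXp - tL)
  new$rates[R] <- tree$rates[R] * (tX - tR) / (tXp - tR)
  lg <- log((tX - tL) / (tXp - tL)) + log((tX - tR) / (tXp - tR))
  proposal_result(new, lg, TRUE, FALSE,
                  list(op = "simple_distance", a = a))
}

#' Small-pulley move on the root
#'
#' Slides genetic distance between the two root branches while all node
#' times stay put: `d_L' = d_L + b` with `b ~ Uniform[-v, v]`, `d_R'` takes
#' up the slack so `D = d_L + d_R` is conserved, and the two rates are
#' re-derived from the new distances.  Rejected unless `0 < d_L' < D`.  The
#' Jacobian of the rate map is the identity, so the Green ratio is exactly
#' 1.
#'
#' @inheritParams propose_internal_node
#' @param b distance displacement (drawn if `NULL`).
#' @return A [proposal_result()].
#' @export
propose_small_pulley <- function(tree, cfg = operator_config(), b = NULL) {
  X <- tree$root
  if (is.null(b)) b <- cfg$draw(cfg$v)
  kids <- tree$children[[X]]; L <- kids[1]; R <- kids[2]
  tX <- tree$times[X]; tL <- tree$times[L]; tR <- tree$times[R]
  dL <- tree$rates[L] * (tX - tL); dR <- tree$rates[R] * (tX - tR)
  D <- dL + dR
  dLp <- dL + b
  if (!(dLp > 0 && dLp < D))
    return(reject_proposal(tree, list(op = "small_pulley", b = b)))
  new <- tree
  new$rates[L] <- dLp / (tX - tL)
  new$rates[R] <- (D - dLp) / (tX - tR)
  proposal_result(new, 0, TRUE, FALSE, list(op = "small_pulley", b = b))
}

#' Exchange: re-hang the root between two branches
#'
#' The structural edit inside the big pulley (configuration: root `X`
#' with children `C` and `N`, and `C` with children `S` and `M`).  `M` and
#' `N` are swapped by prune-and-regraft and the four distances adjusted so
#' every path distance among the `S`, `M`, `N` subtrees is conserved:
#' `d_C' = d_C + b`, `d_S' = d_S`, `d_M' = d_M - d_C'`, `d_N' = d_N + d_C`.
#' Invalid unless `0 < d_C' < d_C + d_N` and `d_M' > 0`.
#'
#' Node times are not touched here; the caller (the big pulley) proposes
#' the new times and re-derives rates.
#'
#' @param tree a [timetree()].
#' @param M a grandchild of the root through `C`.
#' @param N the root child that is not `C`.
#' @param b distance displacement.
#' @return A list with the edited `parent`/`children` maps, the full
#'   per-branch distance vector `d` (indexed by node), the actors
#'   (`X`, `C`, `N`, `M`, `S`) and a `valid` flag.
#' @export
exchange_nodes <- function(tree, M, N, b) {
  X <- tree$root
  if (!(N %in% tree$children[[X]]))
    stop("N must be a child of the root")
  C <- setdiff(tree$children[[X]], N)
  if (!(M %in% tree$children[[C]]))
    stop("M must be a child of the root's other child")
  S <- setdiff(tree$children[[C]], M)
  d <- numeric(length(tree$parent))
  nonroot <- setdiff(seq_along(tree$parent), X)
  d[nonroot] <- tree$rates[nonroot] *
    (tree$times[tree$parent[nonroot]] - tree$times[nonroot])
  dCp <- d[C] + b
  valid <- dCp > 0 && dCp < d[C] + d[N] && d[M] - dCp > 0
  parent <- tree$parent; children <- tree$children
  dnew <- d
  if (valid) {
    parent[M] <- X; parent[N] <- C
    children[[X]] <- c(C, M)
    children[[C]] <- c(S, N)
    dnew[M] <- d[M] - dCp
    dnew[N] <- d[N] + d[C]
    dnew[C] <- dCp
  }
  list(parent = parent, children = children, d = dnew, valid = valid,
       X = X, C = C, N = N, M = M, S = S)
}

# age of the elder grandchild of the root through its internal child C;
# used by the asymmetric-shape selection rule
elder_grandchild <- function(tree, C) {
  g <- tree$children[[C]]
  g[order(-tree$times[g], g)][1]
}

# probability that the big pulley, applied to `g`, selects precisely the
# topology move that produced `gprime` (selection probability only; the
# displacement densities are symmetric and cancel).
bp_choice_prob <- function(g, gprime) {
  X <- g$root
  kids <- g$children[[X]]
  internal_kids <- kids[!vapply(kids, function(k) is_tip(g, k), TRUE)]
  kids_p <- gprime$children[[gprime$root]]
  C <- intersect(kids, kids_p)
  if (length(C) != 1L) stop("not a big-pulley move pair")
  M <- setdiff(kids_p, C)
  if (length(internal_kids) == 2L) return(0.25)       # symmetric shape
  if (length(internal_kids) != 1L) stop("root children are both tips")
  if (C != internal_kids) stop("not a big-pulley move pair")
  G1 <- elder_grandchild(g, C)
  tCp <- gprime$times[C]                               # proposed new age of C
  if (tCp < g$times[G1]) {
    if (M != G1) stop("forced move pair inconsistent with the proposed tree")
    1
  } else 0.5
}

#' Topology-selection ratio of a big-pulley move pair
#'
#' `mu = p(g'->g) / p(g->g')`: the ratio of the reverse to the forward
#' topology-selection probability.  On a symmetric tree each of the four
#' candidate re-rootings has probability 0.25; on an asymmetric tree the
#' move displacing the elder grandchild is forced (probability 1) when the
#' proposed internal-child age falls below that grandchild's age, and the
#' two candidates have probability 0.5 each otherwise.
#'
#' @param g current [timetree()].
#' @param gprime proposed [timetree()] (same node ids, as produced by
#'   [propose_big_pulley()]).
#' @return `mu`, a value in \{0.25, 0.5, 1, 2, 4\}.
#' @export
topology_proposal_ratio <- function(g, gprime) {
  bp_choice_prob(gprime, g) / bp_choice_prob(g, gprime)
}

#' Big-pulley move on the root
#'
#' Re-hangs the root onto a neighbouring branch of the underlying unrooted
#' tree, proposing new ages for the root and for the root's internal child
#' and a new split of genetic distance, while conserving every tip-pairwise
#' genetic distance.  On a symmetric tree (both root children internal) one
#' of four target re-rootings is chosen uniformly; on an asymmetric tree
#' (one root child a tip) the selection follows the elder-grandchild rule
#' (see [topology_proposal_ratio()]).  The Green ratio is
#' `mu * prod(dt_old / dt_new)` over the four re-rated branches.
#'
#' @inheritParams propose_internal_node
#' @param a,a2 root / internal-child time displacements (drawn if `NULL`).
#' @param b distance displacement (drawn if `NULL`).
#' @param choice grandchild index 1..4 to force a symmetric-case target
#'   (testing hook).
#' @param M node to promote to the root (testing hook overriding the
#'   random selection; the selection probability is still computed from the
#'   shape rule).
#' @return A [proposal_result()].
#' @export
propose_big_pulley <- function(tree, cfg = operator_config(),
                               a = NULL, a2 = NULL, b = NULL,
                               choice = NULL, M = NULL) {
  if (tree$ntaxa < 3L)
    stop("big pulley needs at least 3 taxa")
  X <- tree$root
  kids <- tree$children[[X]]
  internal_kids <- kids[!vapply(kids, function(k) is_tip(tree, k), TRUE)]
  if (is.null(a)) a <- cfg$draw(cfg$w)
  if (is.null(a2)) a2 <- cfg$draw(cfg$w)
  if (is.null(b)) b <- cfg$draw(cfg$v)
  tXp <- tree$times[X] + a

  if (length(internal_kids) == 2L) {
    # symmetric: pick one of the four grandchildren, promote it to the root
    if (is.null(M)) {
      gc <- c(tree$children[[internal_kids[1]]],
              tree$children[[internal_kids[2]]])
      if (is.null(choice)) choice <- sample.int(4L, 1L)
      M <- gc[choice]
    }
    C <- tree$parent[M]
    N <- setdiff(kids, C)
    p_fwd <- 0.25
  } else {
    C <- internal_kids
    N <- setdiff(kids, C)                 # the tip child
    tCp_try <- tree$times[C] + a2
    G1 <- elder_grandchild(tree, C)
    if (tCp_try < tree$times[G1]) {
      if (is.null(M)) M <- G1
      p_fwd <- 1
      if (M != G1)
        return(reject_proposal(tree, list(op = "big_pulley", a = a,
                                          a2 = a2, b = b)))
    } else {
      if (is.null(M)) M <- tree$children[[C]][sample.int(2L, 1L)]
      p_fwd <- 0.5
    }
  }
  tC <- tree$times[C]; tCp <- tC + a2
  info <- list(op = "big_pulley", a = a, a2 = a2, b = b,
               C = C, M = M, N = N)

  ex <- exchange_nodes(tree, M, N, b)
  S <- ex$S
  ok <- ex$valid &&
    tXp > max(tCp, tree$times[M]) &&
    tCp > max(tree$times[S], tree$times[N])
  if (!ok) return(reject_proposal(tree, info))

  new <- tree
  new$parent <- ex$parent; new$children <- ex$children
  new$times[X] <- tXp; new$times[C] <- tCp
  new$rates[C] <- ex$d[C] / (tXp - tCp)
  new$rates[S] <- ex$d[S] / (tCp - tree$times[S])
  new$rates[M] <- ex$d[M] / (tXp - tree$times[M])
  new$rates[N] <- ex$d[N] / (tCp - tree$times[N])
  if (any(!is.finite(new$rates[c(C, S, M, N)])) ||
      any(new$rates[c(C, S, M, N)] <= 0))
    return(reject_proposal(tree, info))

  # reverse selection probability (see topology_proposal_ratio)
  p_rev <- if (!is_tip(tree, M)) 0.25
  else if (tC < max(new$times[c(S, N)])) 1 else 0.5
  mu <- p_rev / p_fwd

  tX <- tree$times[X]
  lg <- log(mu) +
    log((tX - tC) / (tXp - tCp)) +
    log((tC - tree$times[S]) / (tCp - tree$times[S])) +
    log((tC - tree$times[M]) / (tXp - tree$times[M])) +
    log((tX - tree$times[N]) / (tCp - tree$times[N]))
  proposal_result(new, lg, TRUE, FALSE, c(info, list(mu = mu)))
}
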