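#' HKY85 substitution model
#'
#' Transition/transversion-biased reversible nucleotide model with arbitrary
#' base frequencies.  The rate matrix is normalized so the expected
#' substitution rate at stationarity is 1, making branch "distance" mean
#' expected substitutions per site.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi base frequencies in order A, C, G, T (each > 0, summing to 1).
#' @return An object of class `"hky_model"`.
#' @export
hky_model <- function(kappa = 2, pi = c(0.25, 0.25, 0.25, 0.25)) {
  stopifnot(kappa > 0, length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  names(pi) <- c("A", "C", "G", "T")
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  beta <- 1 / (2 * kappa * (pi["A"] * pi["G"] + pi["C"] * pi["T"]) +
                 2 * piR * piY)
  pur <- c(TRUE, FALSE, TRUE, FALSE)
  structure(list(kappa = kappa, pi = pi, beta = unname(beta),
                 piR = unname(piR), piY = unname(piY),
                 grp = unname(ifelse(pur, piR, piY)),
                 same_grp = outer(pur, pur, "==")),
            class = "hky_model")
}

#' Unnormalized-to-normalized HKY rate matrix
#'
#' The generator `Q` (rows sum to zero, mean rate 1) -- mainly for testing
#' against a generic matrix exponential.
#'
#' @param model an [hky_model()].
#' @return 4x4 matrix with dimnames A,C,G,T.
#' @export
hky_rate_matrix <- function(model) {
  b <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  transition <- function(i, j)
    (i == "A" && j == "G") || (i == "G" && j == "A") ||
    (i == "C" && j == "T") || (i == "T" && j == "C")
  for (i in b) for (j in b) if (i != j)
    Q[i, j] <- model$beta * model$pi[j] *
      (if (transition(i, j)) model$kappa else 1)
  diag(Q) <- -rowSums(Q)
  Q
}

#' HKY transition probability matrix
#'
#' `P(d) = exp(Q d)` in closed form, `d` in expected substitutions per site.
#' `P(0)` is the identity and rows tend to the stationary frequencies as
#' `d` grows.
#'
#' @param model an [hky_model()].
#' @param d genetic distance (>= 0).
#' @return 4x4 stochastic matrix (rows sum to 1), dimnames A,C,G,T.
#' @export
hky_transition_matrix <- function(model, d) {
  if (!(is.finite(d) && d >= 0)) stop("distance must be >= 0")
  pi <- unname(model$pi); grp <- model$grp; beta <- model$beta
  e2 <- exp(-beta * d)
  e4 <- exp(-beta * d * (grp * model$kappa + (1 - grp)))  # per target base
  # same column j throughout each row: build by-row constants
  same <- pi + pi * (1 / grp - 1) * e2 - (pi / grp) * e4
  diff <- pi * (1 - e2)
  P <- matrix(diff, 4, 4, byrow = TRUE)
  sg <- model$same_grp
  P[sg] <- matrix(same, 4, 4, byrow = TRUE)[sg]
  P[c(1, 6, 11, 16)] <- same + e4                 # diagonal
  dimnames(P) <- list(names(model$pi), names(model$pi))
  P
}

iupac_partials <- local({
  base <- c("A", "C", "G", "T")
  amb <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = base, "-" = base, "?" = base)
  m <- sapply(amb, function(s) as.numeric(base %in% s))
  rownames(m) <- base
  m
})

#' Nucleotide alignment
#'
#' @param taxa tip labels.
#' @param seqs character matrix (`length(taxa)` rows) of single-letter
#'   nucleotide states; IUPAC ambiguity codes, `N`, `-` and `?` are treated
#'   as partial uncertainty in the likelihood.
#' @return An object of class `"alignment"`.
#' @export
alignment <- function(taxa, seqs) {
  seqs <- toupper(as.matrix(seqs))
  stopifnot(length(taxa) == nrow(seqs), ncol(seqs) >= 1)
  if (!all(seqs %in% colnames(iupac_partials)))
    stop("unknown nucleotide state(s): ",
         paste(setdiff(unique(c(seqs)), colnames(iupac_partials)),
               collapse = ", "))
  rownames(seqs) <- taxa
  structure(list(taxa = taxa, seqs = seqs, nsites = ncol(seqs)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Alignment:", length(x$taxa), "taxa x", x$nsites, "sites\n")
  invisible(x)
}

#' Read / write FASTA alignments
#'
#' Thin wrappers around `ape`'s FASTA support returning/accepting
#' [alignment()] objects.
#'
#' @param file path.
#' @rdname fasta_io
#' @export
read_fasta <- function(file) {
  m <- ape::read.dna(file, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  alignment(rownames(m), toupper(m))
}

#' @param aln an [alignment()].
#' @rdname fasta_io
#' @export
write_fasta <- function(aln, file) {
  con <- file(file, "w"); on.exit(close(con))
  for (i in seq_along(aln$taxa))
    writeLines(c(paste0(">", aln$taxa[i]),
                 paste(aln$seqs[i, ], collapse = "")), con)
  invisible(file)
}

# per-branch distances for either tree flavour
tree_branch_distances <- function(tree) {
  if (inherits(tree, "timetree")) {
    nonroot <- setdiff(seq_along(tree$parent), tree$root)
    d <- numeric(length(tree$parent))
    d[nonroot] <- tree$rates[nonroot] *
      (tree$times[tree$parent[nonroot]] - tree$times[nonroot])
    d
  } else if (inherits(tree, "subst_tree")) {
    d <- tree$lengths; d[tree$root] <- 0; d
  } else stop("need a timetree or subst_tree")
}

#' Felsenstein pruning log-likelihood under HKY
#'
#' Post-order pruning over per-branch transition matrices
#' `P(d_i) = exp(Q d_i)` with `d_i = r_i * dt_i`, with per-node partial
#' rescaling against underflow.  Because the model is time-reversible the
#' value is invariant under re-rooting along a branch -- the property that
#' licenses the pulley moves.
#'
#' @param tree a [timetree()] (distances from rates and spans) or a
#'   `"subst_tree"` (explicit substitution lengths).
#' @param aln an [alignment()] over the same taxa.
#' @param model an [hky_model()].
#' @return Log-likelihood of the alignment.
#' @export
pruning_log_likelihood <- function(tree, aln, model) {
  pruning_full(tree, aln, model)$loglik
}

# Full pruning pass; returns per-node partials and log scaling factors so
# the engine can update only the ancestors of a changed branch.
pruning_full <- function(tree, aln, model) {
  if (!setequal(tree$taxa, aln$taxa))
    stop("tree and alignment taxa differ")
  cache <- list(partial = vector("list", 2L * tree$ntaxa - 1L),
                scalelog = numeric(2L * tree$ntaxa - 1L))
  for (v in seq_len(tree$ntaxa))
    cache$partial[[v]] <-
      iupac_partials[, aln$seqs[tree$taxa[v], ], drop = FALSE]
  d <- tree_branch_distances(tree)
  post <- postorder_nodes(tree)
  for (v in post[post > tree$ntaxa])
    cache <- recompute_partial(tree, model, d, cache, v)
  list(loglik = root_loglik(tree, model, cache), cache = cache)
}

recompute_partial <- function(tree, model, d, cache, v) {
  kids <- tree$children[[v]]
  P1 <- hky_transition_matrix(model, d[kids[1]])
  P2 <- hky_transition_matrix(model, d[kids[2]])
  acc <- (P1 %*% cache$partial[[kids[1]]]) *
    (P2 %*% cache$partial[[kids[2]]])
  # per-node rescaling is only needed when the tree is deep enough for the
  # partials to underflow a double
  if (tree$ntaxa > 60L) {
    mx <- pmax(acc[1, ], acc[2, ], acc[3, ], acc[4, ])
    cache$partial[[v]] <- acc * rep.int(1 / mx, rep.int(4L, length(mx)))
    cache$scalelog[v] <- sum(log(mx))
  } else {
    cache$partial[[v]] <- acc
  }
  cache
}

root_loglik <- function(tree, model, cache) {
  sum(log(as.numeric(model$pi %*% cache$partial[[tree$root]]))) +
    sum(cache$scalelog)
}

# Update the cache after the branches above `dirty` changed distance:
# recompute the partials of their ancestors, bottom-up.
pruning_update <- function(tree, model, cache, dirty) {
  d <- tree_branch_distances(tree)
  affected <- integer(0)
  for (v in dirty) {
    a <- if (is.na(tree$parent[v])) v else tree$parent[v]
    while (!is.na(a)) {
      if (a %in% affected) break
      affected <- c(affected, a)
      a <- tree$parent[a]
    }
  }
  # bottom-up: order by number of ancestors (depth)
  depth <- vapply(affected, function(v) length(ancestors_of(tree, v)), 1L)
  for (v in affected[order(-depth)])
    cache <- recompute_partial(tree, model, d, cache, v)
  list(loglik = root_loglik(tree, model, cache), cache = cache)
}

#' Simulate an alignment along a tree
#'
#' Draws root states from the stationary frequencies and evolves them down
#' every branch with the HKY transition matrix for that branch's genetic
#' distance.
#'
#' @param tree a [timetree()] or `"subst_tree"`.
#' @param model an [hky_model()].
#' @param n_sites number of independent sites.
#' @param seed optional RNG seed for reproducibility.
#' @return An [alignment()].
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL) {
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- tree_branch_distances(tree)
  b <- c("A", "C", "G", "T")
  nnode <- 2L * tree$ntaxa - 1L
  states <- matrix(NA_integer_, nnode, n_sites)
  states[tree$root, ] <- sample.int(4, n_sites, replace = TRUE,
                                    prob = model$pi)
  for (v in preorder_nodes(tree)) {
    if (v == tree$root) next
    P <- hky_transition_matrix(model, d[v])
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n_sites)
    par_state <- states[tree$parent[v], ]
    states[v, ] <- 1L + rowSums(cum[par_state, , drop = FALSE] <
                                  u)
  }
  alignment(tree$taxa,
            matrix(b[states[seq_len(tree$ntaxa), ]], tree$ntaxa, n_sites))
}
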