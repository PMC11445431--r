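# --- state handling -----------------------------------------------------

# Align tip states to tree$tip.label and encode them as integer indices into
# an ordered state space. Missing tips (NA or absent names) stay NA.
normalize_tip_states <- function(tree, tip_states, state_space = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(tip_states)) && length(tip_states) == length(tree$tip.label))
    names(tip_states) <- tree$tip.label
  x <- tip_states[tree$tip.label]
  if (is.null(state_space)) {
    obs <- unique(x[!is.na(x)])
    state_space <- as.character(sort(obs))
  }
  idx <- match(as.character(x), as.character(state_space))
  if (any(!is.na(x) & is.na(idx)))
    stop("tip states outside the declared state space")
  list(idx = idx, state_space = as.character(state_space),
       k = length(state_space))
}

# ER transition matrix: all off-diagonal rates equal q.
er_pmat <- function(k, q, t) {
  e <- exp(-k * q * t)
  stay <- 1 / k + (1 - 1 / k) * e
  sw <- (1 - e) / k
  P <- matrix(sw, k, k)
  diag(P) <- stay
  P
}

# --- rooting ------------------------------------------------------------

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. A stand-in
#' for rooting tools that need outgroup or deviation statistics; downstream
#' statistics only require a rooted topology with branch lengths.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return a rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0) stop("degenerate tree: total branch length is zero")
  if (ape::Ntip(tree) == 2) {
    half <- sum(tree$edge.length) / 2
    tree$edge.length <- rep(half, nrow(tree$edge))
    return(tree)
  }
  phangorn::midpoint(tree)
}

# --- equal-rates likelihood ---------------------------------------------

#' Log-likelihood of tip states under the equal-rates Markov model
#'
#' Felsenstein pruning with the closed-form ER transition probabilities
#' `P_stay(t) = 1/k + (1 - 1/k) e^(-kqt)`, `P_switch(t) = (1 - e^(-kqt)) / k`,
#' and a flat root prior `1/k`. Missing tip states contribute all-ones
#' partials. Computed with per-node rescaling, so long trees do not
#' underflow.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_states named vector (tip label -> state); `NA` = unknown.
#' @param q equal transition rate (>= 0).
#' @param state_space ordered state ids; derived from the observed states
#'   when `NULL`. Must have k >= 2.
#' @return log-likelihood (scalar; `-Inf` for impossible histories).
#' @export
er_log_likelihood <- function(tree, tip_states, q, state_space = NULL) {
  if (q < 0) stop("rate q must be non-negative")
  st <- normalize_tip_states(tree, tip_states, state_space)
  k <- st$k
  if (k < 2) stop("need at least 2 states in the state space")
  pr <- er_pruning(tree, st$idx, k, q)
  root <- ape::Ntip(tree) + 1L
  s <- sum(pr$L[root, ]) / k
  if (s <= 0) return(-Inf)
  log(s) + pr$logscale[root]
}

# shared pruning pass: returns scaled partials and per-node log scale factors
er_pruning <- function(tree, idx, k, q) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  L <- matrix(1, nn, k)
  for (i in seq_len(nt)) if (!is.na(idx[i])) {
    L[i, ] <- 0
    L[i, idx[i]] <- 1
  }
  logscale <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    msg <- as.numeric(er_pmat(k, q, t) %*% L[ch, ])
    L[p, ] <- L[p, ] * msg
    logscale[p] <- logscale[p] + logscale[ch]
    s <- max(L[p, ])
    if (s > 0 && is.finite(s)) {
      L[p, ] <- L[p, ] / s
      logscale[p] <- logscale[p] + log(s)
    }
  }
  list(L = L, logscale = logscale)
}

#' Fit the equal-rates transition rate by maximum likelihood
#'
#' Scalar maximization of [er_log_likelihood()] over `q` in
#' `[1e-8, q_max]`. With fewer than 2 distinct observed tip states the
#' likelihood is monotone decreasing in `q` and the estimate is pinned to the
#' lower bound.
#'
#' @inheritParams er_log_likelihood
#' @param q_max upper bound of the search interval.
#' @param tol optimizer tolerance.
#' @return a `qs_er_fit`: list with `q`, `logLik`, `k`, `state_space`,
#'   `tree`, `tip_states`.
#' @export
fit_er_rate <- function(tree, tip_states, state_space = NULL, q_max = 100,
                        tol = 1e-8) {
  st <- normalize_tip_states(tree, tip_states, state_space)
  f <- function(q) er_log_likelihood(tree, tip_states, q, st$state_space)
  lo <- 1e-8
  if (length(unique(st$idx[!is.na(st$idx)])) < 2) {
    fit <- list(maximum = lo, objective = f(lo))
  } else {
    # the ER likelihood flattens at large q; bracket the optimum on a coarse
    # log-grid first so golden-section search cannot settle on the plateau
    grid <- exp(seq(log(lo), log(q_max), length.out = 40))
    gll <- vapply(grid, f, numeric(1))
    i <- which.max(gll)
    lower <- grid[max(1, i - 1)]
    upper <- grid[min(length(grid), i + 1)]
    fit <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
    if (gll[i] > fit$objective)
      fit <- list(maximum = grid[i], objective = gll[i])
    if (f(lo) > fit$objective) fit <- list(maximum = lo, objective = f(lo))
  }
  structure(list(q = fit$maximum, logLik = fit$objective, k = st$k,
                 state_space = st$state_space, tree = tree,
                 tip_states = tip_states),
            class = "qs_er_fit")
}

#' @export
print.qs_er_fit <- function(x, ...) {
  cat("Equal-rates (ER) Markov fit:", x$k, "states [",
      paste(x$state_space, collapse = ", "), "]\n")
  cat("  rate q =", signif(x$q, 6), " log-likelihood =", signif(x$logLik, 8), "\n")
  invisible(x)
}

#' @export
logLik.qs_er_fit <- function(object, ...) {
  structure(object$logLik, df = 1, class = "logLik")
}

#' @export
summary.qs_er_fit <- function(object, ...) {
  marg <- marginal_ancestral(object$tree, object$tip_states, object$q,
                             object$state_space)
  root <- ape::Ntip(object$tree) + 1L
  out <- list(fit = object, root_probs = marg[root, ],
              root_passed = root_confidence_filter(marg[root, ]))
  class(out) <- "summary.qs_er_fit"
  out
}

#' @export
print.summary.qs_er_fit <- function(x, ...) {
  print(x$fit)
  cat("  root state probabilities:",
      paste(names(x$root_probs), signif(x$root_probs, 4), sep = "=",
            collapse = " "), "\n")
  cat("  root confidence filter (>= 0.51):",
      if (x$root_passed) "keep" else "drop", "\n")
  invisible(x)
}

#' Marginal ancestral state probabilities under the ER model
#'
#' Standard two-pass algorithm: downward (pruning) partials plus upward
#' messages, giving for every node the posterior probability of each state
#' given all tips, the fitted rate and a flat root prior. Each node's vector
#' sums to 1; observed tips get probability 1 on their state.
#'
#' @inheritParams er_log_likelihood
#' @return matrix `(Ntip + Nnode) x k` of probabilities (rows are ape node
#'   numbers; columns named by state).
#' @export
marginal_ancestral <- function(tree, tip_states, q, state_space = NULL) {
  st <- normalize_tip_states(tree, tip_states, state_space)
  k <- st$k
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  pr <- er_pruning(tree, st$idx, k, q)
  D <- pr$L
  root <- nt + 1L

  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge
  elen <- tr$edge.length
  children <- split(seq_len(nrow(edges)), edges[, 1])

  U <- matrix(0, nn, k)
  U[root, ] <- 1 / k
  # preorder = reverse postorder over parents
  for (e in rev(seq_len(nrow(edges)))) {
    p <- edges[e, 1]
    kid_edges <- children[[as.character(p)]]
    # messages from every child of p through its own edge
    M <- lapply(kid_edges, function(ke)
      as.numeric(er_pmat(k, q, elen[ke]) %*% D[edges[ke, 2], ]))
    names(M) <- as.character(kid_edges)
    ce <- which(kid_edges == e)
    W <- U[p, ]
    for (s in seq_along(kid_edges)) if (s != ce) W <- W * M[[s]]
    u <- as.numeric(er_pmat(k, q, elen[e]) %*% W)  # ER P is symmetric
    tot <- sum(u)
    U[edges[e, 2], ] <- if (tot > 0) u / tot else rep(1 / k, k)
  }
  post <- D * U
  sums <- rowSums(post)
  bad <- sums <= 0 | !is.finite(sums)
  post[bad, ] <- 1 / k
  post <- post / rowSums(post)
  colnames(post) <- st$state_space
  post
}

#' Fit-and-reconstruct convenience wrapper
#'
#' Fits the ER rate and computes marginal ancestral probabilities in one
#' step. A tree whose leaves all carry the same state is retained with that
#' state certain at every node and rate 0 (no fit is possible or needed).
#'
#' @inheritParams er_log_likelihood
#' @param tip_states named vector of leaf state ids (`NA` = unknown).
#' @return list with `marginals` (node x state matrix), `rate`,
#'   `state_space`.
#' @export
er_reconstruction <- function(tree, tip_states, state_space = NULL) {
  observed <- unique(tip_states[!is.na(tip_states)])
  if (is.null(state_space) && length(observed) < 2) {
    nn <- ape::Ntip(tree) + tree$Nnode
    marg <- matrix(1, nn, 1, dimnames = list(NULL, as.character(observed)))
    return(list(marginals = marg, rate = 0,
                state_space = as.character(observed)))
  }
  fit <- fit_er_rate(tree, tip_states, state_space)
  list(marginals = marginal_ancestral(tree, tip_states, fit$q,
                                      fit$state_space),
       rate = fit$q, state_space = fit$state_space)
}

#' Determined node states from marginal probabilities
#'
#' A node's state is "determined" when its maximum marginal probability
#' exceeds `threshold` (default 0.5, mirroring the root-confidence
#' convention at internal nodes); otherwise it is `NA`.
#'
#' @param marginals matrix from [marginal_ancestral()].
#' @param threshold determination threshold (strict `>`).
#' @return character vector of state ids (`NA` = undetermined), one per node.
#' @export
determined_states <- function(marginals, threshold = 0.5) {
  apply(marginals, 1, function(p) {
    m <- max(p)
    if (m > threshold && sum(p == m) == 1) colnames(marginals)[which.max(p)]
    else NA_character_
  })
}

#' Root-confidence filter
#'
#' Keep a tree only when the most likely root state has at least `threshold`
#' probability.
#'
#' @param root_probs probability vector at the root (sums to 1).
#' @param threshold minimum top probability (default 0.51; `>=`).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @export
root_confidence_filter <- function(root_probs, threshold = 0.51) {
  max(root_probs) >= threshold
}

# --- parsimony ----------------------------------------------------------

#' ACCTRAN parsimony reconstruction
#'
#' Downpass via Hartigan's generalization of Fitch (exact on arbitrary
#' out-degree), then a preorder pass resolving ambiguity by preferring the
#' parent's assigned state (accelerating changes toward the root), then the
#' lowest state index. Missing tips act as fully ambiguous and never force a
#' change.
#'
#' @inheritParams er_log_likelihood
#' @return list with `states` (character vector of assigned state ids, one
#'   per node), `score` (minimum number of state changes), `state_space`.
#' @export
acctran_parsimony <- function(tree, tip_states, state_space = NULL) {
  st <- normalize_tip_states(tree, tip_states, state_space)
  k <- st$k
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  S <- matrix(TRUE, nn, k)
  for (i in seq_len(nt)) if (!is.na(st$idx[i])) {
    S[i, ] <- FALSE
    S[i, st$idx[i]] <- TRUE
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge
  kids <- split(edges[, 2], edges[, 1])
  score <- 0L
  # process each internal node once all its child edges (and hence all child
  # subtrees) have appeared: ascending order of last occurrence in postorder
  node_order <- rev(unique(rev(edges[, 1])))
  for (p in node_order) {
    cnt <- colSums(S[kids[[as.character(p)]], , drop = FALSE])
    m <- max(cnt)
    S[p, ] <- cnt == m
    score <- score + (length(kids[[as.character(p)]]) - m)
  }
  assign <- integer(nn)
  root <- nt + 1L
  assign[root] <- which(S[root, ])[1]
  for (e in rev(seq_len(nrow(edges)))) {   # preorder
    p <- edges[e, 1]; ch <- edges[e, 2]
    assign[ch] <- if (S[ch, assign[p]]) assign[p] else which(S[ch, ])[1]
  }
  list(states = st$state_space[assign], score = as.integer(score),
       state_space = st$state_space)
}
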