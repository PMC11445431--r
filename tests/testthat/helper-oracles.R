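# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive and separate from the package's own implementations.

# ER transition matrix (re-derived here, not imported from the package)
oracle_er_pmat <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (1 - 1 / k) * e
  P
}

# joint probability of every full labeling, by exhaustive enumeration
oracle_er_joint <- function(tree, tip_idx, k, q) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  internal <- (nt + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  st <- matrix(NA_integer_, nrow(grid), nn)
  st[, seq_len(nt)] <- matrix(tip_idx, nrow(grid), nt, byrow = TRUE)
  st[, internal] <- grid
  P <- lapply(tree$edge.length, function(t) oracle_er_pmat(k, q, t))
  p <- rep(1 / k, nrow(grid))
  for (e in seq_len(nrow(tree$edge)))
    p <- p * P[[e]][cbind(st[, tree$edge[e, 1]], st[, tree$edge[e, 2]])]
  list(states = st, p = p, internal = internal, nn = nn)
}

# log-likelihood by exhaustive summation over all internal-node labelings
oracle_er_loglik <- function(tree, tip_idx, k, q) {
  log(sum(oracle_er_joint(tree, tip_idx, k, q)$p))
}

# marginal posteriors at internal nodes by the same exhaustive sum
oracle_er_marginals <- function(tree, tip_idx, k, q) {
  j <- oracle_er_joint(tree, tip_idx, k, q)
  post <- matrix(0, j$nn, k)
  for (v in j$internal) for (s in seq_len(k))
    post[v, s] <- sum(j$p[j$states[, v] == s])
  post[j$internal, ] <- post[j$internal, ] /
    rowSums(post[j$internal, , drop = FALSE])
  post
}

# minimum number of state changes by exhaustive internal labeling
oracle_parsimony_min <- function(tree, tip_idx, k) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  internal <- (nt + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  st <- matrix(NA_integer_, nrow(grid), nn)
  st[, seq_len(nt)] <- matrix(tip_idx, nrow(grid), nt, byrow = TRUE)
  st[, internal] <- grid
  cost <- integer(nrow(grid))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (st[, tree$edge[e, 1]] != st[, tree$edge[e, 2]])
  min(cost)
}

# affine-gap global alignment score by straightforward Gotoh DP
oracle_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- S[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                   X[i - 1, j] - gap_extend)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                   Y[i, j - 1] - gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# random rooted tree with seeded branch lengths
random_tree <- function(n, seed, min_len = 0.05, max_len = 2) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
    tr
  })
}
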