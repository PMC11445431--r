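# Synthetic-data generators. Every generator is a pure function of its seed
# and parameters: all draws go through withr::with_seed on a local RNG state.

#' Reference areas for pseudo-atom toy structures
#'
#' Toy complexes use one sphere per residue, so the RSA denominator is the
#' isolated-residue sphere area `4 pi (r + probe)^2` rather than Miller
#' values (which presume full side chains).
#'
#' @param bead_radius residue sphere radius in Angstrom.
#' @param probe_radius probe radius in Angstrom.
#' @return named numeric vector over 3- and 1-letter residue codes.
#' @export
toy_reference_areas <- function(bead_radius = 1.9, probe_radius = 1.4) {
  area <- 4 * pi * (bead_radius + probe_radius)^2
  aa1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  setNames(rep(area, 40), c(bio3d::aa123(aa1), aa1))
}

# compact self-avoiding bead chain: greedy walk biased toward the centroid
compact_chain <- function(n_residues, step = 3.8, min_dist = 3.6,
                          max_retries = 50) {
  for (retry in seq_len(max_retries)) {
    pos <- matrix(NA_real_, n_residues, 3)
    pos[1, ] <- 0
    ok <- TRUE
    for (i in 2:n_residues) {
      u <- matrix(stats::rnorm(3 * 24), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      cand <- sweep(u * step, 2, pos[i - 1, ], "+")
      prev <- pos[seq_len(i - 2), , drop = FALSE]
      valid <- rep(TRUE, nrow(cand))
      if (nrow(prev)) {
        for (j in seq_len(nrow(cand)))
          valid[j] <- all(sqrt(colSums((t(prev) - cand[j, ])^2)) >= min_dist)
      }
      if (!any(valid)) { ok <- FALSE; break }
      cen <- colMeans(pos[seq_len(i - 1), , drop = FALSE])
      d2c <- rowSums(sweep(cand, 2, cen)^2)
      d2c[!valid] <- Inf
      pos[i, ] <- cand[which.min(d2c), ]
    }
    if (ok) return(pos)
  }
  stop("generation error: could not pack a self-avoiding chain")
}

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Generate a Cn-symmetric toy complex with known buried residues
#'
#' Builds a compact self-avoiding pseudo-atom chain (one sphere per residue),
#' replicates it by rotation about the z axis, and slides the chains toward
#' the axis until adjacent subunits touch (minimum inter-chain bead distance
#' within `contact_range`). The ground-truth buried set is every residue
#' whose bead lies within `2 * bead_radius + probe` of a neighbouring chain:
#' below that separation the probe centre cannot pass between the spheres,
#' so the residue loses substantial SASA on assembly.
#'
#' @param n_subunits number of chains (>= 1).
#' @param n_residues residues per chain (>= 20).
#' @param seed integer seed (required; the generator is deterministic per
#'   seed).
#' @param bead_radius residue sphere radius (default 1.9 A).
#' @param probe_radius probe radius used for the burial cutoff (default 1.4).
#' @param contact_range admissible band for the minimum inter-chain bead
#'   distance, in Angstrom.
#' @return a `qs_toy_complex`: list with `assembly` (`qs_assembly`),
#'   `buried_truth` (residue keys), `applied_transform` (rotation angle and
#'   radial offset), `reference_area` (isolated-bead sphere area).
#' @export
gen_cn_complex <- function(n_subunits, n_residues = 40, seed,
                           bead_radius = 1.9, probe_radius = 1.4,
                           contact_range = c(4.0, 4.6)) {
  stopifnot(n_subunits >= 1, n_residues >= 20)
  res <- withr::with_seed(seed, {
    chain <- compact_chain(n_residues)
    chain <- sweep(chain, 2, colMeans(chain))
    aa <- sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                 n_residues, replace = TRUE)
    list(chain = chain, aa = aa)
  })
  chain <- res$chain
  offset <- 0
  if (n_subunits > 1) {
    theta <- 2 * pi / n_subunits
    min_cross <- function(d) {
      c0 <- sweep(chain, 2, c(d, 0, 0), "+")
      c1 <- c0 %*% rot_z(theta)
      min(sqrt(pmax(outer(rowSums(c0^2), rowSums(c1^2), "+") -
                      2 * c0 %*% t(c1), 0)))
    }
    lo <- 0
    hi <- 2 * max(sqrt(rowSums(chain^2))) + 10
    target <- mean(contact_range)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      v <- min_cross(mid)
      if (v >= contact_range[1] && v <= contact_range[2]) { lo <- hi <- mid; break }
      if (v < target) lo <- mid else hi <- mid
    }
    offset <- (lo + hi) / 2
  }
  chains <- LETTERS[seq_len(n_subunits)]
  placed <- lapply(seq_len(n_subunits) - 1, function(j) {
    sweep(chain, 2, c(offset, 0, 0), "+") %*% rot_z(2 * pi * j / max(1, n_subunits))
  })
  atoms <- do.call(rbind, lapply(seq_along(placed), function(j) {
    data.frame(chain = chains[j], resno = seq_len(n_residues), icode = "",
               resname = bio3d::aa123(res$aa), elety = "CA", element = "C",
               x = placed[[j]][, 1], y = placed[[j]][, 2], z = placed[[j]][, 3],
               radius = bead_radius, is_hetero = FALSE,
               stringsAsFactors = FALSE)
  }))
  assembly <- make_assembly(atoms)
  buried <- character(0)
  if (n_subunits > 1) {
    cutoff <- 2 * bead_radius + probe_radius
    xyz <- lapply(placed, identity)
    for (j in seq_len(n_subunits)) {
      others <- do.call(rbind, xyz[-j])
      d <- sqrt(pmax(outer(rowSums(xyz[[j]]^2), rowSums(others^2), "+") -
                       2 * xyz[[j]] %*% t(others), 0))
      hit <- apply(d, 1, min) < cutoff
      buried <- c(buried, residue_key(chains[j], which(hit), ""))
    }
    if (!length(buried))
      stop("generation error: contact placement produced no buried residues")
  }
  structure(list(assembly = assembly, buried_truth = buried,
                 applied_transform = list(angle = if (n_subunits > 1)
                   2 * pi / n_subunits else 0, offset = offset),
                 reference_area = 4 * pi * (bead_radius + probe_radius)^2),
            class = "qs_toy_complex")
}

#' Generate a pure-birth (Yule) tree
#'
#' Forward simulation with unit birth rate starting from two lineages; after
#' the n-th lineage is born, all pendant branches are extended by a final
#' Exp(n * rate) waiting time. Expected tree height is therefore
#' `sum_{k=2}^{n} 1/k` at unit rate, which the tests use as a closed-form
#' check. Deterministic per seed.
#'
#' @param n_leaves number of tips (>= 2).
#' @param seed integer seed.
#' @param birth_rate per-lineage birth rate (default 1).
#' @return a rooted `ape::phylo` with tips labelled `t1..tn`.
#' @export
gen_birth_tree <- function(n_leaves, seed, birth_rate = 1) {
  stopifnot(n_leaves >= 2)
  withr::with_seed(seed, {
    start <- c(0, 0)           # birth time per lineage
    parent <- c(NA, NA)        # splitting lineage that created it
    is_tip <- c(TRUE, TRUE)
    end <- c(NA_real_, NA_real_)
    t <- 0
    while (sum(is_tip) < n_leaves) {
      k <- sum(is_tip)
      t <- t + stats::rexp(1, k * birth_rate)
      live <- which(is_tip)
      i <- live[sample.int(length(live), 1)]
      is_tip[i] <- FALSE
      end[i] <- t
      start <- c(start, t, t)
      parent <- c(parent, i, i)
      is_tip <- c(is_tip, TRUE, TRUE)
      end <- c(end, NA, NA)
    }
    t_end <- t + stats::rexp(1, n_leaves * birth_rate)
    end[is_tip] <- t_end
    nwk_of <- function(i) {
      kids <- which(parent == i)
      len <- end[i] - start[i]
      if (!length(kids)) return(sprintf("L%d:%.10f", i, len))
      inner <- paste(vapply(kids, nwk_of, character(1)), collapse = ",")
      sprintf("(%s):%.10f", inner, len)
    }
    nwk <- sprintf("(%s,%s);", nwk_of(1), nwk_of(2))
    tree <- ape::read.tree(text = nwk)
    tree$tip.label <- paste0("t", seq_along(tree$tip.label))
    tree
  })
}

#' Equal-rates generator matrix
#'
#' @param state_ids character state ids (k >= 2).
#' @param q common off-diagonal rate.
#' @return k x k generator matrix (rows sum to 0).
#' @export
er_generator <- function(state_ids, q) {
  k <- length(state_ids)
  Q <- matrix(q, k, k, dimnames = list(state_ids, state_ids))
  diag(Q) <- -(k - 1) * q
  Q
}

#' Stepwise gain/loss generator over a subunit-count ladder
#'
#' States are subunit counts; gains move one rung up at `gain_rate`, losses
#' one rung down at `loss_rate`. Emulates a ratchet when
#' `gain_rate > loss_rate`.
#'
#' @param counts increasing integer subunit counts (e.g. `c(1, 2, 4)`).
#' @param gain_rate,loss_rate per-unit-branch-length rates.
#' @return generator matrix with state ids `as.character(counts)`.
#' @export
ladder_generator <- function(counts = c(1, 2, 4), gain_rate, loss_rate) {
  k <- length(counts)
  ids <- as.character(counts)
  Q <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) Q[i, i + 1] <- gain_rate
  for (i in 2:k) Q[i, i - 1] <- loss_rate
  diag(Q) <- -rowSums(Q)
  Q
}

#' Simulate a discrete-trait history along a tree
#'
#' Exact stochastic simulation (exponential waiting times) of a
#' continuous-time Markov chain along every branch, with the full event log.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param rates generator matrix (rows sum to 0, off-diagonals >= 0), with
#'   state ids as dimnames.
#' @param root_state state id at the root.
#' @param seed integer seed.
#' @return a `qs_sim_history`: list with `tree`, `node_states` (ids per ape
#'   node number), `tip_states` (named by tip label), `events` (data.frame
#'   edge, time, from, to), `rates`.
#' @export
sim_trait_history <- function(tree, rates, root_state, seed) {
  ids <- rownames(rates)
  stopifnot(!is.null(ids), all(abs(rowSums(rates)) < 1e-9),
            root_state %in% ids)
  off <- rates; diag(off) <- 0
  stopifnot(all(off >= 0))
  withr::with_seed(seed, {
    nt <- ape::Ntip(tree)
    nn <- nt + tree$Nnode
    tr <- ape::reorder.phylo(tree, "postorder")
    state <- integer(nn)
    state[nt + 1L] <- match(root_state, ids)
    ev <- list()
    for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; len <- tr$edge.length[e]
      s <- state[p]
      t <- 0
      repeat {
        rate <- -rates[s, s]
        if (rate <= 0) break
        t <- t + stats::rexp(1, rate)
        if (t > len) break
        to <- sample.int(length(ids), 1, prob = off[s, ] / rate)
        ev[[length(ev) + 1]] <- data.frame(edge = e, time = t,
                                           from = ids[s], to = ids[to])
        s <- to
      }
      state[ch] <- s
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(edge = integer(0), time = numeric(0),
                 from = character(0), to = character(0))
    node_states <- ids[state]
    structure(list(tree = tree, edge_order = tr$edge,
                   node_states = node_states,
                   tip_states = setNames(node_states[seq_len(nt)],
                                         tree$tip.label),
                   events = events, rates = rates),
              class = "qs_sim_history")
  })
}

#' Replay a simulated history's event log
#'
#' Re-derives every node state from the root state and the event log alone;
#' used to check event-log consistency.
#'
#' @param history a `qs_sim_history`.
#' @return character vector of node states, comparable to
#'   `history$node_states`.
#' @export
replay_history <- function(history) {
  tree <- history$tree
  nt <- ape::Ntip(tree)
  edges <- history$edge_order
  state <- rep(NA_character_, nt + tree$Nnode)
  root <- nt + 1L
  state[root] <- history$node_states[root]
  for (e in rev(seq_len(nrow(edges)))) {
    s <- state[edges[e, 1]]
    ev <- history$events[history$events$edge == e, , drop = FALSE]
    if (nrow(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      stopifnot(ev$from[1] == s)
      s <- ev$to[nrow(ev)]
    }
    state[edges[e, 2]] <- s
  }
  state
}

#' Generate per-residue conservation scores with interface enrichment
#'
#' Surface and core residues draw from Normal(0, `noise_sd`); interface
#' residues from Normal(`-interface_shift`, `noise_sd`) — lower scores mean
#' more conserved (ConSurf convention), so a positive shift makes interfaces
#' more conserved.
#'
#' @param profile a `qs_interface_profile` (its `region_of` is used).
#' @param interface_shift conservation enrichment of the interface, in score
#'   units.
#' @param noise_sd score standard deviation.
#' @param seed integer seed.
#' @return named numeric vector keyed by residue key.
#' @export
gen_conservation_scores <- function(profile, interface_shift, noise_sd, seed) {
  region <- profile$region_of
  stopifnot(length(region) > 0)
  withr::with_seed(seed, {
    mu <- ifelse(region == "interface", -interface_shift, 0)
    setNames(stats::rnorm(length(region), mu, noise_sd), names(region))
  })
}

#' Generate a synthetic abundance table
#'
#' Lognormal abundances (ppm); homomer abundances shifted by
#' `homomer_log_shift` on the log scale, with subunit counts drawn from
#' `subunit_dist`.
#'
#' @param n_monomers,n_homomers group sizes.
#' @param log_mean,log_sd lognormal parameters of the monomer group.
#' @param homomer_log_shift additive log-scale shift for homomers.
#' @param subunit_dist named probability vector over homomer subunit counts
#'   (names = counts), e.g. `c("2" = 1)`.
#' @param seed integer seed.
#' @return data.frame with `id`, `is_homomer`, `abundance`, `n_subunits`,
#'   `scaled_abundance`.
#' @export
gen_abundance <- function(n_monomers, n_homomers, log_mean = 3, log_sd = 2,
                          homomer_log_shift = 0, subunit_dist = c("2" = 1),
                          seed) {
  stopifnot(abs(sum(subunit_dist) - 1) < 1e-9)
  withr::with_seed(seed, {
    mono <- stats::rlnorm(n_monomers, log_mean, log_sd)
    homo <- stats::rlnorm(n_homomers, log_mean + homomer_log_shift, log_sd)
    counts <- as.integer(sample(names(subunit_dist), n_homomers,
                                replace = TRUE, prob = subunit_dist))
    ab <- c(mono, homo)
    ns <- c(rep(1L, n_monomers), counts)
    rec <- scaled_abundance(ab, ns)
    cbind(data.frame(id = sprintf("p%04d", seq_along(ab)),
                     is_homomer = c(rep(FALSE, n_monomers),
                                    rep(TRUE, n_homomers))),
          rec)
  })
}
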