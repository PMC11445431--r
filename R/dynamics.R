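#' Subunit count encoded in a state id
#'
#' State ids are `"monomer"`, `"homomer"` (binary mode, count unknown),
#' `"<n>:<group>"` (multi-state) or a bare count `"<n>"`.
#'
#' @param ids character vector of state ids.
#' @return integer vector of subunit counts (`NA` where not encoded).
#' @export
subunit_count_of <- function(ids) {
  out <- rep(NA_integer_, length(ids))
  out[ids == "monomer"] <- 1L
  num <- grepl("^[0-9]+(:.*)?$", ids) & !is.na(ids)
  out[num] <- as.integer(sub(":.*$", "", ids[num]))
  out
}

# determined parent/child state pairs over the tree's edges
edge_state_pairs <- function(tree, node_states) {
  stopifnot(inherits(tree, "phylo"))
  nn <- ape::Ntip(tree) + tree$Nnode
  if (length(node_states) != nn)
    stop("node_states must have one entry per node (tips then internals)")
  ps <- node_states[tree$edge[, 1]]
  cs <- node_states[tree$edge[, 2]]
  ok <- !is.na(ps) & !is.na(cs)
  data.frame(parent = ps[ok], child = cs[ok], stringsAsFactors = FALSE)
}

#' Frequency of quaternary-structure changes along a tree
#'
#' Number of parent-child node pairs whose states differ, divided by the
#' number of pairs where both states are determined. Pairs with an
#' undetermined member are excluded from numerator and denominator.
#'
#' @param tree rooted `phylo`.
#' @param node_states character vector of determined state ids per node
#'   (ape numbering: tips 1..Ntip, then internals), `NA` = undetermined.
#' @return fraction in \[0, 1\].
#' @export
change_frequency <- function(tree, node_states) {
  pairs <- edge_state_pairs(tree, node_states)
  if (!nrow(pairs))
    stop("undefined change frequency: no parent-child pair has both states determined")
  mean(pairs$parent != pairs$child)
}

#' Subunit gain and loss counts along a tree
#'
#' Per determined parent-child pair: a gain when the child's subunit count
#' exceeds the parent's, a loss when it is smaller. State changes at equal
#' subunit count (interface-homology switches) count as neither. A multi-rung
#' jump on one edge is one event.
#'
#' @inheritParams change_frequency
#' @return list with `n_gains`, `n_losses`, `n_pairs` (determined pairs with
#'   known subunit counts on both ends).
#' @export
gain_loss_counts <- function(tree, node_states) {
  pairs <- edge_state_pairs(tree, node_states)
  if (!nrow(pairs))
    stop("undefined gain/loss counts: no determined parent-child pairs")
  pc <- subunit_count_of(pairs$parent)
  cc <- subunit_count_of(pairs$child)
  ok <- !is.na(pc) & !is.na(cc)
  list(n_gains = sum(cc[ok] > pc[ok]),
       n_losses = sum(cc[ok] < pc[ok]),
       n_pairs = sum(ok))
}

#' Per-tree location and distance summaries
#'
#' Computes the tree-shape and cellular-location summaries reported per
#' orthogroup: mean root-to-leaf distance, mean pairwise leaf distance,
#' fraction of extracellular leaves, the modal quaternary structure among
#' extracellular leaves (ties give `NA`), and whether that modal state
#' matches the root state.
#'
#' @param tree rooted `phylo`.
#' @param leaf_states named character vector of leaf state ids.
#' @param locations named character vector of leaf locations
#'   (`"cytoplasmic"`, `"extracellular"`, `"other"`, `NA` = unknown).
#' @param root_state root state id (e.g. argmax of the root marginals).
#' @param min_located minimum number of leaves with known location for the
#'   location-dependent fields (default 5; fewer gives `NA`s).
#' @return one-row data.frame.
#' @export
tree_summaries <- function(tree, leaf_states, locations = NULL,
                           root_state = NA_character_, min_located = 5) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  coph <- ape::cophenetic.phylo(tree)
  mean_pair <- mean(coph[upper.tri(coph)])
  out <- data.frame(mean_root_distance = mean(depths),
                    mean_pairwise_distance = mean_pair,
                    extracellular_fraction = NA_real_,
                    modal_extracellular_qs = NA_character_,
                    root_vs_extracellular_match = NA,
                    stringsAsFactors = FALSE)
  if (is.null(locations)) return(out)
  loc <- locations[tree$tip.label]
  known <- !is.na(loc)
  if (sum(known) < min_located) return(out)
  out$extracellular_fraction <- mean(loc[known] == "extracellular")
  ex_tips <- tree$tip.label[known & loc == "extracellular"]
  ex_states <- leaf_states[ex_tips]
  ex_states <- ex_states[!is.na(ex_states)]
  if (length(ex_states)) {
    tab <- table(ex_states)
    top <- tab[tab == max(tab)]
    if (length(top) == 1) {
      out$modal_extracellular_qs <- names(top)
      if (!is.na(root_state))
        out$root_vs_extracellular_match <- identical(names(top), root_state)
    }
  }
  out
}

#' Consolidated per-orthogroup report
#'
#' One row combining the ancestral-state, ratchet and location summaries of a
#' single orthogroup tree.
#'
#' @param tree rooted `phylo`.
#' @param marginals matrix from [marginal_ancestral()].
#' @param leaf_states named character vector of leaf state ids.
#' @param locations optional named location vector (see [tree_summaries()]).
#' @param interface_areas optional named numeric vector of per-protein
#'   interface areas (A^2) over the leaves.
#' @param determine_threshold internal-node determination threshold.
#' @return one-row data.frame (an `OrthogroupReport`).
#' @export
orthogroup_report <- function(tree, marginals, leaf_states, locations = NULL,
                              interface_areas = NULL,
                              determine_threshold = 0.5) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  node_states <- determined_states(marginals, determine_threshold)
  # annotated leaves are always determined
  node_states[seq_len(nt)] <- unname(leaf_states[tree$tip.label])
  root_probs <- marginals[root, ]
  root_state <- colnames(marginals)[which.max(root_probs)]
  gl <- tryCatch(gain_loss_counts(tree, node_states),
                 error = function(e) list(n_gains = NA_integer_,
                                          n_losses = NA_integer_,
                                          n_pairs = 0L))
  cf <- tryCatch(change_frequency(tree, node_states),
                 error = function(e) NA_real_)
  mean_area <- if (is.null(interface_areas)) NA_real_ else
    mean(interface_areas[tree$tip.label], na.rm = TRUE)
  cbind(data.frame(n_leaves = nt,
                   root_state = root_state,
                   root_prob = max(root_probs),
                   root_passed = root_confidence_filter(root_probs),
                   change_frequency = cf,
                   n_gains = gl$n_gains, n_losses = gl$n_losses,
                   n_determined_pairs = gl$n_pairs,
                   mean_interface_area = mean_area,
                   stringsAsFactors = FALSE),
        tree_summaries(tree, leaf_states, locations, root_state))
}
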