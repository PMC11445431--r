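#' Interface overlap between two corresponded structures
#'
#' Number of structurally aligned residue pairs where both residues belong to
#' an interface, divided by the size of the smaller interface. The
#' min-normalization makes the statistic symmetric.
#'
#' @param pairs data.frame with columns `keyA`, `keyB` (residue keys of
#'   corresponded residues).
#' @param interfaceA,interfaceB character vectors of interface residue keys.
#' @return fraction in \[0, 1\], or `NA` when either interface is empty
#'   (undefined overlap, excluded from averages).
#' @export
interface_overlap <- function(pairs, interfaceA, interfaceB) {
  if (!length(interfaceA) || !length(interfaceB)) return(NA_real_)
  hits <- sum(pairs$keyA %in% interfaceA & pairs$keyB %in% interfaceB)
  hits / min(length(interfaceA), length(interfaceB))
}

#' Pairwise overlap and TM-score matrices for a set of homomers
#'
#' Superposes every pair of first subunits ([iterative_superpose()]) and
#' computes the interface overlap for each. Diagonal overlaps are 1 for
#' proteins with a non-empty interface.
#'
#' @param structures named list of `qs_assembly` (one per protein; first
#'   chain used).
#' @param interfaces named list of interface residue-key vectors (first
#'   subunit), parallel to `structures`.
#' @param ... passed to [iterative_superpose()].
#' @return a `qs_overlap_matrix`: list with `proteins`, `overlap` and `tm`
#'   (symmetric matrices).
#' @export
overlap_matrix <- function(structures, interfaces, ...) {
  ids <- names(structures)
  stopifnot(!is.null(ids), setequal(ids, names(interfaces)))
  n <- length(ids)
  ov <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  tm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ov[i, i] <- if (length(interfaces[[ids[i]]])) 1 else NA_real_
    tm[i, i] <- 1
    if (i == n) next
    for (j in seq(i + 1, n)) {
      sup <- iterative_superpose(structures[[ids[i]]], structures[[ids[j]]], ...)
      pr <- sup$correspondence
      o <- interface_overlap(pr, interfaces[[ids[i]]], interfaces[[ids[j]]])
      ov[i, j] <- ov[j, i] <- o
      tm[i, j] <- tm[j, i] <- sup$tm_score
    }
  }
  structure(list(proteins = ids, overlap = ov, tm = tm),
            class = "qs_overlap_matrix")
}

#' Interface-homology groups by connected components
#'
#' Builds a graph over proteins with an edge whenever the pairwise interface
#' overlap reaches `threshold` (the overlap is normalized by the smaller
#' interface, so "at least 50% of the smaller interface aligned" is a single
#' symmetric criterion) and returns connected components. Group ids are
#' deterministic: each group is labelled by its lexicographically smallest
#' member.
#'
#' @param matrix a `qs_overlap_matrix`, or a plain symmetric overlap matrix
#'   with dimnames.
#' @param threshold overlap threshold (default 0.5; edge when `>=`).
#' @return named character vector: protein id -> group id.
#' @export
homology_groups <- function(matrix, threshold = 0.5) {
  ov <- if (inherits(matrix, "qs_overlap_matrix")) matrix$overlap else matrix
  ids <- rownames(ov)
  adj <- !is.na(ov) & ov >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- vapply(split(ids, comp), min, character(1))
  setNames(unname(labels[as.character(comp)]), ids)
}

#' Quaternary-structure state constructor
#'
#' @param n_subunits subunit count (>= 1).
#' @param homology_group interface-homology group id (ignored for monomers).
#' @param kind `"binary"` or `"multi"`.
#' @return a `qs_state` list with `kind`, `is_homomer`, `n_subunits`,
#'   `homology_group` and a canonical `id` string ("monomer", "homomer", or
#'   "<n>:<group>").
#' @export
qs_state <- function(n_subunits, homology_group = NA_character_,
                     kind = c("multi", "binary")) {
  kind <- match.arg(kind)
  stopifnot(n_subunits >= 1)
  is_homomer <- n_subunits > 1
  id <- if (kind == "binary") {
    if (is_homomer) "homomer" else "monomer"
  } else if (!is_homomer) "monomer" else {
    paste0(n_subunits, ":", homology_group)
  }
  structure(list(kind = kind, is_homomer = is_homomer,
                 n_subunits = as.integer(n_subunits),
                 homology_group = if (is_homomer) homology_group else "0",
                 id = id),
            class = "qs_state")
}

#' Assign discrete quaternary-structure states to proteins
#'
#' Binary mode distinguishes monomers from homomers; multi-state mode uses
#' (subunit count, interface-homology group) as the state identity, so
#' complexes with equal subunit counts but non-homologous interfaces are
#' separate states, and all monomers share one state.
#'
#' @param n_subunits named integer vector (protein id -> subunit count;
#'   `NA` allowed, producing a missing state).
#' @param groups named vector from [homology_groups()] (required for multi
#'   mode when homomers are present).
#' @param mode `"binary"` or `"multi"`.
#' @return named character vector of state ids (`NA` where the subunit count
#'   is unknown).
#' @export
assign_states <- function(n_subunits, groups = NULL, mode = c("binary", "multi")) {
  mode <- match.arg(mode)
  ids <- names(n_subunits)
  stopifnot(!is.null(ids))
  out <- rep(NA_character_, length(ids))
  names(out) <- ids
  for (p in ids) {
    n <- n_subunits[[p]]
    if (is.na(n)) next
    g <- if (!is.null(groups) && p %in% names(groups)) groups[[p]] else NA_character_
    out[p] <- qs_state(n, g, kind = if (mode == "binary") "binary" else "multi")$id
  }
  out
}

#' Reclassify probable quaternary-structure errors as monomers
#'
#' Homomers whose per-subunit interface area falls below `min_area` are
#' treated as quaternary-structure assignment errors and demoted to the
#' monomer state; everything else is unchanged.
#'
#' @param state a `qs_state`.
#' @param interface_area per-subunit interface area in A^2 (or a
#'   `qs_interface_profile`).
#' @param min_area threshold in A^2 (default 1000).
#' @return a `qs_state`.
#' @export
qs_error_filter <- function(state, interface_area, min_area = 1000) {
  stopifnot(inherits(state, "qs_state"))
  if (inherits(interface_area, "qs_interface_profile"))
    interface_area <- interface_area$interface_area
  if (state$is_homomer && !is.na(interface_area) && interface_area < min_area)
    return(qs_state(1, kind = state$kind))
  state
}
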