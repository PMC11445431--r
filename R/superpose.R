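#' Sequence-guided residue correspondence between two chains
#'
#' Global (Needleman-Wunsch, affine-gap) alignment of the two sequences;
#' matched columns become residue pairs. Used to seed structural
#' superposition between homologous subunits, where sequence alignment is a
#' reliable stand-in for a structure-based aligner.
#'
#' @param seqA,seqB 1-letter amino-acid strings (length >= 10).
#' @param substitution_table substitution matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (defaults 11 / 1).
#' @return a `qs_correspondence`: data.frame `pairs` with 1-based positions
#'   `posA`, `posB`; `method = "sequence-guided"`; alignment `score`.
#' @export
sequence_guided_correspondence <- function(seqA, seqB,
                                           substitution_table = "BLOSUM62",
                                           gap_open = 11, gap_extend = 1) {
  if (nchar(seqA) < 10 || nchar(seqB) < 10)
    stop("sequences shorter than 10 residues cannot be aligned reliably")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = substitution_table,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  structure(list(pairs = data.frame(posA = ia[keep], posB = ib[keep]),
                 method = "sequence-guided",
                 score = Biostrings::score(aln)),
            class = "qs_correspondence")
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `A %*% R + t` against `B` (row-vector convention). Reflections are
#' excluded by the usual determinant correction.
#'
#' @param coordsA,coordsB n x 3 matrices of paired coordinates (n >= 3,
#'   non-collinear).
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`.
#' @export
kabsch <- function(coordsA, coordsB) {
  A <- as.matrix(coordsA); B <- as.matrix(coordsB)
  if (nrow(A) < 3 || nrow(A) != nrow(B))
    stop("need >= 3 coordinate pairs for superposition")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (svd(Ac)$d[2] < 1e-9 || svd(Bc)$d[2] < 1e-9)
    stop("degenerate geometry: collinear points cannot fix a rotation")
  H <- t(Ac) %*% Bc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fit <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((fit - Bc)^2)))
  list(rotation = R, translation = as.numeric(cb - ca %*% R), rmsd = rmsd)
}

#' TM-score from superposed pair distances
#'
#' `(1 / L_norm) * sum_i 1 / (1 + (d_i / d0)^2)` with
#' `d0 = 1.24 (L_norm - 15)^(1/3) - 1.8`, floored at 0.5 A (the floor also
#' covers `L_norm < 16`, where the cube-root formula turns invalid).
#'
#' @param distances superposed residue-pair distances in Angstrom.
#' @param L_norm normalizing length (number of residues of the reference
#'   chain; by convention here, the smaller chain).
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(distances, L_norm) {
  if (!length(distances)) stop("undefined TM-score: empty correspondence")
  stopifnot(L_norm >= 1)
  d0 <- max(0.5, 1.24 * max(L_norm - 15, 0)^(1 / 3) - 1.8)
  sum(1 / (1 + (distances / d0)^2)) / L_norm
}

# one representative (CA if present) coordinate per residue of a chain
chain_ca_coords <- function(assembly, chain = assembly$chains[1]) {
  a <- assembly$atoms[assembly$atoms$chain == chain & !assembly$atoms$is_hetero, ]
  ca <- a[a$elety == "CA", ]
  rep_at <- if (nrow(ca)) ca else a[!duplicated(a$key), ]
  rep_at <- rep_at[!duplicated(rep_at$key), ]
  list(keys = rep_at$key, xyz = as.matrix(rep_at[, c("x", "y", "z")]))
}

#' Iterative superposition of two homologous structures
#'
#' Sequence-guided correspondence, then alternating Kabsch fits and rejection
#' of residue pairs farther apart than `reject_cutoff`, until the retained
#' pair set is stable (or `max_iter`). The final TM-score is computed over
#' all corresponded pairs under the final transform, normalized by the
#' smaller chain length.
#'
#' @param structA,structB `qs_assembly` objects (first chain used) with
#'   >= 10 residues each.
#' @param reject_cutoff pair-rejection distance in Angstrom (default 5).
#' @param max_iter maximum refinement iterations.
#' @param pairs optional externally produced correspondence: data.frame with
#'   columns `keyA`, `keyB` (residue keys), bypassing sequence alignment.
#' @return list with `correspondence` (data.frame `keyA`, `keyB`, `retained`),
#'   `rotation`, `translation`, `rmsd` (over retained pairs), `tm_score`,
#'   `n_aligned` (retained pair count).
#' @export
iterative_superpose <- function(structA, structB, reject_cutoff = 5,
                                max_iter = 20, pairs = NULL) {
  ca <- chain_ca_coords(structA)
  cb <- chain_ca_coords(structB)
  if (length(ca$keys) < 10 || length(cb$keys) < 10)
    stop("need >= 10 residues with coordinates in both structures")
  if (is.null(pairs)) {
    seqA <- structA$sequences[[1]]
    seqB <- structB$sequences[[1]]
    corr <- sequence_guided_correspondence(seqA, seqB)
    pairs <- data.frame(keyA = ca$keys[corr$pairs$posA],
                        keyB = cb$keys[corr$pairs$posB])
  }
  ia <- match(pairs$keyA, ca$keys)
  ib <- match(pairs$keyB, cb$keys)
  ok <- !is.na(ia) & !is.na(ib)
  pairs <- pairs[ok, ]; ia <- ia[ok]; ib <- ib[ok]
  A <- ca$xyz[ia, , drop = FALSE]
  B <- cb$xyz[ib, , drop = FALSE]
  retained <- rep(TRUE, nrow(A))
  fit <- NULL
  for (it in seq_len(max_iter)) {
    if (sum(retained) < 3)
      stop("superposition failure: fewer than 3 pairs survive rejection")
    fit <- kabsch(A[retained, , drop = FALSE], B[retained, , drop = FALSE])
    d <- sqrt(rowSums((sweep(A %*% fit$rotation, 2, fit$translation, "+") - B)^2))
    new_retained <- d <= reject_cutoff
    if (identical(new_retained, retained)) break
    if (sum(new_retained) < 3)
      stop("superposition failure: fewer than 3 pairs survive rejection")
    retained <- new_retained
  }
  d_all <- sqrt(rowSums((sweep(A %*% fit$rotation, 2, fit$translation, "+") - B)^2))
  L_norm <- min(length(ca$keys), length(cb$keys))
  list(correspondence = data.frame(keyA = pairs$keyA, keyB = pairs$keyB,
                                   retained = retained),
       rotation = fit$rotation, translation = fit$translation,
       rmsd = fit$rmsd, tm_score = tm_score(d_all, L_norm),
       n_aligned = sum(retained))
}
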