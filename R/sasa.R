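#' Deterministic unit sphere point set (golden-section spiral)
#'
#' Quadrature points for the Shrake-Rupley algorithm. The golden-section
#' spiral spreads points nearly uniformly over the sphere and involves no
#' random draws, so SASA values are bit-reproducible.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over every atom by testing quadrature points on the
#' expanded sphere of radius `r + probe` against all neighbouring expanded
#' spheres. Per-atom area is `(accessible points / n_points) * 4 pi
#' (r + probe)^2`; per-residue areas sum the residue's atoms.
#'
#' Coincident atom centres (distance < 1e-6 A) are handled deterministically:
#' each member of such a pair is treated as fully occluding the other, with a
#' warning.
#'
#' @param atoms atom data.frame with columns `x`, `y`, `z`, `radius` and
#'   (for per-residue sums) `chain`, `resno`, `icode`; or a `qs_assembly`.
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom (>= 100; default 960).
#' @return a `qs_sasa` list: `per_atom` (numeric vector, one entry per atom
#'   row), `per_residue` (named by residue key), `total` (A^2).
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960) {
  if (inherits(atoms, "qs_assembly")) atoms <- atoms$atoms
  stopifnot(n_points >= 100, probe_radius > 0, nrow(atoms) >= 1)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rext <- atoms$radius + probe_radius
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)

  # neighbour candidates via cell lists would be overkill at the sizes used
  # here; a distance matrix is fine for a few thousand atoms
  d2 <- as.matrix(stats::dist(xyz))^2
  coincident <- d2 < 1e-12 & !diag(TRUE, n)
  if (any(coincident))
    warning("coincident atom centres detected; treating them as mutually occluding")

  for (i in seq_len(n)) {
    if (any(coincident[i, ])) next  # fully occluded, area stays 0
    cut2 <- (rext[i] + rext)^2
    nb <- which(d2[i, ] < cut2 & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * rext[i]^2
      next
    }
    p <- pts * rext[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= rext[j]^2
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * rext[i]^2
  }
  key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  per_res <- tapply(per_atom, key, sum)
  per_residue <- setNames(as.numeric(per_res), names(per_res))
  structure(list(per_atom = per_atom, per_residue = per_residue,
                 total = sum(per_atom)),
            class = "qs_sasa")
}

#' Relative solvent accessibility
#'
#' Divides each residue's SASA by a reference maximal area for its residue
#' type (Miller et al. values by default). RSA can exceed 1 for extended
#' termini and is not clipped.
#'
#' @param sasa a `qs_sasa` (per-residue areas used).
#' @param resnames named character vector: residue key -> residue name
#'   (3- or 1-letter, matching the reference table keys).
#' @param reference_areas named numeric vector of reference areas.
#' @param fallback reference area used for residue names absent from the
#'   table; `NULL` (default) makes unknown names an error.
#' @return named numeric vector of RSA fractions keyed by residue key.
#' @export
relative_accessibility <- function(sasa, resnames,
                                   reference_areas = miller_reference_areas(),
                                   fallback = NULL) {
  keys <- names(sasa$per_residue)
  rn <- resnames[keys]
  if (any(is.na(rn))) stop("residues without a residue name: ",
                           paste(utils::head(keys[is.na(rn)]), collapse = ", "))
  ref <- reference_areas[rn]
  if (any(is.na(ref))) {
    if (is.null(fallback))
      stop("residue names missing from reference table: ",
           paste(unique(rn[is.na(ref)]), collapse = ", "))
    ref[is.na(ref)] <- fallback
  }
  setNames(as.numeric(sasa$per_residue / ref), keys)
}

# residue key -> resname lookup for an assembly
assembly_resnames <- function(assembly) {
  a <- assembly$atoms
  res <- a[!duplicated(a$key), ]
  setNames(res$resname, res$key)
}
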