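#' Per-subunit interface area of a complex
#'
#' Total SASA difference between the sum of the isolated subunits and the
#' assembled complex, divided by the number of subunits. Monomers score 0.
#'
#' @param sasa_subunits_total sum of subunit SASAs (A^2).
#' @param sasa_complex_total complex SASA (A^2).
#' @param n_subunits number of subunits (>= 1).
#' @param tol tolerance for a numerically negative difference.
#' @return interface area per subunit in A^2.
#' @export
interface_area <- function(sasa_subunits_total, sasa_complex_total, n_subunits,
                           tol = 1e-6) {
  stopifnot(n_subunits >= 1, sasa_subunits_total >= 0, sasa_complex_total >= 0)
  d <- sasa_subunits_total - sasa_complex_total
  if (d < -tol * max(1, sasa_subunits_total))
    stop("complex SASA exceeds subunit total beyond tolerance; inconsistent inputs")
  max(0, d) / n_subunits
}

#' Relative buried surface of a complex
#'
#' Fraction of the total subunit surface buried on assembly: (sum of subunit
#' SASAs - complex SASA) / (sum of subunit SASAs). 0 for monomers, approaches
#' 1 when nearly the whole subunit surface is buried.
#'
#' @inheritParams interface_area
#' @return fraction in \[0, 1\].
#' @export
relative_buried_surface <- function(sasa_subunits_total, sasa_complex_total) {
  if (sasa_subunits_total <= 0) stop("subunit SASA total must be positive")
  if (sasa_complex_total == 0)
    warning("complex SASA is 0; relative buried surface is 1 (degenerate input)")
  v <- (sasa_subunits_total - sasa_complex_total) / sasa_subunits_total
  min(1, max(0, v))
}

#' Hydrophobic residue fraction
#'
#' Fraction of C, F, I, L, M, V and W residues in a region.
#'
#' @param residues character vector of 1-letter (or 3-letter) residue codes.
#' @return fraction in \[0, 1\].
#' @export
hydrophobic_fraction <- function(residues) {
  if (!length(residues)) stop("empty region: hydrophobic fraction undefined")
  res <- residues
  if (any(nchar(res) == 3)) res <- suppressWarnings(bio3d::aa321(res))
  mean(res %in% c("C", "F", "I", "L", "M", "V", "W"))
}

#' Molecular weight of a (multi-subunit) protein
#'
#' Sum of water-subtracted residue masses over the sequence, minus any
#' excluded ranges (signal/transit peptides), multiplied by the number of
#' subunits.
#'
#' @param sequence 1-letter amino-acid string.
#' @param n_subunits subunit multiplier (>= 1).
#' @param exclude_ranges list of `c(start, end)` 1-based residue ranges to
#'   drop before summing.
#' @param masses named residue-mass vector, see [residue_masses()].
#' @return mass in Daltons.
#' @export
molecular_weight <- function(sequence, n_subunits = 1, exclude_ranges = list(),
                             masses = residue_masses()) {
  stopifnot(n_subunits >= 1)
  aa <- strsplit(sequence, "")[[1]]
  keep <- rep(TRUE, length(aa))
  for (r in exclude_ranges) keep[seq(r[1], r[2])] <- FALSE
  aa <- aa[keep]
  if (!length(aa)) stop("empty sequence after exclusions")
  m <- masses[aa]
  if (any(is.na(m))) stop("unknown residue letter(s): ",
                          paste(unique(aa[is.na(m)]), collapse = ", "))
  sum(m) * n_subunits
}

#' Call interface, surface and core residues from SASA differences
#'
#' A residue is *interface* when its SASA drops by more than `delta_frac` of
#' its isolated-subunit SASA on assembly AND its subunit RSA exceeds
#' `rsa_min`; *surface* when it is not interface and its RSA exceeds
#' `rsa_min`; *core* otherwise. Residues with zero subunit SASA cannot
#' satisfy the relative-drop rule and fall to core.
#'
#' @param partition a `qs_partition` from [partition_complex()].
#' @param sasa_complex `qs_sasa` of the assembled complex.
#' @param sasa_subunits list of `qs_sasa`, one per subunit (same residue
#'   keys as the complex).
#' @param delta_frac relative SASA-drop threshold (default 0.10; strict `>`).
#' @param rsa_min RSA threshold (default 0.20; strict `>`).
#' @param reference_areas RSA reference areas; defaults to Miller values.
#' @param hydrophobic_subunit which subunit's residues feed the hydrophobicity
#'   (and downstream conservation) summaries; default the first.
#' @return a `qs_interface_profile`: `region_of` (named character vector over
#'   residue keys), `rsa`, `interface_area`, `relative_buried`,
#'   `hydrophobic_fraction_interface`, `hydrophobic_fraction_surface`,
#'   `n_subunits`.
#' @export
call_regions <- function(partition, sasa_complex, sasa_subunits,
                         delta_frac = 0.10, rsa_min = 0.20,
                         reference_areas = miller_reference_areas(),
                         hydrophobic_subunit = 1L) {
  stopifnot(inherits(partition, "qs_partition"))
  sub_res <- unlist(lapply(sasa_subunits, function(s) s$per_residue))
  names(sub_res) <- unlist(lapply(sasa_subunits, function(s) names(s$per_residue)))
  cmx_res <- sasa_complex$per_residue
  if (!setequal(names(cmx_res), names(sub_res)))
    stop("complex and subunit SASA cover different residue sets")
  keys <- names(cmx_res)
  s_sub <- sub_res[keys]
  s_cmx <- cmx_res[keys]

  resnames <- assembly_resnames(partition$complex)
  ref <- reference_areas[resnames[keys]]
  if (any(is.na(ref)))
    stop("residue names missing from reference table: ",
         paste(unique(resnames[keys][is.na(ref)]), collapse = ", "))
  rsa <- as.numeric(s_sub / ref)
  names(rsa) <- keys

  is_iface <- (s_sub - s_cmx) > delta_frac * s_sub & rsa > rsa_min & s_sub > 0
  is_surf <- !is_iface & rsa > rsa_min
  region <- ifelse(is_iface, "interface", ifelse(is_surf, "surface", "core"))
  names(region) <- keys

  n_sub <- length(partition$subunits)
  tot_sub <- sum(vapply(sasa_subunits, function(s) s$total, numeric(1)))
  area <- interface_area(tot_sub, sasa_complex$total, n_sub)
  rel_buried <- if (n_sub == 1) 0 else relative_buried_surface(tot_sub, sasa_complex$total)

  first_chain <- partition$complex$chains[hydrophobic_subunit]
  on_first <- startsWith(keys, paste0(first_chain, "|"))
  hyd <- function(sel) {
    k <- keys[sel & on_first]
    if (!length(k)) return(NA_real_)
    hydrophobic_fraction(unname(resnames[k]))
  }
  structure(list(
    region_of = region, rsa = rsa,
    interface_area = area, relative_buried = rel_buried,
    hydrophobic_fraction_interface = hyd(region == "interface"),
    hydrophobic_fraction_surface = hyd(region == "surface"),
    n_subunits = n_sub), class = "qs_interface_profile")
}

#' Full interface profile of an assembly
#'
#' Convenience wrapper: partitions the assembly, computes complex and
#' subunit SASAs, and calls regions.
#'
#' @param assembly a `qs_assembly`.
#' @param probe_radius,n_points passed to [shrake_rupley()].
#' @param ... passed to [call_regions()].
#' @return a `qs_interface_profile`.
#' @export
interface_profile <- function(assembly, probe_radius = 1.4, n_points = 960, ...) {
  part <- partition_complex(assembly)
  sc <- shrake_rupley(assembly, probe_radius, n_points)
  ss <- lapply(part$subunits, shrake_rupley, probe_radius = probe_radius,
               n_points = n_points)
  call_regions(part, sc, ss, ...)
}

#' @export
print.qs_interface_profile <- function(x, ...) {
  tab <- table(x$region_of)
  cat("qs_interface_profile:", x$n_subunits, "subunit(s);",
      "interface area", round(x$interface_area, 1), "A^2;",
      "relative buried", round(x$relative_buried, 3), "\n")
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Residue keys of the interface of one subunit
#'
#' @param profile a `qs_interface_profile`.
#' @param chain chain id; `NULL` returns interface residues of all chains.
#' @return character vector of residue keys.
#' @export
interface_residues <- function(profile, chain = NULL) {
  k <- names(profile$region_of)[profile$region_of == "interface"]
  if (!is.null(chain)) k <- k[startsWith(k, paste0(chain, "|"))]
  k
}

#' Write a per-residue interface/SASA profile as TSV
#'
#' One row per residue: chain, resnum, icode, resname, region, sasa in the
#' complex, sasa in the isolated subunit, subunit RSA.
#'
#' @param profile a `qs_interface_profile`.
#' @param sasa_complex,sasa_subunits the SASA objects used to build it.
#' @param assembly the `qs_assembly`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_profile_tsv <- function(profile, sasa_complex, sasa_subunits, assembly, path) {
  keys <- names(profile$region_of)
  parts <- t(vapply(strsplit(keys, "|", fixed = TRUE),
                    function(p) c(p, "", "")[1:3], character(3)))
  sub_res <- unlist(lapply(sasa_subunits, function(s) s$per_residue))
  names(sub_res) <- unlist(lapply(sasa_subunits, function(s) names(s$per_residue)))
  resnames <- assembly_resnames(assembly)
  df <- data.frame(chain = parts[, 1], resnum = parts[, 2],
                   icode = parts[, 3],
                   resname = unname(resnames[keys]),
                   region = unname(profile$region_of),
                   sasa_complex = unname(sasa_complex$per_residue[keys]),
                   sasa_subunit = unname(sub_res[keys]),
                   rsa_subunit = unname(profile$rsa[keys]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
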