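#' Van der Waals radius table for SASA calculations
#'
#' Element-keyed van der Waals radii in Angstrom, NACCESS/Chothia-style
#' (C 1.87, N 1.65, O 1.40, S 1.85). Hydrogens are rarely present in
#' crystallographic models; when they are, they get 1.20 A. Elements not
#' listed fall back to `default`.
#'
#' @param default radius in Angstrom assigned to elements not in the table.
#' @return named numeric vector of radii, with a `"*"` entry for the fallback.
#' @export
default_radius_table <- function(default = 1.80) {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, H = 1.20, P = 1.80,
    SE = 1.90, "*" = default)
}

#' Look up van der Waals radii for element symbols
#'
#' @param elements character vector of element symbols.
#' @param table named radius vector as from [default_radius_table()].
#' @return numeric vector of radii in Angstrom.
#' @export
element_radii <- function(elements, table = default_radius_table()) {
  el <- toupper(trimws(elements))
  r <- unname(table[el])
  r[is.na(r)] <- unname(table["*"])
  r
}

.qsevo_extdata <- function(file) {
  path <- system.file("extdata", file, package = "qsevo")
  if (!nzchar(path)) stop("fixture not found: ", file)
  path
}

#' Miller reference areas for relative solvent accessibility
#'
#' Maximal per-residue solvent-accessible areas (Gly-X-Gly standard state)
#' used as RSA denominators.
#'
#' @return named numeric vector (A^2), keyed by both 3-letter and 1-letter
#'   residue codes.
#' @export
miller_reference_areas <- function() {
  tab <- utils::read.csv(.qsevo_extdata("miller_areas.csv"), comment.char = "#")
  stats::setNames(c(tab$area, tab$area), c(tab$resname, tab$aa))
}

#' Average residue masses
#'
#' Water-subtracted average masses of the 20 standard amino-acid residues.
#'
#' @return named numeric vector (Daltons), keyed by 1-letter code.
#' @export
residue_masses <- function() {
  tab <- utils::read.csv(.qsevo_extdata("residue_masses.csv"), comment.char = "#")
  stats::setNames(tab$mass, tab$aa)
}

#' Amino-acid synthesis cost table
#'
#' Per-residue synthesis costs in high-energy phosphate bonds (Akashi-Gojobori
#' E. coli values). The cheap (Ala/Gly/Ser = 11) and expensive (Trp = 74)
#' anchors are asserted at load time; a corrupted table fails loudly.
#'
#' @param path optional path to an alternative cost CSV with columns
#'   `aa,pbonds`.
#' @return named numeric vector of costs keyed by 1-letter code.
#' @export
load_cost_table <- function(path = NULL) {
  if (is.null(path)) path <- .qsevo_extdata("akashi_gojobori_costs.csv")
  tab <- utils::read.csv(path, comment.char = "#")
  costs <- stats::setNames(as.numeric(tab$pbonds), tab$aa)
  if (length(costs) != 20L || any(is.na(costs)) || any(costs <= 0))
    stop("cost table must list 20 standard residues with positive costs")
  anchors <- c(A = 11, G = 11, S = 11, W = 74)
  if (!isTRUE(all.equal(costs[names(anchors)], anchors, check.attributes = FALSE)))
    stop("cost table anchors violated: expected Ala/Gly/Ser = 11 and Trp = 74 P-bonds")
  costs
}
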