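#' Conservation differential between interface and surface
#'
#' Difference of mean normalised conservation scores (interface minus
#' surface) plus a two-sided Wilcoxon rank-sum test. With ConSurf-style
#' scores, lower = more conserved, so a *negative* difference means a more
#' conserved interface; the flag fires when the interface is more conserved
#' in that direction and the test is significant.
#'
#' @param iface_scores,surf_scores numeric score vectors (>= 3 each).
#' @param alpha significance level for the flag (default 0.05).
#' @param lower_is_conserved score convention; set `FALSE` when higher
#'   scores mean more conserved.
#' @return list with `mean_difference` (interface - surface), `p_value`,
#'   `significantly_more_conserved`.
#' @export
conservation_differential <- function(iface_scores, surf_scores, alpha = 0.05,
                                      lower_is_conserved = TRUE) {
  if (length(iface_scores) < 3 || length(surf_scores) < 3)
    stop("insufficient data: need >= 3 residues in each region")
  diff <- mean(iface_scores) - mean(surf_scores)
  # ties make the exact rank-sum distribution unavailable; the normal
  # approximation wilcox.test falls back to is fine at these sizes
  p <- suppressWarnings(
    stats::wilcox.test(iface_scores, surf_scores,
                       alternative = "two.sided")$p.value)
  conserved_dir <- if (lower_is_conserved) diff < 0 else diff > 0
  list(mean_difference = diff, p_value = p,
       significantly_more_conserved = conserved_dir && p < alpha)
}

#' Mean synthesis cost of a residue region
#'
#' Arithmetic mean of per-residue synthesis costs (high-energy phosphate
#' bonds) over a region.
#'
#' @param residues character vector of 1-letter residue codes.
#' @param table cost table from [load_cost_table()].
#' @return mean P-bonds per residue.
#' @export
region_cost <- function(residues, table = load_cost_table()) {
  if (!length(residues)) stop("empty region: cost undefined")
  costs <- table[residues]
  if (any(is.na(costs)))
    stop("unknown residue letter(s): ",
         paste(unique(residues[is.na(costs)]), collapse = ", "))
  mean(costs)
}

#' Subunit-scaled protein abundance
#'
#' Divides a protein's abundance (ppm) by its complex's subunit count, so
#' homomers are compared at the level of assembled particles. A predicted
#' homomer with unknown subunit count is assumed to be a dimer when
#' `assume_dimer` is set.
#'
#' @param abundance abundance in ppm (>= 0).
#' @param n_subunits subunit count, or `NA` when unknown.
#' @param is_homomer is the protein a (predicted) homomer? Only consulted
#'   when `n_subunits` is missing.
#' @param assume_dimer apply the assumed-dimer rule for homomers with
#'   missing counts (default `TRUE`).
#' @return data.frame with `abundance`, `n_subunits`, `scaled_abundance`
#'   (an `AbundanceRecord`; vectorized over its inputs).
#' @export
scaled_abundance <- function(abundance, n_subunits, is_homomer = NA,
                             assume_dimer = TRUE) {
  stopifnot(all(abundance >= 0))
  n <- as.integer(n_subunits)
  if (length(is_homomer) == 1) is_homomer <- rep(is_homomer, length(n))
  fill <- is.na(n) & assume_dimer & !is.na(is_homomer)
  n[fill] <- ifelse(is_homomer[fill], 2L, 1L)
  if (any(!is.na(n) & n < 1)) stop("n_subunits must be >= 1")
  data.frame(abundance = abundance, n_subunits = n,
             scaled_abundance = abundance / n)
}

#' Read a ConSurf-style conservation table
#'
#' TSV with columns `chain`, `resnum`, `icode`, `score` (normalised
#' conservation; lower = more conserved by the ConSurf convention).
#'
#' @param path TSV path.
#' @return named numeric vector keyed by residue key.
#' @export
read_conservation_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(icode = "character"))
  setNames(tab$score, residue_key(tab$chain, tab$resnum, tab$icode))
}

#' Write a conservation table as TSV
#'
#' @param scores named numeric vector keyed by residue key.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(scores, path) {
  parts <- t(vapply(strsplit(names(scores), "|", fixed = TRUE),
                    function(p) c(p, "", "")[1:3], character(3)))
  utils::write.table(
    data.frame(chain = parts[, 1], resnum = parts[, 2], icode = parts[, 3],
               score = as.numeric(scores)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
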