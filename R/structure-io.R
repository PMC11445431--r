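#' @importFrom stats setNames
NULL

# Residue identity used throughout: author chain id + author residue number +
# insertion code, composed into a single string key.
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

#' Construct an assembly model from an atom table
#'
#' Low-level constructor shared by the file readers and the synthetic
#' generators. `atoms` must have columns `chain`, `resno`, `icode`,
#' `resname`, `element`, `x`, `y`, `z`, `radius` and optionally `is_hetero`.
#'
#' @param atoms atom data.frame (see Details).
#' @param sequences optional named character vector of 1-letter sequences per
#'   chain; derived from `resname` when `NULL`.
#' @param identity_min minimum pairwise sequence identity for chains to count
#'   as copies of the same subunit.
#' @return an object of class `qs_assembly` with elements `atoms`, `chains`,
#'   `sequences` and `n_subunits`.
#' @export
make_assembly <- function(atoms, sequences = NULL, identity_min = 0.95) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("chain", "resno", "icode", "resname", "element", "x", "y", "z", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  if (is.null(atoms$is_hetero)) atoms$is_hetero <- FALSE
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  chains <- unique(atoms$chain)
  if (is.null(sequences)) {
    sequences <- vapply(chains, function(ch) {
      a <- atoms[atoms$chain == ch & !atoms$is_hetero, ]
      res <- a[!duplicated(a$key), ]
      paste(suppressWarnings(bio3d::aa321(res$resname)), collapse = "")
    }, character(1))
    names(sequences) <- chains
  }
  structure(
    list(atoms = atoms, chains = chains, sequences = sequences,
         n_subunits = count_identical_chains(sequences, identity_min)),
    class = "qs_assembly")
}

count_identical_chains <- function(sequences, identity_min = 0.95) {
  if (length(sequences) <= 1L) return(1L)
  ref <- sequences[[1]]
  same <- vapply(sequences, function(s) {
    if (identical(s, ref)) return(TRUE)
    if (nchar(s) < 1 || nchar(ref) < 1) return(FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ref), Biostrings::AAString(s),
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    Biostrings::pid(aln) / 100 >= identity_min
  }, logical(1))
  sum(same)
}

#' @export
print.qs_assembly <- function(x, ...) {
  cat("qs_assembly:", nrow(x$atoms), "atoms,", length(x$chains), "chain(s) [",
      paste(x$chains, collapse = ","), "],", x$n_subunits,
      "identical subunit(s)\n")
  invisible(x)
}

#' Read a structure file into an assembly model
#'
#' Parses a PDB or mmCIF file (via bio3d), keeps the first model and the
#' highest-occupancy alternate conformer, assigns element-derived van der
#' Waals radii, and (by default) drops waters and hetero atoms. Deposited
#' coordinates are taken as the biological assembly; symmetry expansion is
#' the caller's responsibility.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"pdb"` or `"mmcif"`.
#' @param exclude_waters drop water records.
#' @param include_ligands keep non-water HETATM records.
#' @param radius_table named radius vector, see [default_radius_table()].
#' @param identity_min sequence identity threshold for counting subunit copies.
#' @return a `qs_assembly`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           exclude_waters = TRUE, include_ligands = FALSE,
                           radius_table = default_radius_table(),
                           identity_min = 0.95) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE)
    else suppressWarnings(bio3d::read.cif(path)),  # bio3d's beta notice is noise here
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  # altloc: keep highest-occupancy conformer per (chain, residue, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(at$chain, at$resno, at$insert, at$elety, -occ)
    at <- at[ord, ]
    k <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    at <- at[!duplicated(k), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  water <- at$resid %in% c("HOH", "WAT", "DOD", "H2O")
  het <- at$type == "HETATM" & !water
  keep <- rep(TRUE, nrow(at))
  if (exclude_waters) keep <- keep & !water
  if (!include_ligands) keep <- keep & !het
  at <- at[keep, ]
  if (nrow(at) == 0) stop("empty structure: no atoms left after filtering in ", path)
  element <- at$elesy
  bad <- is.na(element) | element == ""
  element[bad] <- substr(gsub("[^A-Za-z]", "", at$elety[bad]), 1, 1)
  atoms <- data.frame(
    chain = at$chain, resno = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == " ", "", at$insert),
    resname = at$resid, elety = at$elety, element = element,
    x = at$x, y = at$y, z = at$z,
    radius = element_radii(element, radius_table),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  make_assembly(atoms, identity_min = identity_min)
}

#' Split an assembly into its single-chain subunits
#'
#' Coordinates are unchanged: each subunit is the complex's atoms of one
#' chain, in chain order, so complex-vs-subunit SASA differences isolate the
#' burial caused by assembly.
#'
#' @param assembly a `qs_assembly`.
#' @return a `qs_partition`: list with `complex` and `subunits` (one
#'   `qs_assembly` per chain).
#' @export
partition_complex <- function(assembly) {
  stopifnot(inherits(assembly, "qs_assembly"))
  subunits <- lapply(assembly$chains, function(ch) {
    a <- assembly$atoms[assembly$atoms$chain == ch, , drop = FALSE]
    make_assembly(a, sequences = assembly$sequences[ch])
  })
  names(subunits) <- assembly$chains
  structure(list(complex = assembly, subunits = subunits), class = "qs_partition")
}

#' Write an assembly to a PDB file
#'
#' Convenience writer (via bio3d) used mainly to emit synthetic complexes in
#' the same format the production reader consumes.
#'
#' @param assembly a `qs_assembly`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assembly_pdb <- function(assembly, path) {
  a <- assembly$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$elety, o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
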