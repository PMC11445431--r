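# helper: a fake dimer partition with prescribed per-residue SASA values,
# so the threshold logic can be exercised at exact values
fake_case <- function(s_sub, s_cmx, ref_area) {
  atoms <- data.frame(chain = "A", resno = seq_along(s_sub), icode = "",
                      resname = "ALA", elety = "CA", element = "C",
                      x = seq_along(s_sub) * 10, y = 0, z = 0, radius = 1.9)
  part <- partition_complex(make_assembly(atoms))
  keys <- residue_key("A", seq_along(s_sub), "")
  mk <- function(v) structure(list(per_residue = stats::setNames(v, keys),
                                   per_atom = v, total = sum(v)),
                              class = "qs_sasa")
  call_regions(part, mk(s_cmx), list(A = mk(s_sub)),
               reference_areas = c(ALA = ref_area))
}

test_that("region calling follows the 10% SASA-drop and 20% RSA thresholds", {
  # RSA = s_sub / 200 here
  prof <- fake_case(s_sub = c(100, 100, 10), s_cmx = c(80, 96, 2),
                    ref_area = 200)
  expect_equal(unname(prof$region_of),
               c("interface",  # drop 20 > 10, RSA 0.5
                 "surface",    # drop 4 <= 10, RSA 0.5
                 "core"))      # RSA 0.05 <= 0.2
  # boundary: drop exactly 10% is NOT interface; RSA exactly 0.2 is core
  prof2 <- fake_case(s_sub = c(100, 40), s_cmx = c(90, 40), ref_area = 200)
  expect_equal(unname(prof2$region_of), c("surface", "core"))
  # zero subunit SASA cannot be interface
  prof3 <- fake_case(s_sub = c(0, 100), s_cmx = c(0, 50), ref_area = 200)
  expect_equal(unname(prof3$region_of)[1], "core")
})

test_that("interface area follows the per-subunit SASA-difference formula", {
  expect_equal(interface_area(10000, 10000, 1), 0)
  expect_equal(interface_area(10000, 9000, 2), 500)
  expect_equal(interface_area(10000, 10000 + 1e-9, 2), 0)  # clipped
  expect_error(interface_area(9000, 10000, 2), "exceeds")
})

test_that("complex interface area matches brute-force per-atom accounting", {
  toy <- gen_cn_complex(3, n_residues = 20, seed = 21)
  part <- partition_complex(toy$assembly)
  sc <- shrake_rupley(toy$assembly, n_points = 480)
  ss <- lapply(part$subunits, shrake_rupley, n_points = 480)
  # oracle: per-atom SASA losses summed over all atoms, divided by n
  per_atom_sub <- unlist(lapply(ss, function(s) s$per_atom))
  oracle <- sum(per_atom_sub - sc$per_atom) / 3
  got <- interface_area(sum(vapply(ss, function(s) s$total, numeric(1))),
                        sc$total, 3)
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_gt(got, 0)
})

test_that("relative buried surface is the buried fraction of subunit SASA", {
  expect_equal(relative_buried_surface(10000, 9000), 0.10)
  expect_equal(relative_buried_surface(10000, 10000), 0)
  expect_warning(v <- relative_buried_surface(10000, 0), "degenerate")
  expect_equal(v, 1)
  expect_error(relative_buried_surface(0, 0), "positive")
})

test_that("hydrophobic fraction counts the CFILMVW residues", {
  expect_equal(hydrophobic_fraction(c("C", "A", "T")), 1 / 3)
  expect_equal(hydrophobic_fraction(rep("W", 5)), 1)
  expect_equal(hydrophobic_fraction(c("S", "T", "N", "Q")), 0)
  expect_equal(hydrophobic_fraction(c("TRP", "SER")), 0.5)  # 3-letter input
  expect_error(hydrophobic_fraction(character(0)), "empty region")
})

test_that("molecular weight sums residue masses times subunit count", {
  expect_equal(molecular_weight("G", 1), 57.05)
  seqs <- "GASPVWLK"
  expect_equal(molecular_weight(seqs, 2), 2 * molecular_weight(seqs, 1))
  expect_equal(molecular_weight("AGW", 1, exclude_ranges = list(c(1, 2))),
               186.21)
  expect_error(molecular_weight("AG", 1, exclude_ranges = list(c(1, 2))),
               "empty sequence")
  expect_error(molecular_weight("AZ", 1), "unknown residue")
})

test_that("monomers have zero interface area and empty interface region", {
  toy <- gen_cn_complex(1, n_residues = 20, seed = 13)
  prof <- interface_profile(toy$assembly, n_points = 480,
                            reference_areas = toy_reference_areas())
  expect_identical(prof$interface_area, 0)
  expect_identical(prof$relative_buried, 0)
  expect_false(any(prof$region_of == "interface"))
})

test_that("ground-truth buried residues with RSA > 0.2 are called interface", {
  hits <- 0; total <- 0
  for (seed in 1:8) {
    toy <- gen_cn_complex(2, n_residues = 35, seed = seed)
    prof <- interface_profile(toy$assembly, n_points = 480,
                              reference_areas = toy_reference_areas())
    truth <- toy$buried_truth[prof$rsa[toy$buried_truth] > 0.2]
    hits <- hits + sum(prof$region_of[truth] == "interface")
    total <- total + length(truth)
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.9)
})

test_that("region calls are invariant under rigid motion and chain relabeling", {
  toy <- gen_cn_complex(2, n_residues = 20, seed = 17)
  prof1 <- interface_profile(toy$assembly, n_points = 480,
                             reference_areas = toy_reference_areas())
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- toy$assembly
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% R
  moved$atoms$x <- xyz[, 1] - 3; moved$atoms$y <- xyz[, 2] + 7
  moved$atoms$z <- xyz[, 3]
  # relabel chains A,B -> X,Y (atom order unchanged)
  moved$atoms$chain <- c(X = "X", Y = "Y")[match(moved$atoms$chain, c("A", "B"))]
  moved <- make_assembly(moved$atoms[, setdiff(names(moved$atoms), "key")])
  prof2 <- interface_profile(moved, n_points = 480,
                             reference_areas = toy_reference_areas())
  expect_equal(unname(prof2$region_of), unname(prof1$region_of))
  # the interface area is a small difference of large totals, so quadrature
  # noise is amplified relative to the totals themselves
  expect_equal(prof2$interface_area, prof1$interface_area, tolerance = 0.1)
})
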