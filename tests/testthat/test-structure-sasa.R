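test_that("read_structure parses hand-written PDB records", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), path)
  asm <- read_structure(path)
  expect_s3_class(asm, "qs_assembly")
  expect_equal(nrow(asm$atoms), 2)
  expect_equal(asm$chains, "A")
  expect_equal(asm$atoms$element, c("N", "C"))
  expect_equal(asm$atoms$radius, c(1.65, 1.87))
})

test_that("generated C2 dimer round-trips through the PDB reader", {
  toy <- gen_cn_complex(2, n_residues = 25, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_assembly_pdb(toy$assembly, path)
  asm <- read_structure(path)
  expect_equal(length(asm$chains), 2)
  expect_identical(asm$sequences[[1]], asm$sequences[[2]])
  expect_identical(asm$sequences[[1]], toy$assembly$sequences[[1]])
  expect_equal(asm$n_subunits, 2)
  expect_lt(max(abs(asm$atoms$x - toy$assembly$atoms$x)), 1e-2)
})

test_that("mmCIF atom_site records parse to the same model", {
  path <- withr::local_tempfile(fileext = ".cif")
  hdr <- c("data_toy", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- c(
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . GLY A 1 2 ? 10.560 5.500 -4.200 1.00 0.00 ? 2 GLY A C 1")
  writeLines(c(hdr, rows), path)
  asm <- read_structure(path, format = "mmcif")
  expect_equal(nrow(asm$atoms), 3)
  expect_equal(asm$atoms$resname, c("ALA", "ALA", "GLY"))
  expect_equal(asm$atoms$radius, c(1.65, 1.87, 1.87))
  expect_equal(asm$sequences[["A"]], "AG")
})

test_that("water-only files give an empty-structure error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
    "END"), path)
  expect_error(read_structure(path, exclude_waters = TRUE), "empty structure")
})

test_that("partition_complex splits chains in order without touching coordinates", {
  mono <- gen_cn_complex(1, n_residues = 20, seed = 3)
  p1 <- partition_complex(mono$assembly)
  expect_length(p1$subunits, 1)
  expect_identical(p1$subunits[[1]]$atoms$x, mono$assembly$atoms$x)

  tri <- gen_cn_complex(3, n_residues = 20, seed = 5)
  p3 <- partition_complex(tri$assembly)
  expect_identical(names(p3$subunits), c("A", "B", "C"))
  expect_equal(vapply(p3$subunits, function(s) nrow(s$atoms), numeric(1)),
               c(A = 20, B = 20, C = 20))
  expect_equal(sum(vapply(p3$subunits, function(s) nrow(s$atoms), numeric(1))),
               nrow(tri$assembly$atoms))
})

one_atom <- function(r = 1.9) data.frame(
  chain = "A", resno = 1, icode = "", resname = "ALA", elety = "CA",
  element = "C", x = 0, y = 0, z = 0, radius = r)

test_that("single-sphere SASA matches the analytic area", {
  s <- shrake_rupley(one_atom(), probe_radius = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.3^2, tolerance = 0.01)
  # doubling the quadrature changes the area by < 1%
  s2 <- shrake_rupley(one_atom(), probe_radius = 1.4, n_points = 1920)
  expect_lt(abs(s2$total - s$total) / s$total, 0.01)
})

test_that("well-separated atoms have exactly additive SASA", {
  a <- rbind(one_atom(), one_atom())
  a$resno <- 1:2
  a$x <- c(0, 2 * (1.9 + 1.4) + 0.5)
  s <- shrake_rupley(a)
  expect_equal(s$total, 2 * 4 * pi * 3.3^2, tolerance = 1e-9)
})

test_that("occlusion is monotone as a second atom approaches", {
  areas <- vapply(seq(7, 3, by = -0.5), function(d) {
    a <- rbind(one_atom(), one_atom())
    a$resno <- 1:2
    a$x <- c(0, d)
    shrake_rupley(a)$per_atom[1]
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("an atom enclosed by a tight shell is fully buried", {
  shell <- sphere_points(60) * 3.0
  a <- rbind(one_atom(),
             data.frame(chain = "A", resno = 2:61, icode = "", resname = "ALA",
                        elety = "CA", element = "C",
                        x = shell[, 1], y = shell[, 2], z = shell[, 3],
                        radius = 1.9))
  s <- shrake_rupley(a)
  expect_lt(s$per_atom[1], 1)
})

test_that("coincident atom centres warn and are handled deterministically", {
  a <- rbind(one_atom(), one_atom())
  a$resno <- 1:2
  expect_warning(s <- shrake_rupley(a), "coincident")
  expect_equal(s$per_atom[1], s$per_atom[2])
})

test_that("SASA is invariant under rigid-body motion and sums to total", {
  toy <- gen_cn_complex(2, n_residues = 22, seed = 9)
  s1 <- shrake_rupley(toy$assembly)
  expect_equal(sum(s1$per_residue), s1$total, tolerance = 1e-6)
  expect_equal(sum(s1$per_atom), s1$total, tolerance = 1e-12)

  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- toy$assembly
  xyz <- as.matrix(rot$atoms[, c("x", "y", "z")]) %*% R
  rot$atoms$x <- xyz[, 1] + 5; rot$atoms$y <- xyz[, 2] - 2; rot$atoms$z <- xyz[, 3] + 1
  s2 <- shrake_rupley(rot)
  expect_lt(abs(s2$total - s1$total) / s1$total, 0.005)
})

test_that("relative accessibility divides by the reference area", {
  sasa <- structure(list(per_residue = c("A|1|" = 40.2, "A|2|" = 0, "A|3|" = 113),
                         per_atom = NULL, total = 153.2), class = "qs_sasa")
  rn <- c("A|1|" = "GLY", "A|2|" = "ALA", "A|3|" = "ALA")
  rsa <- relative_accessibility(sasa, rn)
  expect_equal(unname(rsa["A|1|"]), 40.2 / 85)
  expect_equal(unname(rsa["A|2|"]), 0)
  expect_equal(unname(rsa["A|3|"]), 1.0)

  rn2 <- c("A|1|" = "XYZ", "A|2|" = "ALA", "A|3|" = "ALA")
  expect_error(relative_accessibility(sasa, rn2), "missing from reference")
  rsa2 <- relative_accessibility(sasa, rn2, fallback = 100)
  expect_equal(unname(rsa2["A|1|"]), 0.402)
})
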