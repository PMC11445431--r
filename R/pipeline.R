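#' Filter a dataset of protein records
#'
#' Keeps records with resolution strictly better than `max_resolution`
#' ("better than 3 A"), UniProt coverage and mature-sequence length at least
#' their minima, and a monomer or homomer quaternary-structure label.
#' Records failing several rules are counted under the first failing rule,
#' in the order incomplete, resolution, coverage, length, qs_label.
#'
#' @param records data.frame with columns `protein_id`, `resolution`,
#'   `uniprot_coverage`, `length`, `qs_label`.
#' @param max_resolution resolution cutoff in Angstrom (strict `<`).
#' @param min_coverage minimum UniProt coverage (inclusive).
#' @param min_length minimum residue count (inclusive; signal/transit
#'   peptides are assumed already excluded from `length`).
#' @return list with `kept` (filtered data.frame) and `drops` (named integer
#'   vector of per-rule drop counts).
#' @export
filter_dataset <- function(records, max_resolution = 3.0, min_coverage = 0.80,
                           min_length = 100) {
  need <- c("protein_id", "resolution", "uniprot_coverage", "length", "qs_label")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  incomplete <- is.na(records$resolution) | is.na(records$uniprot_coverage) |
    is.na(records$length) | is.na(records$qs_label)
  reason[incomplete] <- "incomplete"
  f <- function(cond, tag) {
    hit <- is.na(reason) & !incomplete & cond
    reason[hit] <<- tag
  }
  f(records$resolution >= max_resolution, "resolution")
  f(records$uniprot_coverage < min_coverage, "coverage")
  f(records$length < min_length, "length")
  f(!records$qs_label %in% c("monomer", "homomer"), "qs_label")
  drops <- table(factor(reason, levels = c("incomplete", "resolution",
                                           "coverage", "length", "qs_label")))
  list(kept = records[is.na(reason), , drop = FALSE],
       drops = setNames(as.integer(drops), names(drops)))
}

#' Pipeline configuration
#'
#' Collects the thresholds and paths of a full run; all defaults are the
#' analysis-wide conventions (10% SASA drop / 20% RSA for region calling,
#' 1000 A^2 quaternary-structure error filter, 50% interface overlap for
#' homology groups, 51% root confidence).
#'
#' @param input_dir directory with `dataset.tsv`, `structures/`, `trees/`.
#' @param output_dir directory for stage outputs.
#' @param delta_frac,rsa_min region-calling thresholds.
#' @param min_interface_area homomer-reclassification threshold (A^2).
#' @param overlap_threshold interface-homology edge threshold.
#' @param root_confidence root-filter probability.
#' @param max_resolution,min_coverage,min_length dataset filters.
#' @param n_points SASA quadrature points.
#' @param reference_areas RSA reference table (named vector).
#' @param seed integer seed for any stochastic stage.
#' @param force rerun stages whose outputs already exist.
#' @return a validated `qs_config` list.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            delta_frac = 0.10, rsa_min = 0.20,
                            min_interface_area = 1000,
                            overlap_threshold = 0.5,
                            root_confidence = 0.51,
                            max_resolution = 3.0, min_coverage = 0.80,
                            min_length = 100, n_points = 960,
                            reference_areas = miller_reference_areas(),
                            seed = 1L, force = FALSE) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              delta_frac = delta_frac, rsa_min = rsa_min,
              min_interface_area = min_interface_area,
              overlap_threshold = overlap_threshold,
              root_confidence = root_confidence,
              max_resolution = max_resolution, min_coverage = min_coverage,
              min_length = min_length, n_points = n_points,
              reference_areas = reference_areas, seed = as.integer(seed),
              force = isTRUE(force))
  in01 <- c("delta_frac", "rsa_min", "overlap_threshold", "root_confidence",
            "min_coverage")
  for (nm in in01)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("config value out of range [0, 1]: ", nm)
  if (cfg$min_interface_area < 0 || cfg$max_resolution <= 0 ||
      cfg$min_length < 0 || cfg$n_points < 100)
    stop("config value out of valid range")
  class(cfg) <- "qs_config"
  cfg
}

#' Run the full quaternary-structure evolution pipeline
#'
#' Stages: dataset filter, per-protein interface profiles, pairwise
#' superposition/overlap and multi-state assignment within each orthogroup,
#' ancestral reconstruction (ER maximum likelihood), ratchet statistics and
#' per-orthogroup report. Each stage writes a TSV under
#' `config$output_dir`; completed stages are skipped on rerun unless
#' `config$force`.
#'
#' The input directory must contain `dataset.tsv` (columns `protein_id`,
#' `orthogroup`, `resolution`, `uniprot_coverage`, `length`, `qs_label`,
#' `location`, `structure` — a path relative to the input dir) and
#' `trees/<orthogroup>.nwk`.
#'
#' @param config a `qs_config`.
#' @return invisibly, a list with the consolidated `report` data.frame and
#'   per-stage file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qs_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "pipeline_log.tsv")
  log_stage <- function(stage, detail) {
    utils::write.table(
      data.frame(stage = stage, detail = detail, seed = config$seed),
      log_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = !file.exists(log_path), append = file.exists(log_path))
  }
  stage_file <- function(name) file.path(config$output_dir, name)
  done <- function(name) !config$force && file.exists(stage_file(name))

  dataset <- utils::read.delim(file.path(config$input_dir, "dataset.tsv"))

  # stage 1: filter
  if (!done("filtered.tsv")) {
    flt <- filter_dataset(dataset, config$max_resolution, config$min_coverage,
                          config$min_length)
    utils::write.table(flt$kept, stage_file("filtered.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("filter", paste(names(flt$drops), flt$drops, sep = "=",
                              collapse = " "))
  }
  kept <- utils::read.delim(stage_file("filtered.tsv"))
  if (!nrow(kept)) stop("pipeline halt at stage 'filter': no records survive")

  # stage 2: interface profiles
  if (!done("interfaces.tsv")) {
    rows <- list(); profiles <- list()
    for (i in seq_len(nrow(kept))) {
      id <- kept$protein_id[i]
      path <- file.path(config$input_dir, kept$structure[i])
      asm <- tryCatch(read_structure(path),
                      error = function(e) stop("pipeline halt at stage 'interface', input ",
                                               id, ": ", conditionMessage(e)))
      prof <- interface_profile(asm, n_points = config$n_points,
                                delta_frac = config$delta_frac,
                                rsa_min = config$rsa_min,
                                reference_areas = config$reference_areas)
      rows[[id]] <- data.frame(
        protein_id = id, n_subunits = prof$n_subunits,
        interface_area = prof$interface_area,
        relative_buried = prof$relative_buried,
        n_interface = sum(prof$region_of == "interface"),
        interface_keys = paste(interface_residues(prof,
          asm$chains[1]), collapse = ","))
      profiles[[id]] <- prof
    }
    utils::write.table(do.call(rbind, rows), stage_file("interfaces.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("interface", paste(nrow(kept), "proteins"))
  }
  iface <- utils::read.delim(stage_file("interfaces.tsv"),
                             colClasses = c(interface_keys = "character"))

  # stage 3: states (overlap + homology groups + QS-error filter) per orthogroup
  if (!done("states.tsv")) {
    out <- list()
    for (og in unique(kept$orthogroup)) {
      sub <- kept[kept$orthogroup == og, ]
      info <- iface[match(sub$protein_id, iface$protein_id), ]
      homomer <- info$n_subunits > 1 & info$n_interface > 0
      groups <- NULL
      if (sum(homomer) >= 2) {
        ids <- sub$protein_id[homomer]
        structs <- lapply(ids, function(p) read_structure(
          file.path(config$input_dir, sub$structure[sub$protein_id == p])))
        names(structs) <- ids
        ifres <- lapply(ids, function(p)
          strsplit(info$interface_keys[info$protein_id == p], ",")[[1]])
        names(ifres) <- ids
        om <- overlap_matrix(structs, ifres)
        groups <- homology_groups(om, config$overlap_threshold)
      } else if (sum(homomer) == 1) {
        groups <- setNames(sub$protein_id[homomer], sub$protein_id[homomer])
      }
      counts <- setNames(info$n_subunits, sub$protein_id)
      states <- assign_states(counts, groups, mode = "multi")
      for (p in sub$protein_id) {
        st <- qs_error_filter(
          qs_state(counts[[p]],
                   if (!is.null(groups) && p %in% names(groups))
                     groups[[p]] else NA_character_),
          info$interface_area[info$protein_id == p],
          config$min_interface_area)
        states[p] <- st$id
      }
      out[[og]] <- data.frame(protein_id = sub$protein_id, orthogroup = og,
                              state = unname(states[sub$protein_id]))
    }
    utils::write.table(do.call(rbind, out), stage_file("states.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("states", paste(length(unique(kept$orthogroup)), "orthogroups"))
  }
  states <- utils::read.delim(stage_file("states.tsv"))

  # stage 4+5: ancestral reconstruction and report
  if (!done("report.tsv")) {
    reports <- list()
    for (og in unique(states$orthogroup)) {
      sub <- states[states$orthogroup == og, ]
      tree_path <- file.path(config$input_dir, "trees", paste0(og, ".nwk"))
      if (!file.exists(tree_path))
        stop("pipeline halt at stage 'ancestral', input ", og,
             ": tree file missing")
      tree <- ape::read.tree(tree_path)
      if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
      leaf_states <- setNames(as.character(sub$state), sub$protein_id)
      rec <- er_reconstruction(tree, leaf_states)
      marg <- rec$marginals
      er_rate <- rec$rate
      loc <- setNames(as.character(kept$location),
                      kept$protein_id)[tree$tip.label]
      names(loc) <- tree$tip.label
      areas <- setNames(iface$interface_area,
                        iface$protein_id)[tree$tip.label]
      names(areas) <- tree$tip.label
      rep_row <- orthogroup_report(tree, marg, leaf_states, loc, areas)
      rep_row$root_passed <- rep_row$root_prob >= config$root_confidence
      reports[[og]] <- cbind(data.frame(orthogroup = og, er_rate = er_rate),
                             rep_row)
    }
    utils::write.table(do.call(rbind, reports), stage_file("report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("report", paste(length(reports), "orthogroups"))
  }
  report <- utils::read.delim(stage_file("report.tsv"))
  invisible(list(report = report,
                 files = list(filtered = stage_file("filtered.tsv"),
                              interfaces = stage_file("interfaces.tsv"),
                              states = stage_file("states.tsv"),
                              report = stage_file("report.tsv"),
                              log = log_path)))
}

#' Generate a synthetic pipeline input bundle
#'
#' Emits everything [run_pipeline()] consumes, with known ground truth: toy
#' Cn complexes as PDB files, Yule trees as Newick, simulated
#' quaternary-structure histories as the dataset's subunit counts, and a
#' dataset table passing all filters.
#'
#' @param dir output directory (created).
#' @param n_orthogroups number of orthogroups.
#' @param leaves_per_group tips per orthogroup tree.
#' @param n_residues residues per toy chain.
#' @param seed integer seed.
#' @return `dir`, invisibly. Ground-truth histories are written to
#'   `truth_states.tsv` for reference.
#' @export
gen_pipeline_bundle <- function(dir, n_orthogroups = 3, leaves_per_group = 6,
                                n_residues = 30, seed = 1) {
  dir.create(file.path(dir, "structures"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE, recursive = TRUE)
  rows <- list(); truth <- list()
  Q <- ladder_generator(c(1, 2), gain_rate = 0.4, loss_rate = 0.15)
  for (g in seq_len(n_orthogroups)) {
    og <- sprintf("og%02d", g)
    tree <- gen_birth_tree(leaves_per_group, seed = seed * 1000 + g)
    hist <- sim_trait_history(tree, Q, root_state = "1",
                              seed = seed * 1000 + 500 + g)
    tree$tip.label <- sprintf("%s_p%02d", og, seq_len(leaves_per_group))
    names(hist$tip_states) <- tree$tip.label
    ape::write.tree(tree, file.path(dir, "trees", paste0(og, ".nwk")))
    for (i in seq_len(leaves_per_group)) {
      id <- tree$tip.label[i]
      n_sub <- as.integer(hist$tip_states[[id]])
      toy <- gen_cn_complex(n_sub, n_residues,
                            seed = seed * 10000 + g * 100 + i)
      write_assembly_pdb(toy$assembly,
                         file.path(dir, "structures", paste0(id, ".pdb")))
      rows[[id]] <- data.frame(
        protein_id = id, orthogroup = og,
        resolution = 1.5 + 0.01 * i, uniprot_coverage = 0.95,
        length = n_residues * 4,
        qs_label = if (n_sub > 1) "homomer" else "monomer",
        location = if (i %% 2 == 0) "extracellular" else "cytoplasmic",
        structure = file.path("structures", paste0(id, ".pdb")))
    }
    truth[[og]] <- data.frame(protein_id = tree$tip.label,
                              true_state = unname(hist$tip_states))
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "dataset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, truth), file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
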