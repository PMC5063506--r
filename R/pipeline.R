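#' Build a validated pipeline run configuration
#'
#' Collects input paths, the chain-role map and the distance/clustering
#' parameters for [run_pipeline()]. All referenced files must exist; the
#' labels table is required whenever the alignment is given. Defaults are
#' the canonical cutoffs: pocket 3.4, interface 4.0, contact 4.0, cluster
#' 2.0, box padding 6.0 Angstrom, 48 trajectories, 9 saved modes.
#'
#' @param alignment,labels Aligned FASTA and species-phenotype TSV paths.
#' @param structure Optional complex PDB path.
#' @param roles Named chain-role map for the structure.
#' @param ligand Ligand selection spec, e.g. `"L:201"`.
#' @param poses Optional scored pose file.
#' @param dose_response Optional dose-response CSV
#'   (`concentration,replicate,response`).
#' @param group_assay Optional cytokine replicate CSV (`group,value`).
#' @param reference Reference species for residue numbering.
#' @param pocket_cutoff,interface_cutoff,contact_cutoff,cluster_rmsd,box_padding
#'   Distance parameters in Angstrom.
#' @param exhaustiveness,num_modes Docking engine parameters echoed into the
#'   emitted config.
#' @param level Confidence level for percent-difference CIs.
#' @param seed Integer seed used for every stochastic step.
#' @param out_dir Optional output directory for the JSON report.
#' @return List of class `run_config`.
#' @export
run_config <- function(alignment = NULL, labels = NULL, structure = NULL,
                       roles = c(A = "receptor-A", C = "accessory-C",
                                 B = "partner-B"),
                       ligand = "L:201", poses = NULL, dose_response = NULL,
                       group_assay = NULL, reference = NULL,
                       pocket_cutoff = 3.4, interface_cutoff = 4.0,
                       contact_cutoff = 4.0, cluster_rmsd = 2.0,
                       box_padding = 6.0, exhaustiveness = 48, num_modes = 9,
                       level = 0.90, seed = 1, out_dir = NULL) {
  cfg <- list(alignment = alignment, labels = labels, structure = structure,
              roles = roles, ligand = ligand, poses = poses,
              dose_response = dose_response, group_assay = group_assay,
              reference = reference, pocket_cutoff = pocket_cutoff,
              interface_cutoff = interface_cutoff,
              contact_cutoff = contact_cutoff, cluster_rmsd = cluster_rmsd,
              box_padding = box_padding, exhaustiveness = exhaustiveness,
              num_modes = num_modes, level = level, seed = seed,
              out_dir = out_dir)
  for (p in c("pocket_cutoff", "interface_cutoff", "contact_cutoff",
              "cluster_rmsd", "box_padding")) {
    if (cfg[[p]] <= 0) stop_input(p, " must be positive")
  }
  if (!is.null(alignment) && is.null(labels)) {
    stop_input("a labels file is required with the alignment")
  }
  for (p in c("alignment", "labels", "structure", "poses", "dose_response",
              "group_assay")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop_input("configured ", p, " file not found: ", cfg[[p]])
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `roles` is a mapping of
#' chain id to role. Relative paths are resolved against the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  for (p in c("alignment", "labels", "structure", "poses", "dose_response",
              "group_assay")) {
    if (!is.null(raw[[p]]) && !grepl("^/", raw[[p]])) {
      raw[[p]] <- file.path(base_dir, raw[[p]])
    }
  }
  if (!is.null(raw$roles)) raw$roles <- unlist(raw$roles)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "specmap_input_error")) {
      stop_input("stage '", name, "': ", conditionMessage(e))
    }
    stop_compute("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: separating-position
#' discovery on the alignment, structural context classification of those
#' positions, docking-region construction (box, flexible shell, engine
#' config), pose clustering with contacts and inter-mode score gaps, and
#' assay summaries. Produces a single report list, optionally written as
#' JSON; reruns with the same configuration and seed are byte-identical.
#'
#' @param config A [run_config()] or a YAML path accepted by
#'   [read_run_config()].
#' @return List of class `pipeline_report`; when `out_dir` is configured,
#'   the JSON path is in `report_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop_input("config must be a run_config")
  params <- config[!vapply(config, is.null, logical(1))]
  params$out_dir <- NULL  # not part of the analysis; keeps reruns byte-identical
  report <- list(parameters = params)

  model <- NULL
  if (!is.null(config$alignment)) {
    report$positions <- run_stage("positions", {
      aln <- read_alignment(config$alignment, config$labels,
                            reference = config$reference)
      pos <- find_separating_positions(aln)
      list(n_species = nrow(aln),
           n_columns = nchar(aln$seq[1]),
           separating = as.data.frame(pos),
           excluded_gap_columns = attr(pos, "excluded_columns"))
    })
  }
  if (!is.null(config$structure)) {
    model <- run_stage("structure", {
      read_structure(config$structure, roles = config$roles,
                     ligand = config$ligand)
    })
    report$context <- run_stage("context", {
      residues <- if (!is.null(report$positions) &&
                      nrow(report$positions$separating) > 0) {
        acc_chain <- unique(model$chain[model$role == "accessory-C"])[1]
        sprintf("%s:%d", acc_chain,
                report$positions$separating$ref_residue)
      } else NULL
      ctx <- classify_residue_context(
        model, residues = residues,
        pocket_cutoff = config$pocket_cutoff,
        interface_cutoff = config$interface_cutoff)
      as.data.frame(ctx)
    })
    report$docking_region <- run_stage("dockprep", {
      box <- compute_search_box(ligand_atoms(model),
                                padding = config$box_padding)
      shell <- select_flexible_shell(
        model, ligand_atoms(model),
        cutoffs = c("receptor-A" = config$pocket_cutoff,
                    "accessory-C" = config$pocket_cutoff,
                    "partner-B" = config$interface_cutoff))
      list(box = list(center = box$center, size = box$size),
           flexible_shell = as.data.frame(
             shell[, c("chain", "resnum", "role", "min_dist")]),
           config_text = emit_docking_config(
             box, shell, config$structure, "ligand.pdbqt",
             exhaustiveness = config$exhaustiveness,
             num_modes = config$num_modes))
    })
  }
  if (!is.null(config$poses)) {
    report$binding_modes <- run_stage("poses", {
      ps <- read_poses(config$poses)
      modes <- cluster_poses(ps, rmsd_threshold = config$cluster_rmsd)
      gap <- mode_score_gap(ps, rmsd_threshold = config$cluster_rmsd)
      contacts <- if (!is.null(model)) {
        lapply(seq_len(nrow(modes)), function(k) {
          rep_pose <- ps$coords[[match(modes$representative[k], ps$pose)]]
          as.data.frame(contact_residues(model, rep_pose,
                                         cutoff = config$contact_cutoff))
        })
      } else NULL
      list(n_poses = nrow(ps), n_modes = nrow(modes),
           modes = data.frame(mode = modes$mode, n_members = modes$n_members,
                              best_score = modes$best_score),
           gap = list(median = gap$median_gap, max = gap$max_gap,
                      per_run = as.data.frame(gap$per_run)),
           representative_contacts = contacts)
    })
  }
  if (!is.null(config$dose_response)) {
    report$dose_response <- run_stage("assay", {
      dr <- utils::read.csv(config$dose_response)
      fit <- fit_pec50(dr)
      list(trapezoid_auc = trapezoid_auc(dr), spline_auc = spline_auc(dr),
           pec50 = fit$pec50, converged = fit$converged)
    })
  }
  if (!is.null(config$group_assay)) {
    report$group_assay <- run_stage("group_assay", {
      ga <- utils::read.csv(config$group_assay)
      as.data.frame(percent_diff_ci(ga, level = config$level,
                                    seed = config$seed))
    })
  }
  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(config$out_dir, "report.json")
    write_report(report, path)
    report$report_path <- path
  }
  report
}

#' Write a pipeline report as JSON
#'
#' Deterministic serialization (fixed precision, no timestamps), so reruns
#' with identical inputs and seeds give byte-identical files.
#'
#' @param report A `pipeline_report`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  clean <- unclass(report)
  clean$parameters$roles <- as.list(clean$parameters$roles)
  json <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = 8,
                           pretty = TRUE, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Generates every file the pipeline consumes - alignment FASTA + labels
#' TSV, bound and unbound complex PDBs, a scored pose file, a dose-response
#' CSV and a cytokine group CSV - from the default planted truths, all
#' deterministic in the seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of file paths, with the planted truths in the
#'   `truth` attribute.
#' @export
synth_inputs <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aln <- gen_labeled_alignment(seed = seed)
  write_alignment(aln, file.path(dir, "alignment.fa"),
                  file.path(dir, "labels.tsv"))
  # structure truth mirrors the alignment truth: the separating columns
  # (130/132) sit on the distal surface, the conserved tyrosine-like column
  # (131) lines the pocket next to the mobile 120-129 loop, and residue 86
  # touches the dimerization partner
  cplx <- gen_toy_complex(
    n_residues = 160,
    truth = structure_truth(pocket = c(121L, 126L, 131L), interface = 86L,
                            surface = c(130L, 132L),
                            loop = c(120L, 122:125, 127:129)),
    seed = seed + 1)
  write_structure(cplx$bound, file.path(dir, "bound.pdb"))
  write_structure(cplx$unbound, file.path(dir, "unbound.pdb"))
  poses <- gen_pose_set(seed = seed + 2)
  write_poses(poses, file.path(dir, "poses.pdb"))
  dr <- gen_dose_response(concentrations = 10^seq(-9, -4, by = 0.5),
                          seed = seed + 3)
  utils::write.csv(as.data.frame(dr), file.path(dir, "dose_response.csv"),
                   row.names = FALSE)
  ga <- gen_group_assay(mean_ref = 100, mean_cmp = 180, seed = seed + 4)
  utils::write.csv(as.data.frame(ga), file.path(dir, "group_assay.csv"),
                   row.names = FALSE)
  out <- list(alignment = file.path(dir, "alignment.fa"),
              labels = file.path(dir, "labels.tsv"),
              structure = file.path(dir, "bound.pdb"),
              unbound = file.path(dir, "unbound.pdb"),
              poses = file.path(dir, "poses.pdb"),
              dose_response = file.path(dir, "dose_response.csv"),
              group_assay = file.path(dir, "group_assay.csv"))
  attr(out, "truth") <- list(alignment = attr(aln, "truth"),
                             structure = cplx$truth,
                             dose_response = attr(dr, "truth"),
                             group_assay = attr(ga, "true_pct_diff"))
  out
}
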