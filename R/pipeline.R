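# End-to-end orchestration: write a synthetic study to disk, read study
# inputs, and run the full analysis (anchor quantification -> label-free
# calibration -> flux integration -> regulation -> allocation) with a run
# log of filter-stage counts.

#' Write a complete synthetic study to a directory
#'
#' Generates ground truth, DIA intensities, the dilution series, and flux /
#' expression tables, and writes every input the pipeline consumes as
#' tab-separated text (plus FASTA sequences and the truth tables for
#' validation).
#'
#' @param dir Output directory (created if absent).
#' @param truth Optional pre-built [generate_ground_truth()] object.
#' @param design [dia_design()] list.
#' @param seed Random seed (used for the ground truth when `truth` is
#'   `NULL`).
#' @param ... Passed to [generate_ground_truth()].
#' @return Invisibly, a list with `truth` and the simulated tables.
#' @export
simulate_study <- function(dir, truth = NULL, design = dia_design(),
                           seed = 1L, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(truth)) truth <- generate_ground_truth(seed = seed, ...)
  dia <- simulate_dia_intensities(truth, design)
  dil <- simulate_dilution_series(truth, design)
  flx <- simulate_fluxes_and_expression(truth)

  write_table_tsv(dia$measurements, file.path(dir, "peptide_measurements.tsv"))
  write_table_tsv(dia$features, file.path(dir, "fragment_features.tsv"))
  write_table_tsv(dia$spikes, file.path(dir, "spike_amounts.tsv"))
  write_table_tsv(dia$biomass, file.path(dir, "biomass_equivalents.tsv"))
  write_table_tsv(dia$samples, file.path(dir, "samples.tsv"))
  write_table_tsv(dil$dilution, file.path(dir, "dilution_series.tsv"))
  write_table_tsv(flx$fluxes, file.path(dir, "fluxes.tsv"))
  write_table_tsv(flx$expression, file.path(dir, "enzyme_expression.tsv"))
  write_table_tsv(flx$gpr, file.path(dir, "gpr.tsv"))
  write_fasta(truth$proteins, file.path(dir, "proteins.fasta"))

  hierarchy <- synthetic_hierarchy(truth)
  write_table_tsv(hierarchy, file.path(dir, "hierarchy.tsv"))

  write_table_tsv(truth$concentrations, file.path(dir, "truth_concentrations.tsv"))
  write_table_tsv(dil$planted, file.path(dir, "truth_dilution_lloq.tsv"))
  write_table_tsv(flx$truth, file.path(dir, "truth_regulation.tsv"))
  writeLines(flx$reference_reaction, file.path(dir, "reference_reaction.txt"))

  invisible(list(truth = truth, dia = dia, dilution = dil, flux = flx,
                 hierarchy = hierarchy))
}

# deterministic toy functional hierarchy: proteins binned by id into a
# handful of categories
synthetic_hierarchy <- function(truth) {
  ids <- truth$proteins$protein_id
  l1 <- c("Metabolism", "Genetic information processing",
          "Cellular processes", "Environmental information processing")
  l2 <- c("C1 fixation", "Amino acid metabolism", "Translation",
          "Energy conservation", "Membrane transport", "Folding and repair")
  i <- seq_along(ids)
  data.frame(protein_id = ids,
             level1 = l1[(i %% length(l1)) + 1L],
             level2 = l2[(i %% length(l2)) + 1L],
             level3 = paste0(l2[(i %% length(l2)) + 1L], " / sub",
                             (i %% 3L) + 1L),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline on study inputs
#'
#' Executes anchor quantification (dilution-series calibration, peptide
#' filtering, concentration computation), per-sample label-free model
#' selection and proteome estimation, total proteome mass, k_app
#' integration, regulation classification, and allocation aggregation, and
#' writes the report tables plus a run log of counts at each filter stage.
#'
#' @param input_dir Directory produced by [simulate_study()] (or holding
#'   equivalent tables).
#' @param output_dir Directory for report tables (created if absent).
#' @param config [pipeline_config()] list.
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(input_dir, output_dir = file.path(input_dir, "out"),
                         config = pipeline_config()) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_lines <- c(paste("anchorlfq", as.character(utils::packageVersion("anchorlfq"))),
                 paste("seed:", config$seed))
  stage <- function(...) log_lines <<- c(log_lines, paste0(...))

  meas <- read_table_checked(file.path(input_dir, "peptide_measurements.tsv"),
                             c("protein_id", "peptide", "sample_id",
                               "condition", "replicate", "light_intensity",
                               "heavy_intensity"))
  dil <- read_table_checked(file.path(input_dir, "dilution_series.tsv"),
                            c("peptide", "level", "light_intensity",
                              "heavy_intensity"))
  spikes <- read_table_checked(file.path(input_dir, "spike_amounts.tsv"),
                               c("protein_id", "sample_id", "amount"))
  biomass <- read_table_checked(file.path(input_dir, "biomass_equivalents.tsv"),
                                c("sample_id", "gdcw"))
  features <- read_table_checked(file.path(input_dir, "fragment_features.tsv"),
                                 c("protein_id", "peptide", "sample_id",
                                   "fragment_index", "intensity"))
  sequences <- read_fasta(file.path(input_dir, "proteins.fasta"))

  # --- anchor quantification ---
  stage("anchor peptides in: ", length(unique(meas$peptide)))
  filt <- filter_anchor_peptides(meas, dil, config = config)
  stage("anchor peptides retained: ",
        length(unique(filt$measurements$peptide)))
  anchors <- compute_anchor_concentrations(filt$measurements, spikes,
                                           biomass, cv_max = config$cv_max)
  quality <- summarize_anchor_quality(anchors$condition_level,
                                      anchors$peptide_level)
  stage("anchor proteins quantified: ",
        length(unique(anchors$condition_level$protein_id)))
  write_table_tsv(filt$removal_log, file.path(output_dir, "removal_log.tsv"))
  write_table_tsv(filt$calibrations,
                  file.path(output_dir, "dilution_calibrations.tsv"))
  write_table_tsv(anchors$condition_level,
                  file.path(output_dir, "anchor_concentrations.tsv"))

  # --- label-free calibration and proteome estimation, per sample ---
  observable <- vapply(sequences$sequence, count_observable_peptides,
                       integer(1),
                       missed_cleavages = config$ibaq_missed_cleavages,
                       length_range = config$ibaq_length_range,
                       USE.NAMES = FALSE)
  names(observable) <- sequences$protein_id
  anchor_sample <- anchors$sample_level[, c("protein_id", "sample_id",
                                            "conc")]
  sample_ids <- sort(unique(anchor_sample$sample_id))
  proteome <- list(); fits <- list()
  for (sid in sample_ids) {
    sel <- select_lfq_model(features, anchor_sample, sid,
                            observable_counts = observable, config = config)
    fit <- sel$fits[1, ]
    est <- estimate_proteome(fit, sel$intensities,
                             anchor_conc = anchor_sample[
                               anchor_sample$sample_id == sid, ],
                             report_anchor_sil = config$report_anchor_sil)
    proteome[[sid]] <- est
    fits[[sid]] <- cbind(sample_id = sid, sel$fits)
    stage("sample ", sid, ": best model ", sel$best,
          " (CV-MFE ", round(fit$cv_mfe, 3), "), proteins ", nrow(est))
  }
  proteome <- do.call(rbind, proteome)
  rownames(proteome) <- NULL
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  mass <- total_proteome_mass(proteome, sequences, biomass)
  write_table_tsv(proteome, file.path(output_dir, "proteome_concentrations.tsv"))
  write_table_tsv(fits, file.path(output_dir, "lfq_model_fits.tsv"))
  write_table_tsv(mass, file.path(output_dir, "proteome_mass.tsv"))

  # condition-level concentrations for downstream integration
  pr <- data.table::as.data.table(proteome)
  smp <- read_table_checked(file.path(input_dir, "samples.tsv"),
                            c("sample_id", "condition"))
  pr <- data.table::as.data.table(smp)[pr, on = "sample_id"]
  cond_conc <- pr[, .(mean = mean(conc), sd = sd(conc)),
                  by = .(protein_id, condition)]

  # --- flux integration and regulation ---
  kapp <- NULL; correlations <- NULL; regulation <- NULL
  flux_path <- file.path(input_dir, "fluxes.tsv")
  if (file.exists(flux_path)) {
    fluxes <- read_table_checked(flux_path, c("reaction_id", "condition",
                                              "replicate", "value"))
    gpr <- read_table_checked(file.path(input_dir, "gpr.tsv"),
                              c("reaction_id", "alternative_index",
                                "protein_id", "membrane_flag"))
    ref <- readLines(file.path(input_dir, "reference_reaction.txt"))[1]
    kapp <- kapp_table(fluxes, gpr, as.data.frame(cond_conc), ref,
                       config = config)
    stage("reactions with k_app: ", length(unique(kapp$reaction_id)))
    correlations <- flux_proteome_correlations(kapp)
    write_table_tsv(kapp, file.path(output_dir, "kapp.tsv"))

    expr_path <- file.path(input_dir, "enzyme_expression.tsv")
    if (file.exists(expr_path)) {
      expr <- read_table_checked(expr_path, c("reaction_id", "condition",
                                              "replicate",
                                              "relative_intensity"))
      regulation <- classify_regulation(fluxes, expr, alpha = config$alpha)
      stage("significant flux changes: ",
            sum(regulation$call %in% c("posttranslational", "translational",
                                       "no_enzyme_data")))
      write_table_tsv(regulation, file.path(output_dir, "regulation.tsv"))
    }
  }

  # --- allocation ---
  allocation <- NULL
  hier_path <- file.path(input_dir, "hierarchy.tsv")
  if (file.exists(hier_path)) {
    hierarchy <- read_table_checked(hier_path, c("protein_id", "level1"))
    cond_avg <- pr[, .(conc = mean(conc)), by = protein_id]
    allocation <- aggregate_allocation(as.data.frame(cond_avg), sequences,
                                       hierarchy, level = 1L,
                                       weight = config$allocation_weight)
    write_table_tsv(allocation, file.path(output_dir, "allocation.tsv"))
  }

  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(list(filtered = filt, anchors = anchors, quality = quality,
                 fits = fits, proteome = proteome, mass = mass,
                 condition_concentrations = as.data.frame(cond_conc),
                 kapp = kapp, correlations = correlations,
                 regulation = regulation, allocation = allocation,
                 log = log_lines))
}
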