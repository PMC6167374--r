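#' End-to-end pipeline orchestration
#'
#' One config drives simulate -> TMT quant -> QC -> ageing statistics ->
#' LF/pathways -> ligand-receptor -> single-cell stages, producing a
#' reproducible run directory with a JSON manifest. Stages execute in
#' dependency order; rerunning with the same config and seed is
#' bit-identical apart from nothing (no timestamps are recorded).
#'
#' @name pipeline
NULL

#' Simulate a miniature pathway database over a protein universe
#'
#' Random member sets drawn from the supplied protein names, with a flat
#' two-level hierarchy; used to exercise the pathway analytics on synthetic
#' data.
#'
#' @param proteins protein/gene identifiers to draw from.
#' @param n_pathways number of pathways.
#' @param size_range member-count range.
#' @param seed integer seed.
#' @return pathway data.frame as from [load_pathways()].
#' @export
simulate_pathway_db <- function(proteins, n_pathways = 20L,
                                size_range = c(5L, 30L), seed = 1L) {
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_pathways, replace = TRUE)
  members <- lapply(sizes, function(k) sample(proteins, min(k, length(proteins))))
  out <- data.frame(id = sprintf("PW%03d", seq_len(n_pathways)),
                    name = sprintf("synthetic pathway %d", seq_len(n_pathways)),
                    top_hierarchy = sample(c("Metabolism", "Signaling", "Immune"),
                                           n_pathways, replace = TRUE),
                    level = sample(0:3, n_pathways, replace = TRUE),
                    stringsAsFactors = FALSE)
  out$members <- members
  out$n_members <- lengths(members)
  out
}

#' Pipeline run configuration
#'
#' All thresholds default to the pipeline's standard values: isolation
#' interference 30, reporter sum 30,000, donor coverage 15 percent,
#' significance 0.05 (age) and 0.1 (ligand-receptor), donor overlap 85
#' percent, HDR rejection 97 percent, tendency band 0.001 per year,
#' pathway sizes 5--100 (stoichiometry) and 5--150 (ageing).
#'
#' @param out_dir run directory (created if needed).
#' @param seed master seed; stage seeds derive from it.
#' @param stages stages to run, in dependency order.
#' @param n_donors,populations,n_proteins,n_pathways,n_cells problem sizes.
#' @param noise a [noise_model()].
#' @param planted_slopes,planted_stoichiometry,planted_outliers,planted_lr_pairs
#'   planted truth handed to [cohort_config()]; `NULL` selects a small
#'   default plant covering slopes, one outlier, and one LR pair.
#' @param thresholds named list overriding individual defaults.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "tmt", "qc", "ageing", "lf",
                                  "pathways", "lr", "singlecell"),
                       n_donors = 15L, populations = c("HPC", "MSC"),
                       n_proteins = 60L, n_pathways = 12L, n_cells = 200L,
                       noise = noise_model(),
                       planted_slopes = NULL, planted_stoichiometry = NULL,
                       planted_outliers = NULL, planted_lr_pairs = NULL,
                       thresholds = list()) {
  defaults <- list(max_interference = 30, min_reporter_sum = 30000,
                   min_coverage = 0.15, p_age = 0.05, p_lr = 0.1,
                   min_overlap = 0.85, hdr_reject = 97, tendency_band = 0.001,
                   stoich_size = c(5, 100), ageing_size = c(5, 150))
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) stopf("unknown threshold(s): %s", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 n_donors = n_donors, populations = populations,
                 n_proteins = n_proteins, n_pathways = n_pathways,
                 n_cells = n_cells, noise = noise,
                 planted_slopes = planted_slopes,
                 planted_stoichiometry = planted_stoichiometry,
                 planted_outliers = planted_outliers,
                 planted_lr_pairs = planted_lr_pairs,
                 thresholds = defaults),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value document mirroring the arguments of [run_config()]; a
#' `defaults:` block overrides thresholds explicitly so deviations are
#' visible in the manifest.
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = out_dir %||% y$out_dir %||% stopf("out_dir required"),
             seed = y$seed %||% 1L,
             stages = y$stages %||% formals(run_config)$stages,
             n_donors = y$n_donors %||% 15L,
             populations = y$populations %||% c("HPC", "MSC"),
             n_proteins = y$n_proteins %||% 60L,
             n_pathways = y$n_pathways %||% 12L,
             n_cells = y$n_cells %||% 200L,
             thresholds = y$defaults %||% list())
}

default_plants <- function(config) {
  prot <- sprintf("P%04d", seq_len(config$n_proteins))
  pops <- config$populations
  list(
    slopes = data.frame(
      protein = prot[1:6], population = pops[1],
      slope = c(0.004, 0.003, -0.004, 0.005, -0.003, 0.004),
      stringsAsFactors = FALSE),
    stoich = data.frame(protein = prot[7], population = pops[length(pops)],
                        multiplier = 4, stringsAsFactors = FALSE),
    outliers = character(0),
    lr = if ("MSC" %in% pops && length(pops) > 1L)
      data.frame(ligand = prot[8], receptor = prot[9],
                 population = setdiff(pops, "MSC")[1], slope = 0.004,
                 stringsAsFactors = FALSE) else NULL)
}

#' Run the pipeline
#'
#' @param config a [run_config()].
#' @return the run manifest (invisibly written to
#'   `<out_dir>/manifest.json`): stage outputs, parameter echo, seed, and
#'   package version.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  manifest <- list(
    seed = config$seed,
    parameters = th,
    sizes = list(n_donors = config$n_donors, populations = config$populations,
                 n_proteins = config$n_proteins, n_cells = config$n_cells),
    package_version = as.character(utils::packageVersion("marrowquant")),
    stages = list())
  state <- new.env(parent = emptyenv())
  record <- function(stage, outputs) {
    manifest$stages[[stage]] <<- outputs
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  }
  out_path <- function(...) file.path(config$out_dir, ...)

  stage_simulate <- function() {
    plants <- default_plants(config)
    cc <- cohort_config(
      n_donors = config$n_donors, populations = config$populations,
      seed = config$seed,
      planted_slopes = config$planted_slopes %||% plants$slopes,
      planted_stoichiometry = config$planted_stoichiometry %||% plants$stoich,
      planted_outliers = config$planted_outliers %||% plants$outliers,
      planted_lr_pairs = config$planted_lr_pairs %||% plants$lr)
    state$cohort <- simulate_cohort(cc)
    state$proteins <- simulate_protein_db(config$n_proteins,
                                          seed = derive_seed(config$seed, 1))
    state$psms <- simulate_psm_table(state$cohort, state$proteins,
                                     noise = config$noise,
                                     seed = derive_seed(config$seed, 2))
    write_sample_meta(state$cohort$samples, out_path("samples.csv"))
    write_fasta(state$proteins, out_path("proteins.fasta"))
    write_psm_table(state$psms, out_path("psms.tsv"))
    write_ground_truth(state$cohort$truth, out_path("ground_truth.json"))
    record("simulate", list(samples = "samples.csv", fasta = "proteins.fasta",
                            psms = "psms.tsv", truth = "ground_truth.json"))
  }

  stage_tmt <- function() {
    state$raw <- tmt_protein_matrices(state$psms, state$cohort$samples)
    files <- list()
    for (pop in names(state$raw)) {
      f <- sprintf("tmt_raw_%s.tsv", pop)
      write_matrix_tsv(state$raw[[pop]], out_path(f))
      files[[pop]] <- f
    }
    record("tmt", files)
  }

  stage_qc <- function() {
    eff <- labelling_efficiency(state$psms)
    utils::write.csv(eff$per_batch, out_path("labelling_efficiency.csv"),
                     row.names = FALSE)
    state$retained <- list()
    reports <- list()
    for (pop in names(state$raw)) {
      rep <- detect_outlier_samples(log2(state$raw[[pop]]$values))
      state$retained[[pop]] <- rep$retained
      reports[[pop]] <- cbind(population = pop, rep$samples)
    }
    qc_df <- do.call(rbind, reports)
    utils::write.csv(qc_df, out_path("outlier_report.csv"), row.names = FALSE)
    # drop discarded samples from downstream matrices
    for (pop in names(state$raw)) {
      keep <- colnames(state$raw[[pop]]$values) %in% state$retained[[pop]]
      m <- state$raw[[pop]]
      state$raw[[pop]] <- ratio_matrix(m$values[, keep, drop = FALSE],
                                       state = "raw",
                                       batch = m$batch[keep],
                                       channel = m$channel[keep])
    }
    record("qc", list(labelling = "labelling_efficiency.csv",
                      outliers = "outlier_report.csv",
                      median_efficiency_pct = eff$median_pct))
  }

  stage_ageing <- function() {
    state$assoc <- list(); state$slopes <- list(); state$stud <- list()
    files <- list()
    for (pop in names(state$raw)) {
      stud <- suppressWarnings(studentize_matrix(state$raw[[pop]]))
      mn <- suppressWarnings(mean_normalize_matrix(state$raw[[pop]]))
      smp <- state$cohort$samples
      assoc <- age_correlation(stud, smp, min_coverage = th$min_coverage,
                               p_threshold = th$p_age, population = pop)
      slopes <- age_slopes(mn, smp)
      state$stud[[pop]] <- stud
      state$assoc[[pop]] <- assoc
      state$slopes[[pop]] <- slopes
      f <- sprintf("age_association_%s.tsv", pop)
      utils::write.table(merge(assoc, slopes, by = "protein"), out_path(f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files[[pop]] <- f
    }
    record("ageing", files)
  }

  stage_lf <- function() {
    lf <- lf_quantify(state$psms, state$proteins, state$cohort$samples)
    state$lf <- lf
    write_matrix_tsv(lf$matrix, out_path("lf_normalized.tsv"))
    utils::write.table(lf$lf_sums, out_path("lf_sums.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("lf", list(matrix = "lf_normalized.tsv", sums = "lf_sums.tsv"))
  }

  stage_pathways <- function() {
    pw <- simulate_pathway_db(names(as.character(state$proteins)),
                              n_pathways = config$n_pathways,
                              seed = derive_seed(config$seed, 3))
    write_pathways(pw, out_path("pathways.gmt"), out_path("pathway_hierarchy.tsv"))
    res <- list()
    for (pop in names(state$assoc)) {
      res[[pop]] <- pathway_age_results(pw, state$assoc[[pop]],
                                        state$slopes[[pop]], pop,
                                        size_range = th$ageing_size,
                                        band = th$tendency_band)
    }
    age_df <- do.call(rbind, lapply(res, function(d) d[, setdiff(names(d), "sig_members")]))
    utils::write.table(age_df, out_path("pathway_ageing.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    # stoichiometry on raw LF donor columns per population
    if (!is.null(state$lf)) {
      smp <- state$cohort$samples
      by_pop <- lapply(split(smp$sample_id, smp$population), function(ids) {
        cols <- intersect(ids, colnames(state$lf$lf_raw$values))
        state$lf$lf_raw$values[, cols, drop = FALSE]
      })
      st <- pathway_stoichiometry(by_pop, pw, size_range = th$stoich_size,
                                  min_coverage = th$min_coverage)
      if (nrow(st$pathways))
        utils::write.table(st$pathways, out_path("pathway_stoichiometry.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    record("pathways", list(gmt = "pathways.gmt", ageing = "pathway_ageing.tsv",
                            stoichiometry = "pathway_stoichiometry.tsv"))
  }

  stage_lr <- function() {
    truth_lr <- state$cohort$truth$lr_pairs
    if (is.null(truth_lr) || !"MSC" %in% names(state$stud)) {
      record("lr", list(skipped = "no ligand-receptor pairs planted"))
      return(invisible())
    }
    pairs <- truth_lr[, c("ligand", "receptor")]
    lr <- lr_correlation_matrix(pairs, state$stud, state$assoc,
                                state$cohort$samples, p_gate = th$p_lr,
                                min_overlap = th$min_overlap)
    utils::write.table(lr, out_path("lr_correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("lr", list(correlations = "lr_correlations.tsv", n_pairs = nrow(lr)))
  }

  stage_singlecell <- function() {
    mk <- default_marker_sets()
    sim <- simulate_singlecell_counts(config$n_cells,
                                      seed = derive_seed(config$seed, 4))
    write_counts_mm(sim$counts, out_path("sc_counts"))
    qc <- qc_filter_cells_genes(sim$counts)
    if (qc$empty) stopf("no cells or genes survive single-cell QC")
    expr <- normalize_cell_expression(qc$counts, sim$cells)
    refined <- refine_lineage_markers(expr, mk$lymphoid, mk$myeloid)
    calls <- classify_cells(expr, refined$lymphoid, refined$myeloid,
                            exclusion_genes = mk$exclusion)
    utils::write.csv(calls, out_path("cell_classification.csv"), row.names = FALSE)
    enr <- fraction_marker_enrichment(calls, expr, refined$lymphoid, refined$myeloid)
    utils::write.csv(enr$per_sample, out_path("fraction_enrichment.csv"),
                     row.names = FALSE)
    acc <- mean(calls$label[sim$truth$labels[calls$cell_id] != "undefined"] ==
                  sim$truth$labels[calls$cell_id][sim$truth$labels[calls$cell_id] != "undefined"])
    record("singlecell", list(counts = "sc_counts.mtx",
                              classification = "cell_classification.csv",
                              enrichment = "fraction_enrichment.csv",
                              primed_accuracy = acc))
  }

  runners <- list(simulate = stage_simulate, tmt = stage_tmt, qc = stage_qc,
                  ageing = stage_ageing, lf = stage_lf,
                  pathways = stage_pathways, lr = stage_lr,
                  singlecell = stage_singlecell)
  deps <- list(simulate = character(), tmt = "simulate", qc = "tmt",
               ageing = "qc", lf = "simulate", pathways = c("ageing", "lf"),
               lr = "ageing", singlecell = character())
  done <- character()
  for (stage in intersect(names(runners), config$stages)) {
    missing_dep <- setdiff(deps[[stage]], done)
    if (length(missing_dep))
      fail(stage, simpleError(sprintf("unmet dependency: %s",
                                      paste(missing_dep, collapse = ", "))))
    tryCatch(runners[[stage]](), error = function(e) fail(stage, e))
    done <- c(done, stage)
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
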