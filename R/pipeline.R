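#' Pipeline configuration
#'
#' Collects the analysis parameters for [run_crh_pipeline()]. Every
#' published default is surfaced: 500-bp promoters, ABC threshold 0.012 (or
#' calibration to a mean of 4.51 distal elements per gene within two to
#' five), 5-Mb scoring window, 500-bp annotation extension for heritability
#' preparation and the (3, 25) promoter-count strata.
#'
#' @param seed Integer seed (drives the simulate stage).
#' @param promoter_width Promoter window width (bp).
#' @param abc_threshold Functional-pair score threshold; `NULL` calibrates
#'   via [calibrate_threshold()].
#' @param calibration_target,calibration_bounds Calibration parameters used
#'   when `abc_threshold` is `NULL`.
#' @param window ABC scoring window (bp).
#' @param snp_p_thresholds Association p-value thresholds for SNP enrichment.
#' @param ldsc_extend Extension (bp) for heritability-annotation preparation.
#' @param strata Promoter-count strata bounds `c(small_max, medium_max)`.
#' @param fixture A `fixture_config` for the simulate stage; defaults to
#'   `fixture_config(seed = seed)`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            promoter_width = 500,
                            abc_threshold = 0.012,
                            calibration_target = 4.51,
                            calibration_bounds = c(2, 5),
                            window = 5e6,
                            snp_p_thresholds = c(1e-4, 1e-3, 1e-2, 5e-2),
                            ldsc_extend = 500,
                            strata = c(3, 25),
                            fixture = NULL) {
  if (!is.null(abc_threshold) &&
      (abc_threshold < 0 || abc_threshold > 1)) {
    stop_crhub("`abc_threshold` must lie in [0, 1]", "crhub_validation_error")
  }
  if (any(snp_p_thresholds <= 0 | snp_p_thresholds > 1)) {
    stop_crhub("SNP p-value thresholds must lie in (0, 1]",
               "crhub_validation_error")
  }
  cfg <- list(
    seed = seed, promoter_width = promoter_width,
    abc_threshold = abc_threshold,
    calibration_target = calibration_target,
    calibration_bounds = calibration_bounds,
    window = window, snp_p_thresholds = snp_p_thresholds,
    ldsc_extend = ldsc_extend, strata = strata,
    fixture = fixture %||% fixture_config(seed = seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with scalar fields of `pipeline_config()`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "fixture")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop_crhub(sprintf("unknown config key '%s'", unknown[1]),
               "crhub_validation_error")
  }
  do.call(pipeline_config, y)
}

pipeline_stages <- c("simulate", "abc", "crh", "overlap", "enrich",
                     "deglink", "report")

stage_deps <- list(
  simulate = character(0), abc = "simulate", crh = "abc",
  overlap = "crh", enrich = "crh", deglink = "crh",
  report = c("overlap", "enrich", "deglink")
)

stage_marker <- function(outdir, stage) {
  file.path(outdir, paste0("manifest_", stage, ".json"))
}

write_manifest <- function(outdir, stage, params, inputs, outputs, t0) {
  files <- inputs[file.exists(inputs)]
  jsonlite::write_json(
    list(
      stage = stage,
      params = params,
      inputs = as.list(tools::md5sum(files)),
      outputs = basename(outputs),
      wall_time_s = as.numeric(Sys.time()) - t0,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    stage_marker(outdir, stage), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
}

#' Run the hub analysis pipeline
#'
#' Config-driven orchestration of all stages: `simulate` (write a seeded
#' fixture), `abc` (activity and ABC scoring), `crh` (hub construction),
#' `overlap` (compartment/TAD/FIRE/state analyses), `enrich` (SNP, gene,
#' expression and heritability-preparation statistics), `deglink`
#' (SNP-to-DEG linkage across structure kinds) and `report` (aggregate JSON
#' summary). Each stage reads its inputs from `outdir`, writes TSV/JSON
#' results plus a manifest with input hashes and parameters, and is
#' deterministic given (inputs, config, seed); reruns reproduce identical
#' result files (manifests carry timestamps and are excluded).
#'
#' @param config A `pipeline_config`, or path to a YAML file.
#' @param outdir Artifact directory (created).
#' @param stages Subset of stages to run, in pipeline order.
#' @return `outdir`, invisibly.
#' @export
run_crh_pipeline <- function(config = pipeline_config(), outdir,
                             stages = pipeline_stages) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  for (stage in stages) {
    done <- c(stages[seq_len(match(stage, stages) - 1)],
              pipeline_stages[file.exists(stage_marker(outdir, pipeline_stages))])
    missing_dep <- setdiff(stage_deps[[stage]], done)
    if (length(missing_dep) > 0) {
      stop_crhub(sprintf(
        "stage '%s' requires stage '%s' to have run first",
        stage, missing_dep[1]
      ), "crhub_dependency_error")
    }
    message(sprintf("[crhub] running stage '%s'", stage))
    t0 <- as.numeric(Sys.time())
    switch(stage,
      simulate = stage_simulate(config, outdir, t0),
      abc = stage_abc(config, outdir, t0),
      crh = stage_crh(config, outdir, t0),
      overlap = stage_overlap(config, outdir, t0),
      enrich = stage_enrich(config, outdir, t0),
      deglink = stage_deglink(config, outdir, t0),
      report = stage_report(config, outdir, t0)
    )
  }
  invisible(outdir)
}

data_path <- function(outdir, ...) file.path(outdir, "data", ...)

stage_simulate <- function(config, outdir, t0) {
  sim <- simulate_crh_dataset(config$fixture)
  write_fixture(sim, data_path(outdir))
  outs <- list.files(data_path(outdir), full.names = TRUE)
  write_manifest(outdir, "simulate",
                 params = list(seed = config$seed),
                 inputs = character(0), outputs = outs, t0 = t0)
}

# Shared loaders over the on-disk fixture formats.
load_inputs <- function(config, outdir) {
  dd <- data_path(outdir)
  genes <- readr::read_tsv(file.path(dd, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  dnase <- read_intervals(file.path(dd, "dnase.narrowPeak"), "narrowPeak")
  h3k <- read_intervals(file.path(dd, "h3k27ac.bedGraph"), "bedGraph")
  elements <- dnase |>
    dplyr::rename(element_id = "id", dnase_signal = "signal") |>
    dplyr::left_join(
      h3k |>
        dplyr::select("chrom", "start", "end", h3k27ac_signal = "signal"),
      by = c("chrom", "start", "end")
    ) |>
    dplyr::mutate(
      activity = compute_activity(.data$dnase_signal, .data$h3k27ac_signal)
    ) |>
    dplyr::select("element_id", "chrom", "start", "end", "dnase_signal",
                  "h3k27ac_signal", "activity")
  contact_files <- list.files(dd, pattern = "^contacts_.*\\.tsv$",
                              full.names = TRUE)
  contacts <- purrr::map(contact_files, load_contacts)
  names(contacts) <- purrr::map_chr(contacts, "chrom")
  list(
    genes = genes,
    promoters = make_promoters(genes, config$promoter_width),
    elements = elements,
    contacts = contacts,
    snps = read_snps(file.path(dd, "snps.tsv")),
    gene_stats = readr::read_tsv(file.path(dd, "gene_stats.tsv"),
                                 show_col_types = FALSE, progress = FALSE),
    annotations = list(
      compartments = read_intervals(file.path(dd, "compartments.bed"), "bed") |>
        dplyr::rename(label = "id"),
      tads = read_intervals(file.path(dd, "tads.bed"), "bed"),
      fires = read_intervals(file.path(dd, "fires.bed"), "bed"),
      states = read_intervals(file.path(dd, "states.bed"), "bed") |>
        dplyr::rename(label = "id")
    )
  )
}

stage_abc <- function(config, outdir, t0) {
  inp <- load_inputs(config, outdir)
  pairs <- suppressWarnings(compute_abc_scores(
    inp$elements, inp$promoters, inp$contacts, window = config$window
  ))
  thr <- config$abc_threshold %||% as.numeric(calibrate_threshold(
    pairs, config$calibration_target, config$calibration_bounds
  ))
  pairs <- threshold_pairs(pairs, thr)
  dir.create(file.path(outdir, "abc"), showWarnings = FALSE)
  write_pairs(pairs, file.path(outdir, "abc", "pairs.tsv"))
  jsonlite::write_json(list(threshold = thr, n_pairs = nrow(pairs),
                            n_functional = sum(pairs$functional)),
                       file.path(outdir, "abc", "abc_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "abc",
                 params = list(window = config$window, threshold = thr),
                 inputs = list.files(data_path(outdir), full.names = TRUE),
                 outputs = file.path(outdir, "abc", "pairs.tsv"), t0 = t0)
}

rebuild_crhs <- function(config, outdir) {
  inp <- load_inputs(config, outdir)
  pairs <- read_pairs(file.path(outdir, "abc", "pairs.tsv"))
  crhs <- build_crhs(functional_pairs(pairs), promoters = inp$promoters)
  list(inp = inp, pairs = pairs, crhs = crhs)
}

stage_crh <- function(config, outdir, t0) {
  st <- rebuild_crhs(config, outdir)
  write_crh_set(st$crhs, file.path(outdir, "crh"))
  readr::write_tsv(role_census(st$crhs),
                   file.path(outdir, "crh", "role_census.tsv"),
                   progress = FALSE)
  readr::write_tsv(degree_profile(st$crhs),
                   file.path(outdir, "crh", "degree_profile.tsv"),
                   progress = FALSE)
  write_manifest(outdir, "crh", params = list(),
                 inputs = file.path(outdir, "abc", "pairs.tsv"),
                 outputs = list.files(file.path(outdir, "crh"),
                                      full.names = TRUE), t0 = t0)
}

stage_overlap <- function(config, outdir, t0) {
  st <- rebuild_crhs(config, outdir)
  ann <- st$inp$annotations
  dir.create(file.path(outdir, "overlap"), showWarnings = FALSE)
  comp <- compartment_category(st$crhs, ann$compartments)
  readr::write_tsv(comp, file.path(outdir, "overlap", "compartments.tsv"),
                   progress = FALSE)
  readr::write_tsv(compartment_distribution(comp),
                   file.path(outdir, "overlap", "compartment_distribution.tsv"),
                   progress = FALSE)
  readr::write_tsv(tad_overlap_count(st$crhs, ann$tads),
                   file.path(outdir, "overlap", "tad_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(tads_with_k_crhs(st$crhs, ann$tads),
                   file.path(outdir, "overlap", "tad_histogram.tsv"),
                   progress = FALSE)
  fun_el <- functional_elements(st$pairs)
  cand <- build_candidate_sets(
    dnase_peaks = st$inp$elements |>
      dplyr::mutate(id = .data$element_id),
    functional_elements = fun_el,
    all_genes = st$inp$genes, crh_set = st$crhs,
    promoter_width = config$promoter_width
  )
  fire_enr <- region_set_enrichment(fun_el, cand$candidate_distal, ann$fires)
  comb <- state_combination(st$crhs, ann$states)
  readr::write_tsv(comb, file.path(outdir, "overlap", "state_combinations.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(fire_enrichment = tidy(fire_enr),
         unique_state_combinations = combination_census(comb)$n_unique),
    file.path(outdir, "overlap", "overlap_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_manifest(outdir, "overlap", params = list(),
                 inputs = file.path(outdir, "abc", "pairs.tsv"),
                 outputs = list.files(file.path(outdir, "overlap"),
                                      full.names = TRUE), t0 = t0)
}

# Functional distal elements as an interval set with ids.
functional_elements <- function(pairs) {
  fp <- functional_pairs(pairs)
  fp |>
    dplyr::distinct(.data$element_id, .data$chrom, .data$element_start,
                    .data$element_end) |>
    dplyr::transmute(chrom = .data$chrom, start = .data$element_start,
                     end = .data$element_end, id = .data$element_id)
}

stage_enrich <- function(config, outdir, t0) {
  st <- rebuild_crhs(config, outdir)
  dir.create(file.path(outdir, "enrich"), showWarnings = FALSE)
  fun_el <- functional_elements(st$pairs)
  cand <- build_candidate_sets(
    dnase_peaks = st$inp$elements |>
      dplyr::mutate(id = .data$element_id),
    functional_elements = fun_el,
    all_genes = st$inp$genes, crh_set = st$crhs,
    promoter_width = config$promoter_width
  )
  cand_el <- cand$candidate_distal[, c("chrom", "start", "end", "id")]
  snp_enr <- purrr::map_dfr(config$snp_p_thresholds, function(pt) {
    # small fixtures may have no significant SNP at stringent thresholds;
    # record NA rather than aborting the stage
    res <- tryCatch(
      tidy(snp_threshold_enrichment(st$inp$snps, fun_el, cand_el,
                                    p_thresh = pt)),
      crhub_error = function(e) {
        tibble(a = NA_integer_, b = NA_integer_, c = NA_integer_,
               d = NA_integer_, odds_ratio = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p_value = NA_real_, corrected = NA)
      }
    )
    fold <- tryCatch(
      relative_fold_enrichment(st$inp$snps, fun_el, cand_el, pt),
      crhub_error = function(e) NA_real_
    )
    dplyr::mutate(res, p_thresh = pt, relative_fold = fold, .before = 1)
  })
  readr::write_tsv(snp_enr, file.path(outdir, "enrich", "snp_enrichment.tsv"),
                   progress = FALSE)
  gs <- st$inp$gene_stats
  # small gene sets can separate perfectly; record an empty fit then
  logit_td <- tryCatch(tidy(logistic_fit(gs)), crhub_error = function(e) {
    rlang::warn(sprintf("logistic fit skipped: %s", conditionMessage(e)))
    tibble(term = character(), estimate = double(), std_error = double(),
           statistic = double(), p_value = double(), odds_ratio = double(),
           ci_low = double(), ci_high = double())
  })
  readr::write_tsv(logit_td, file.path(outdir, "enrich", "logistic.tsv"),
                   progress = FALSE)
  icc <- icc_fit(dplyr::filter(gs, .data$in_crh), rna_level, hub_id)
  strata <- stratify_crhs(st$crhs)
  readr::write_tsv(strata, file.path(outdir, "enrich", "strata.tsv"),
                   progress = FALSE)
  ldsc <- prepare_ldsc_annotation(fun_el, st$inp$snps,
                                  extend = config$ldsc_extend)
  write_thin_annot(ldsc$annot, file.path(outdir, "enrich", "crh.annot.tsv"))
  census <- associated_gene_census(
    gs |>
      dplyr::filter(.data$in_crh) |>
      dplyr::group_by(.data$hub_id) |>
      dplyr::summarise(n = sum(.data$scz_associated)) |>
      dplyr::pull("n")
  )
  jsonlite::write_json(
    list(icc = tidy(icc), gene_census = census),
    file.path(outdir, "enrich", "enrich_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_manifest(outdir, "enrich",
                 params = list(p_thresholds = config$snp_p_thresholds,
                               ldsc_extend = config$ldsc_extend),
                 inputs = file.path(outdir, "abc", "pairs.tsv"),
                 outputs = list.files(file.path(outdir, "enrich"),
                                      full.names = TRUE), t0 = t0)
}

stage_deglink <- function(config, outdir, t0) {
  st <- rebuild_crhs(config, outdir)
  dir.create(file.path(outdir, "deglink"), showWarnings = FALSE)
  fun_el <- functional_elements(st$pairs)
  structures <- dplyr::bind_rows(
    crh_structures(st$crhs),
    pair_structures(st$pairs),
    tad_structures(st$inp$annotations$tads, st$inp$genes, fun_el)
  )
  structures <- assign_structure_snps(structures, st$inp$snps,
                                      promoters = st$inp$promoters)
  deg_genes <- st$inp$gene_stats$gene_id[st$inp$gene_stats$deg]
  props <- suppressWarnings(deg_proportions(structures, deg_genes))
  readr::write_tsv(props$per_structure,
                   file.path(outdir, "deglink", "structures.tsv"),
                   progress = FALSE)
  readr::write_tsv(props$summary,
                   file.path(outdir, "deglink", "summary.tsv"),
                   progress = FALSE)
  enr <- deg_crh_enrichment(st$inp$gene_stats)
  jsonlite::write_json(
    list(summary = props$summary, tests = props$tests,
         deg_enrichment = tidy(enr)),
    file.path(outdir, "deglink", "deglink_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  write_manifest(outdir, "deglink", params = list(),
                 inputs = file.path(outdir, "abc", "pairs.tsv"),
                 outputs = list.files(file.path(outdir, "deglink"),
                                      full.names = TRUE), t0 = t0)
}

stage_report <- function(config, outdir, t0) {
  st <- rebuild_crhs(config, outdir)
  report <- list(
    crh = glance(st$crhs),
    roles = role_census(st$crhs),
    compartments = readr::read_tsv(
      file.path(outdir, "overlap", "compartment_distribution.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    snp_enrichment = readr::read_tsv(
      file.path(outdir, "enrich", "snp_enrichment.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    deglink = readr::read_tsv(
      file.path(outdir, "deglink", "summary.tsv"),
      show_col_types = FALSE, progress = FALSE
    )
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(outdir, "report", params = list(),
                 inputs = character(0),
                 outputs = file.path(outdir, "report.json"), t0 = t0)
}
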