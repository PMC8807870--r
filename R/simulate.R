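#' Configuration for the synthetic regulatory fixture
#'
#' Assembles and validates the parameters of the seeded generator. The
#' genome is tiled into loci of `locus_size` bp whose content is confined to
#' the central `content_span` bp; loci alternate between planted hubs,
#' candidate-promoter loci and candidate-element loci, and background
#' contacts are only sampled within `background_range` of the diagonal, so
#' planted hubs are separated by construction (no cross-locus contact can
#' exist). See the methods vignette for the rationale behind each default.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_chrom,chrom_length,bin_size Genome shape (default 2 chromosomes
#'   of 20 Mb at 10-kb bins).
#' @param n_genes,n_elements Total genes and DNAse peaks.
#' @param planted_hubs List of `c(n_promoters, n_distal)` hub shapes.
#' @param contact_decay_alpha,baseline_rate Background contact model:
#'   `count ~ Poisson(baseline_rate * (d_bins + 1)^-alpha)`.
#' @param hub_boost Target activity-by-contact numerator for designated hub
#'   edges; the contact boost per edge is `ceiling(hub_boost / activity)`.
#' @param frac_active_elements Fraction of peaks carrying H3K27ac signal;
#'   `NULL` (default) activates exactly the planted hub elements.
#' @param background_range Maximum genomic distance (bp) at which background
#'   contacts are sampled.
#' @param locus_size,content_span Locus tiling geometry (bp).
#' @param snp_density SNPs per bp (clumped-index SNPs).
#' @param planted_risk_elements Fraction of hub distal elements planted as
#'   risk elements.
#' @param risk_effect Multiplier on the significant-SNP fraction inside risk
#'   elements, at reference threshold `snp_p_thresh`.
#' @param snp_p_thresh Reference significance threshold for the planted
#'   enrichment.
#' @param deg_rate_in_crh,deg_rate_out DEG label rates for hub and non-hub
#'   genes.
#' @param icc_true Intraclass correlation of expression within hubs.
#' @param logistic_betas Named vector (`intercept`, `rna_level`,
#'   `n_connections`, `active_distal`, `monogamous`) generating gene disease
#'   status.
#' @param expr_grand_mean,expr_sigma_within Expression model (log scale).
#' @param promoter_width,abc_threshold Downstream analysis defaults carried
#'   with the fixture.
#' @return A validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1,
                           n_chrom = 2,
                           chrom_length = 2e7,
                           bin_size = 1e4,
                           n_genes = 300,
                           n_elements = 1500,
                           planted_hubs = default_hub_shapes(),
                           contact_decay_alpha = 1,
                           baseline_rate = 0.5,
                           hub_boost = 100,
                           frac_active_elements = NULL,
                           background_range = 3e5,
                           locus_size = 5e5,
                           content_span = 1e5,
                           snp_density = 2e-4,
                           planted_risk_elements = 0.25,
                           risk_effect = 3,
                           snp_p_thresh = 0.01,
                           deg_rate_in_crh = 0.35,
                           deg_rate_out = 0.08,
                           icc_true = 0.25,
                           logistic_betas = c(intercept = -1.8,
                                              rna_level = 0.6,
                                              n_connections = -0.15,
                                              active_distal = 0.8,
                                              monogamous = 0.5),
                           expr_grand_mean = 6,
                           expr_sigma_within = 1,
                           promoter_width = 500,
                           abc_threshold = 0.012) {
  cfg <- as.list(environment())
  shapes <- do.call(rbind, planted_hubs)
  if (any(shapes < 1)) stop_crhub("hub shapes must be positive")
  if (any(shapes[, 2] < shapes[, 1] - 1)) {
    stop_crhub("hub needs at least n_promoters - 1 distal elements to connect",
               "crhub_validation_error")
  }
  n_hub_prom <- sum(shapes[, 1])
  n_hub_dist <- sum(shapes[, 2])
  n_loci_per_chrom <- floor(chrom_length / locus_size)
  n_hub_loci <- n_chrom * ceiling(n_loci_per_chrom / 2)
  if (length(planted_hubs) > n_hub_loci) {
    stop_crhub(sprintf(
      "too many hubs (%d) for the genome (%d hub loci available)",
      length(planted_hubs), n_hub_loci
    ), "crhub_validation_error")
  }
  if (n_hub_prom > n_genes) {
    stop_crhub("planted hubs require more promoters than n_genes",
               "crhub_validation_error")
  }
  if (n_hub_dist > n_elements) {
    stop_crhub("planted hubs require more elements than n_elements",
               "crhub_validation_error")
  }
  for (fr in c("planted_risk_elements", "deg_rate_in_crh", "deg_rate_out",
               "icc_true")) {
    if (cfg[[fr]] < 0 || cfg[[fr]] >= 1) {
      stop_crhub(sprintf("`%s` must lie in [0, 1)", fr),
                 "crhub_validation_error")
    }
  }
  if (is.null(cfg$frac_active_elements)) {
    cfg$frac_active_elements <- n_hub_dist / n_elements
  }
  cfg$n_hub_promoters <- n_hub_prom
  cfg$n_hub_distal <- n_hub_dist
  structure(cfg, class = "fixture_config")
}

#' @rdname fixture_config
#' @export
default_hub_shapes <- function() {
  c(
    rep(list(c(1L, 1L)), 12),
    rep(list(c(1L, 3L)), 10),
    rep(list(c(2L, 5L)), 10),
    rep(list(c(3L, 8L)), 6),
    rep(list(c(5L, 15L)), 2)
  )
}

# Locus table: one row per locus with its type and content window.
locus_table <- function(config) {
  per_chrom <- floor(config$chrom_length / config$locus_size)
  loci <- tidyr::expand_grid(
    chrom = paste0("chr", seq_len(config$n_chrom)),
    locus = seq_len(per_chrom) - 1L
  ) |>
    dplyr::mutate(
      start = .data$locus * config$locus_size,
      content_start = .data$start +
        (config$locus_size - config$content_span) / 2,
      content_end = .data$content_start + config$content_span
    )
  n_hubs <- length(config$planted_hubs)
  # even loci host hubs; odd loci alternate promoter / element deserts
  loci$type <- ifelse(loci$locus %% 2 == 0, "hub",
                      ifelse((loci$locus %/% 2) %% 2 == 0,
                             "promoter_desert", "element_desert"))
  hub_rows <- which(loci$type == "hub")
  if (length(hub_rows) > n_hubs) {
    loci$type[utils::tail(hub_rows, length(hub_rows) - n_hubs)] <- "spacer"
  }
  loci$hub_id <- NA_character_
  loci$hub_id[which(loci$type == "hub")] <-
    sprintf("HUB_%03d", seq_len(n_hubs))
  loci
}

#' Generate the synthetic regulatory landscape
#'
#' Places genes, promoter windows and DNAse peaks with lognormal signals on
#' the locus tiling, and emits compartment (alternating 2-Mb A/B blocks),
#' TAD (1-Mb tiling), FIRE and 18-state chromatin-state annotations.
#' Deterministic given `config$seed`.
#'
#' @param config A `fixture_config`.
#' @return List with tibbles `genes`, `promoters`, `elements`, and
#'   `annotations` (list of `compartments`, `tads`, `fires`, `states`), plus
#'   `truth` (hub membership and designated edges).
#' @export
generate_regulatory_landscape <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  loci <- locus_table(config)
  hub_loci <- dplyr::filter(loci, .data$type == "hub")
  shapes <- config$planted_hubs

  rpos <- function(n, lo, hi) sort(round(runif(n, lo, hi - 1)))

  # --- hub genes and elements ---------------------------------------------
  hub_content <- purrr::map_dfr(seq_len(nrow(hub_loci)), function(h) {
    sh <- shapes[[h]]
    lc <- hub_loci[h, ]
    tibble(
      hub_id = lc$hub_id, chrom = lc$chrom,
      what = c(rep("gene", sh[1]), rep("element", sh[2])),
      pos = round(runif(sh[1] + sh[2], lc$content_start, lc$content_end - 1))
    )
  })

  n_cand_genes <- config$n_genes - config$n_hub_promoters
  prom_loci <- dplyr::filter(loci, .data$type == "promoter_desert")
  cand_gene_locus <- rep(seq_len(nrow(prom_loci)),
                         length.out = n_cand_genes)
  cand_genes <- tibble(
    hub_id = NA_character_,
    chrom = prom_loci$chrom[cand_gene_locus],
    what = "gene",
    pos = round(runif(
      n_cand_genes,
      prom_loci$content_start[cand_gene_locus],
      prom_loci$content_end[cand_gene_locus] - 1
    ))
  )

  n_cand_el <- config$n_elements - config$n_hub_distal
  el_loci <- dplyr::filter(loci, .data$type == "element_desert")
  cand_el_locus <- rep(seq_len(nrow(el_loci)), length.out = n_cand_el)
  cand_els <- tibble(
    hub_id = NA_character_,
    chrom = el_loci$chrom[cand_el_locus],
    what = "element",
    pos = round(runif(
      n_cand_el,
      el_loci$content_start[cand_el_locus],
      el_loci$content_end[cand_el_locus] - 1
    ))
  )

  gene_rows <- dplyr::bind_rows(
    dplyr::filter(hub_content, .data$what == "gene"), cand_genes
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  genes <- tibble(
    gene_id = sprintf("G%04d", seq_len(nrow(gene_rows))),
    chrom = gene_rows$chrom,
    strand = sample(c("+", "-"), nrow(gene_rows), replace = TRUE),
    tss = gene_rows$pos,
    hub_id = gene_rows$hub_id
  )

  el_rows <- dplyr::bind_rows(
    dplyr::filter(hub_content, .data$what == "element"), cand_els
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  widths <- round(runif(nrow(el_rows), 200, 1000))
  n_active <- round(config$frac_active_elements * nrow(el_rows))
  # activate planted hub elements first, then desert elements
  act_order <- order(is.na(el_rows$hub_id))
  active <- logical(nrow(el_rows))
  active[act_order[seq_len(n_active)]] <- TRUE
  elements <- tibble(
    element_id = sprintf("E%04d", seq_len(nrow(el_rows))),
    chrom = el_rows$chrom,
    start = pmax(0, el_rows$pos - widths %/% 2),
    end = el_rows$pos + (widths - widths %/% 2),
    dnase_signal = rlnorm(nrow(el_rows), meanlog = 1, sdlog = 0.5),
    h3k27ac_signal = ifelse(
      active, rlnorm(nrow(el_rows), meanlog = 1, sdlog = 0.5), 0
    ),
    hub_id = el_rows$hub_id
  ) |>
    dplyr::mutate(
      activity = compute_activity(.data$dnase_signal, .data$h3k27ac_signal),
      element_class = ifelse(.data$activity > 0, "active", "candidate")
    )

  # --- designated hub edges (connected bipartite graphs) ------------------
  truth_edges <- purrr::map_dfr(unique(stats::na.omit(genes$hub_id)), function(h) {
    gs <- genes$gene_id[which(genes$hub_id == h)]
    es <- elements$element_id[which(elements$hub_id == h)]
    # star on the first promoter plus one bridging edge per extra promoter
    e1 <- tibble(hub_id = h, gene_id = gs[1], element_id = es)
    if (length(gs) > 1) {
      e2 <- tibble(hub_id = h, gene_id = gs[-1],
                   element_id = es[seq_len(length(gs) - 1)])
      e1 <- dplyr::bind_rows(e1, e2)
    }
    e1
  })

  truth_nodes <- dplyr::bind_rows(
    genes |>
      dplyr::filter(!is.na(.data$hub_id)) |>
      dplyr::transmute(node_id = .data$gene_id, node_class = "promoter",
                       hub_id = .data$hub_id),
    elements |>
      dplyr::filter(!is.na(.data$hub_id)) |>
      dplyr::transmute(node_id = .data$element_id, node_class = "distal",
                       hub_id = .data$hub_id)
  )

  # --- structural annotations ---------------------------------------------
  chroms <- paste0("chr", seq_len(config$n_chrom))
  compartments <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0, config$chrom_length - 1, by = 2e6)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + 2e6, config$chrom_length),
           label = rep(c("A", "B"), length.out = length(starts)))
  })
  tads <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0, config$chrom_length - 1, by = 1e6)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + 1e6, config$chrom_length))
  })
  tads$id <- sprintf("TAD_%04d", seq_len(nrow(tads)))
  fire_loci <- dplyr::bind_rows(
    dplyr::slice_sample(dplyr::filter(loci, .data$type == "hub"),
                        prop = 0.5),
    dplyr::slice_sample(dplyr::filter(loci, .data$type == "element_desert"),
                        prop = 0.2)
  )
  fires <- tibble(chrom = fire_loci$chrom,
                  start = fire_loci$content_start,
                  end = fire_loci$content_end) |>
    dplyr::arrange(.data$chrom, .data$start)
  fires$id <- sprintf("FIRE_%03d", seq_len(nrow(fires)))

  vocab <- chromatin_state_grouping()
  active_states <- vocab$state[vocab$group == "Active"]
  state_block <- 25000
  states <- purrr::map_dfr(chroms, function(ch) {
    starts <- seq(0, config$chrom_length - 1, by = state_block)
    tibble(chrom = ch, start = starts,
           end = pmin(starts + state_block, config$chrom_length))
  })
  in_hub_locus <- states$start %/% config$locus_size %% 2 == 0
  states$label <- ifelse(
    in_hub_locus,
    sample(vocab$state, nrow(states), replace = TRUE,
           prob = ifelse(vocab$state %in% active_states, 4, 1))[seq_len(nrow(states))],
    sample(vocab$state, nrow(states), replace = TRUE,
           prob = ifelse(vocab$group == "InactiveRepressor", 6, 1))[seq_len(nrow(states))]
  )

  list(
    genes = genes,
    promoters = make_promoters(genes, config$promoter_width),
    elements = elements,
    annotations = list(compartments = compartments, tads = tads,
                       fires = fires, states = states),
    truth = list(nodes = truth_nodes, edges = truth_edges)
  )
}

#' Generate synthetic contact matrices with planted hub contacts
#'
#' Background counts follow `Poisson(baseline_rate * (d + 1)^-alpha)` in bin
#' distance `d`, sampled only within `background_range` of the diagonal.
#' Each designated hub edge receives an additive contact boost of
#' `ceiling(hub_boost / activity)` so its activity-by-contact numerator is at
#' least `hub_boost`, which keeps every designated edge above the score
#' threshold while structural separation keeps cross-hub scores at zero. A
#' dry-run ABC computation verifies the separation and errors if the boost
#' is insufficient.
#'
#' @param config A `fixture_config`.
#' @param landscape Output of [generate_regulatory_landscape()].
#' @return Named list of `contact_matrix`, one per chromosome.
#' @export
generate_contacts <- function(config, landscape) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed + 1L)
  n_bins <- floor(config$chrom_length / config$bin_size)
  max_d <- floor(config$background_range / config$bin_size)
  chroms <- paste0("chr", seq_len(config$n_chrom))

  mats <- purrr::map(chroms, function(ch) {
    bg <- purrr::map_dfr(0:max_d, function(d) {
      lambda <- config$baseline_rate * (d + 1)^(-config$contact_decay_alpha)
      i <- 0:(n_bins - 1 - d)
      cnt <- rpois(length(i), lambda)
      keep <- cnt > 0
      tibble(bin_i = i[keep], bin_j = i[keep] + d, count = cnt[keep])
    })
    ed <- landscape$truth$edges
    ge <- dplyr::left_join(ed, landscape$genes[, c("gene_id", "chrom", "tss")],
                           by = "gene_id") |>
      dplyr::left_join(
        landscape$elements[, c("element_id", "start", "end", "activity")],
        by = "element_id"
      ) |>
      dplyr::filter(.data$chrom == ch)
    boost <- tibble(
      bin_i = floor(ge$tss / config$bin_size),
      bin_j = floor(interval_midpoint(ge$start, ge$end) / config$bin_size),
      count = ifelse(ge$activity > 0,
                     ceiling(config$hub_boost / pmax(ge$activity, 1e-12)), 0)
    ) |>
      dplyr::filter(.data$count > 0)
    contact_matrix(dplyr::bind_rows(bg, boost), chrom = ch,
                   bin_size = config$bin_size,
                   chrom_length = config$chrom_length)
  })
  names(mats) <- chroms

  # dry-run separation check (only meaningful when all hub elements active)
  hub_el <- dplyr::filter(landscape$elements, !is.na(.data$hub_id))
  if (nrow(hub_el) > 0 && all(hub_el$activity > 0)) {
    pairs <- suppressWarnings(compute_abc_scores(
      landscape$elements, landscape$promoters, mats
    ))
    fun <- functional_pairs(threshold_pairs(pairs, config$abc_threshold))
    truth_keys <- paste(landscape$truth$edges$gene_id,
                        landscape$truth$edges$element_id)
    missing <- setdiff(truth_keys, paste(fun$gene_id, fun$element_id))
    hub_of_gene <- landscape$genes$hub_id[match(fun$gene_id,
                                                landscape$genes$gene_id)]
    hub_of_el <- landscape$elements$hub_id[match(fun$element_id,
                                                 landscape$elements$element_id)]
    crossing <- sum(is.na(hub_of_gene) | is.na(hub_of_el) |
                      hub_of_gene != hub_of_el)
    if (length(missing) > 0 || crossing > 0) {
      stop_crhub(sprintf(
        paste("planted separation failed: %d designated edge(s) below the",
              "threshold and %d stray functional pair(s); increase",
              "`hub_boost` or lower `abc_threshold`"),
        length(missing), crossing
      ), "crhub_separation_error")
    }
  }
  mats
}

#' Generate synthetic phenotypes: SNPs, gene features, expression, DEGs
#'
#' SNP p-values are Uniform(0,1) outside planted risk elements and
#' `Beta(a, 1)` inside them, with `a` chosen so the significant fraction at
#' the reference threshold is `risk_effect` times the baseline. Gene disease
#' status is drawn from a logistic model on the gene covariates with the
#' configured coefficients, then gene-level association p-values are drawn
#' consistently (tiny for associated genes, uniform otherwise) so that
#' Benjamini-Hochberg selection at 0.05 recovers the planted flags.
#' Expression is a hub random-intercept model calibrated to `icc_true`.
#'
#' @param config A `fixture_config`.
#' @param landscape Output of [generate_regulatory_landscape()].
#' @return List with `snps`, `genes` (per-gene stats), `risk_elements`
#'   (element ids).
#' @export
generate_phenotypes <- function(config, landscape) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed + 2L)
  chroms <- paste0("chr", seq_len(config$n_chrom))

  # --- SNPs ----------------------------------------------------------------
  n_per_chrom <- round(config$snp_density * config$chrom_length)
  snps <- purrr::map_dfr(chroms, function(ch) {
    tibble(chrom = ch,
           pos = sort(sample.int(config$chrom_length, n_per_chrom)) - 1L)
  })
  snps$snp_id <- sprintf("rs%06d", seq_len(nrow(snps)))
  snps$is_clumped_index <- TRUE

  hub_el <- dplyr::filter(landscape$elements, !is.na(.data$hub_id))
  n_risk <- round(config$planted_risk_elements * nrow(hub_el))
  risk_ids <- if (n_risk > 0) {
    sample(hub_el$element_id, n_risk)
  } else character(0)
  risk_iv <- dplyr::filter(landscape$elements, .data$element_id %in% risk_ids)

  in_risk <- snps_in_intervals(snps, risk_iv)
  a_shape <- 1 + log(config$risk_effect) / log(config$snp_p_thresh)
  if (a_shape <= 0) {
    stop_crhub("risk_effect too large for the reference threshold",
               "crhub_validation_error")
  }
  snps$pvalue <- runif(nrow(snps))
  if (any(in_risk)) {
    snps$pvalue[in_risk] <- rbeta(sum(in_risk), a_shape, 1)
  }
  snps <- snps[, c("snp_id", "chrom", "pos", "pvalue", "is_clumped_index")]

  # --- gene features -------------------------------------------------------
  genes <- landscape$genes
  edges <- landscape$truth$edges
  deg_tab <- table(edges$gene_id)
  genes$n_connections <- as.integer(deg_tab[genes$gene_id])
  genes$n_connections[is.na(genes$n_connections)] <- 0L
  genes$in_crh <- !is.na(genes$hub_id)
  hub_n_nodes <- dplyr::bind_rows(
    dplyr::distinct(edges, .data$hub_id, node = .data$gene_id),
    dplyr::distinct(edges, .data$hub_id, node = .data$element_id)
  ) |>
    dplyr::distinct() |>
    dplyr::count(.data$hub_id, name = "n_nodes")
  genes$monogamous <- genes$in_crh &
    hub_n_nodes$n_nodes[match(genes$hub_id, hub_n_nodes$hub_id)] == 2
  genes$monogamous[is.na(genes$monogamous)] <- FALSE
  genes$prop_active_distal <- rbeta(nrow(genes), 2, 2)

  # expression: hub random intercept sized to the target ICC
  s2w <- config$expr_sigma_within^2
  s2b <- if (config$icc_true > 0) {
    config$icc_true / (1 - config$icc_true) * s2w
  } else 0
  hub_ids <- unique(stats::na.omit(genes$hub_id))
  b_hub <- setNames(rnorm(length(hub_ids), 0, sqrt(s2b)), hub_ids)
  genes$rna_level <- config$expr_grand_mean +
    ifelse(genes$in_crh, b_hub[genes$hub_id], 0) +
    rnorm(nrow(genes), 0, sqrt(s2w))

  # disease status from the logistic model
  bb <- config$logistic_betas
  p90 <- quantile(genes$prop_active_distal, 0.9, type = 1)
  lin <- bb[["intercept"]] +
    bb[["rna_level"]] * (genes$rna_level - config$expr_grand_mean) +
    bb[["n_connections"]] * genes$n_connections +
    bb[["active_distal"]] * (genes$prop_active_distal > p90) +
    bb[["monogamous"]] * genes$monogamous
  assoc <- rbinom(nrow(genes), 1, plogis(lin)) == 1
  genes$assoc_pvalue <- ifelse(assoc, runif(nrow(genes), 0, 1e-8),
                               runif(nrow(genes)))
  genes$scz_associated <- bh_select(genes$assoc_pvalue, 0.05)

  genes$deg <- rbinom(nrow(genes), 1, ifelse(
    genes$in_crh, config$deg_rate_in_crh, config$deg_rate_out
  )) == 1

  list(snps = snps, genes = genes, risk_elements = risk_ids)
}

#' Simulate a complete hub analysis fixture
#'
#' Runs [generate_regulatory_landscape()], [generate_contacts()] and
#' [generate_phenotypes()] under one seed.
#'
#' @param config A `fixture_config` (or arguments forwarded to one).
#' @return List `config`, `landscape`, `contacts`, `phenotypes`.
#' @export
simulate_crh_dataset <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  landscape <- generate_regulatory_landscape(config)
  contacts <- generate_contacts(config, landscape)
  phenotypes <- generate_phenotypes(config, landscape)
  list(config = config, landscape = landscape, contacts = contacts,
       phenotypes = phenotypes)
}

#' Write a simulated fixture to disk in pipeline formats
#'
#' Emits exactly the formats the analysis consumes: gene table TSV, DNAse
#' narrowPeak, H3K27ac bedGraph, annotation BEDs, contact TSVs with JSON
#' sidecars, SNP TSV, gene-stats TSV and a `truth.json` with the planted hub
#' membership, designated edges and risk elements.
#'
#' @param sim Output of [simulate_crh_dataset()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ls <- sim$landscape
  readr::write_tsv(ls$genes[, c("gene_id", "chrom", "strand", "tss")],
                   file.path(dir, "genes.tsv"), progress = FALSE)
  el <- ls$elements
  write_intervals(
    tibble(chrom = el$chrom, start = el$start, end = el$end,
           id = el$element_id, score = 0, strand = ".",
           signal = el$dnase_signal),
    file.path(dir, "dnase.narrowPeak"), format = "narrowPeak"
  )
  write_intervals(
    tibble(chrom = el$chrom, start = el$start, end = el$end,
           signal = el$h3k27ac_signal),
    file.path(dir, "h3k27ac.bedGraph"), format = "bedGraph"
  )
  ann <- ls$annotations
  for (nm in names(ann)) {
    df <- ann[[nm]]
    out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                  id = df[["label"]] %||% df[["id"]] %||% ".")
    write_intervals(out, file.path(dir, paste0(nm, ".bed")), format = "bed")
  }
  for (ch in names(sim$contacts)) {
    write_contacts(sim$contacts[[ch]],
                   file.path(dir, paste0("contacts_", ch, ".tsv")))
  }
  write_snps(sim$phenotypes$snps, file.path(dir, "snps.tsv"))
  readr::write_tsv(sim$phenotypes$genes, file.path(dir, "gene_stats.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(
      nodes = ls$truth$nodes,
      edges = ls$truth$edges,
      risk_elements = sim$phenotypes$risk_elements,
      config = unclass(sim$config)[setdiff(names(sim$config),
                                           c("planted_hubs"))],
      hub_shapes = purrr::map(sim$config$planted_hubs, identity)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(dir)
}
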