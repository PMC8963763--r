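# Orchestration: discovery (array -> BW -> DMR -> marker panel) and
# validation (MSP -> association -> survival) from a single configuration.

#' Build and validate a pipeline run configuration
#'
#' A single configuration drives both pipeline phases. Each phase takes
#' either simulated inputs (an [array_sim_config()] / [cohort_sim_config()]
#' plus promoter `gene_specs`) or file paths to the corresponding on-disk
#' tables. All thresholds of the cascade are settable here and default to
#' the values used throughout the package.
#'
#' @param array Optional [array_sim_config()] for a simulated discovery
#'   cohort.
#' @param intensities_path,annotation_path,labels_path Paths to a
#'   long-form intensity TSV, BED-like region annotation and sample-label
#'   TSV (alternative to `array`).
#' @param promoter_specs Optional tibble for [simulate_promoters()].
#' @param fasta_path Optional promoter FASTA (alternative to
#'   `promoter_specs`).
#' @param cohort Optional [cohort_sim_config()] for a simulated validation
#'   cohort.
#' @param msp_path,clinical_path CSV paths (alternative to `cohort`).
#' @param alpha Probe-level significance level, in (0, 1).
#' @param variant t-test variant (`"student"`/`"welch"`).
#' @param formula BW formula (`"literal_quotient"`/`"log_ratio"`).
#' @param md_threshold Strict MD cutoff (default 1.4).
#' @param island_min_length,island_gc_min,island_oe_min CpG-island
#'   thresholds.
#' @param min_density CpG-density gate in percent (default 60).
#' @param k Marker panel size (default 3).
#' @param endpoints Survival endpoints to analyse.
#' @param mc_replicates Optional Monte-Carlo replicates for association
#'   tests.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory for reports and artifacts.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(array = NULL,
                       intensities_path = NULL, annotation_path = NULL,
                       labels_path = NULL,
                       promoter_specs = NULL, fasta_path = NULL,
                       cohort = NULL, msp_path = NULL, clinical_path = NULL,
                       alpha = 0.01, variant = "student",
                       formula = "literal_quotient",
                       md_threshold = 1.4,
                       island_min_length = 500L, island_gc_min = 0.5,
                       island_oe_min = 0.6,
                       min_density = 60, k = 3L,
                       endpoints = c("os", "pfs"),
                       mc_replicates = NULL,
                       seed = 1L, out_dir = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1",
          class = "methcascade_config_error")
  }
  if (md_threshold <= 0) {
    abort("`md_threshold` must be > 0", class = "methcascade_config_error")
  }
  if (min_density < 0 || min_density > 100) {
    abort("`min_density` must be a percentage in [0, 100]",
          class = "methcascade_config_error")
  }
  variant <- match.arg(variant, c("student", "welch"))
  formula <- match.arg(formula, c("literal_quotient", "log_ratio"))
  for (p in c(intensities_path, annotation_path, labels_path, fasta_path,
              msp_path, clinical_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("file not found: ", p), class = "methcascade_config_error")
    }
  }
  if (!is.null(array) && !inherits(array, "array_sim_config")) {
    array <- do.call(array_sim_config, array)
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_sim_config")) {
    cohort <- do.call(cohort_sim_config, cohort)
  }
  structure(
    list(array = array, intensities_path = intensities_path,
         annotation_path = annotation_path, labels_path = labels_path,
         promoter_specs = promoter_specs, fasta_path = fasta_path,
         cohort = cohort, msp_path = msp_path, clinical_path = clinical_path,
         alpha = alpha, variant = variant, formula = formula,
         md_threshold = md_threshold,
         island_min_length = island_min_length,
         island_gc_min = island_gc_min, island_oe_min = island_oe_min,
         min_density = min_density, k = k,
         endpoints = match.arg(endpoints, c("os", "pfs"), several.ok = TRUE),
         mc_replicates = mc_replicates,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments
#'   (`array` and `cohort` may be nested maps of simulator parameters;
#'   `promoter_specs` a list of per-gene maps).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path),
          class = "methcascade_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$promoter_specs)) {
    raw$promoter_specs <- dplyr::bind_rows(raw$promoter_specs)
  }
  do.call(run_config, raw)
}

#' Bundled demonstration configuration for the discovery cascade
#'
#' A self-contained discovery run on simulated data: a 2,000-region array
#' (12 CR vs 10 TR) with five planted single-direction marker genes whose
#' methylated-channel shift is large enough to clear the MD cutoff, of
#' which exactly three carry island-rich promoters (planted island 1,400 bp
#' at 60% GC, CpG density about 70%) while the other two carry islands too
#' short to pass the 60% density gate. Running [run_discovery()] on this
#' configuration therefore returns precisely the three island-rich planted
#' genes as the marker panel.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory.
#' @return A [run_config()].
#' @export
#' @examples
#' \donttest{
#' report <- run_discovery(demo_discovery_config(seed = 1))
#' report$marker_panel
#' }
demo_discovery_config <- function(seed = 1L, out_dir = NULL) {
  acfg <- array_sim_config(
    n_regions = 2000L, probes_per_region = 2L,
    frac_hyper = 0, frac_hypo = 5 / 2000,
    effect_size = 7, noise_sd = 0.5, seed = seed
  )
  truth <- simulate_methylation_array(acfg)$truth
  planted <- truth$gene[truth$direction == "hypo"]
  specs <- tibble::tibble(
    gene = planted,
    island_length = c(1400L, 1400L, 1400L, 800L, 800L),
    island_gc = 0.6,
    flank_gc = 0.2
  )
  run_config(array = acfg, promoter_specs = specs, seed = seed,
             out_dir = out_dir)
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

provenance <- function(config) {
  list(config_hash = config_hash(config),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("methcascade")))
}

stage_log <- function(...) inform(paste0("[methcascade] ", ...))

#' Run the discovery phase
#'
#' Chains the full discovery cascade: intensity data (simulated or read
#' from disk) -> BW matrix -> per-probe differential calls -> region
#' summary -> direction-consistent genes -> gene-level medians and MD ->
#' MD threshold -> promoter CpG-island densities -> marker panel; plus
#' Z-scoring of significant probes and sample clustering. Per-stage record
#' counts are logged so the selection funnel is inspectable. Given the same
#' configuration (including seed), the report is identical run-to-run.
#'
#' @param config A [run_config()] with discovery inputs.
#' @return A list of class `meth_run_report` with elements `phase`,
#'   `dmr_summary`, `gene_summaries`, `candidates`, `marker_panel`,
#'   `densities`, `clustering` (rand index + leaf order), `funnel`, and
#'   `provenance`. Written as JSON (plus TSV artifacts) when
#'   `config$out_dir` is set.
#' @export
run_discovery <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$array)) {
    sim <- simulate_methylation_array(config$array)
    ints <- annotate_intensities(sim$intensities, sim$regions)
    labels <- sim$labels
    truth <- sim$truth
  } else {
    if (is.null(config$intensities_path) || is.null(config$annotation_path) ||
        is.null(config$labels_path)) {
      abort("discovery needs either `array` or intensity/annotation/label paths",
            class = "methcascade_config_error")
    }
    ints <- read_intensity_table(config$intensities_path,
                                 config$annotation_path)
    labels <- readr::read_tsv(config$labels_path, show_col_types = FALSE)
    truth <- NULL
  }

  bw <- compute_bw_matrix(ints, config$formula)
  stage_log("BW matrix: ", dplyr::n_distinct(bw$probe_id), " probes x ",
            dplyr::n_distinct(bw$sample_id), " samples (", config$formula, ")")

  dmrs <- call_dmrs(bw, labels, alpha = config$alpha,
                    variant = config$variant)
  dmr_summary <- summarize_dmrs(dmrs)
  stage_log("significant probes at alpha=", config$alpha, ": ",
            dmr_summary$n_sig_probes, " (",
            dmr_summary$n_unique_regions, " unique regions)")

  gene_summaries <- gene_group_medians(bw, labels, dmrs)
  candidates <- select_md_candidates(gene_summaries, config$md_threshold)
  stage_log("direction-consistent genes: ", sum(gene_summaries$consistent),
            "; MD > ", config$md_threshold, ": ", nrow(candidates))

  if (!is.null(config$promoter_specs)) {
    prom <- simulate_promoters(config$promoter_specs,
                               seed = config$seed + 1000003L)
    promoters <- prom$sequences
  } else if (!is.null(config$fasta_path)) {
    promoters <- read_promoter_fasta(config$fasta_path)
  } else {
    abort("discovery needs either `promoter_specs` or `fasta_path`",
          class = "methcascade_config_error")
  }
  scan <- scan_promoters(promoters,
                         min_length = config$island_min_length,
                         gc_min = config$island_gc_min,
                         oe_min = config$island_oe_min)
  panel <- prioritize_by_cpg_density(candidates, scan$densities,
                                     min_density = config$min_density,
                                     k = config$k)
  stage_log("marker panel (density > ", config$min_density, "%, top ",
            config$k, "): ", paste(panel$gene, collapse = ", "))

  clustering_info <- NULL
  if (nrow(dmrs) >= 2) {
    z <- zscore_transform(dplyr::semi_join(bw, dmrs, by = "probe_id"))
    cl <- cluster_samples(z, labels)
    clustering_info <- list(rand_index = cl$rand_index,
                            leaf_order = cl$leaf_order)
  }

  report <- structure(
    list(
      phase = "discovery",
      dmr_summary = dmr_summary,
      gene_summaries = gene_summaries,
      candidates = candidates,
      marker_panel = panel,
      densities = scan$densities,
      clustering = clustering_info,
      funnel = list(
        probes_tested = dplyr::n_distinct(bw$probe_id),
        probes_significant = dmr_summary$n_sig_probes,
        unique_regions = dmr_summary$n_unique_regions,
        consistent_genes = sum(gene_summaries$consistent),
        md_candidates = nrow(candidates),
        panel_size = nrow(panel)
      ),
      truth = truth,
      provenance = provenance(config)
    ),
    class = "meth_run_report"
  )
  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir,
                     extra = list(dmrs = dmrs))
  }
  report
}

#' Run the validation phase
#'
#' For every marker gene in the MSP table: cross-tabulates methylation
#' status against response (and stage / tumour size when present), runs
#' the chi-square association test, and compares survival between the two
#' most frequent status groups per endpoint with Kaplan-Meier / log-rank.
#'
#' @param config A [run_config()] with validation inputs (`cohort` or
#'   `msp_path` + `clinical_path`).
#' @return A list of class `meth_run_report` with `associations` (tibble:
#'   gene, variable, chi2, df, p) and `survival` (tibble: gene, endpoint,
#'   groups, per-group medians, log-rank statistic and p), plus
#'   `provenance`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$cohort)) {
    sim <- simulate_msp_cohort(config$cohort)
    msp <- sim$msp
    clinical <- sim$clinical
  } else {
    if (is.null(config$msp_path) || is.null(config$clinical_path)) {
      abort("validation needs either `cohort` or msp/clinical paths",
            class = "methcascade_config_error")
    }
    cohort <- read_msp_cohort(config$msp_path, config$clinical_path)
    msp <- cohort$msp
    clinical <- cohort$clinical
  }
  genes <- sort(unique(msp$gene))
  variables <- intersect(names(clinical_variable_levels), names(clinical))
  stage_log("validation cohort: ", nrow(clinical), " samples, ",
            length(genes), " genes")

  associations <- tidyr::crossing(gene = genes, variable = variables) |>
    purrr::pmap(function(gene, variable) {
      tab <- build_contingency(msp, clinical, gene, variable)
      fit <- tryCatch(
        chi_square_test(tab, mc_replicates = config$mc_replicates,
                        seed = config$seed + 2000003L),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(gene = gene, variable = variable,
                              chi2 = NA_real_, df = NA_integer_,
                              p = NA_real_, mc_p = NA_real_))
      }
      tibble::tibble(gene = gene, variable = variable,
                     chi2 = fit$statistic, df = fit$df, p = fit$p_value,
                     mc_p = fit$mc_p_value %||% NA_real_)
    }) |>
    dplyr::bind_rows()

  survival_res <- tidyr::crossing(gene = genes,
                                  endpoint = config$endpoints) |>
    purrr::pmap(function(gene, endpoint) {
      cmp <- tryCatch(compare_survival(msp, clinical, gene, endpoint),
                      error = function(e) NULL)
      if (is.null(cmp)) {
        return(tibble::tibble(gene = gene, endpoint = endpoint,
                              group1 = NA_character_, group2 = NA_character_,
                              median1 = NA_real_, median2 = NA_real_,
                              logrank_chi2 = NA_real_, p = NA_real_))
      }
      tibble::tibble(
        gene = gene, endpoint = endpoint,
        group1 = cmp$groups[1], group2 = cmp$groups[2],
        median1 = cmp$km[[1]]$median, median2 = cmp$km[[2]]$median,
        logrank_chi2 = cmp$logrank$statistic, p = cmp$logrank$p_value
      )
    }) |>
    dplyr::bind_rows()

  report <- structure(
    list(phase = "validation",
         associations = associations,
         survival = survival_res,
         n_samples = nrow(clinical),
         provenance = provenance(config)),
    class = "meth_run_report"
  )
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' Write a run report as JSON (plus TSV artifacts)
#'
#' The JSON report contains only fields recomputable from inputs and
#' configuration (no timestamps), so identical configurations produce
#' byte-identical reports.
#'
#' @param report A `meth_run_report`.
#' @param dir Output directory (created if missing).
#' @param extra Optional named list of additional tibbles to write as TSV.
#' @return Invisibly, the JSON path.
#' @export
write_run_report <- function(report, dir, extra = NULL) {
  stopifnot(inherits(report, "meth_run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, paste0(report$phase, "_report.json"))
  out <- report
  out$truth <- NULL
  jsonlite::write_json(strip_classes(out), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  for (nm in names(report)) {
    if (inherits(report[[nm]], "data.frame")) {
      readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")))
    }
  }
  for (nm in names(extra)) {
    readr::write_tsv(extra[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(json_path)
}

# reduce bespoke S3 classes to plain lists / data.frames for JSON output
strip_classes <- function(x) {
  if (is.data.frame(x)) {
    as.data.frame(x)
  } else if (is.list(x)) {
    lapply(x, strip_classes)
  } else {
    x
  }
}

#' @export
print.meth_run_report <- function(x, ...) {
  cat("methcascade", x$phase, "report\n")
  if (x$phase == "discovery") {
    cat("  significant probes:", x$dmr_summary$n_sig_probes,
        "in", x$dmr_summary$n_unique_regions, "regions\n")
    cat("  MD candidates:", nrow(x$candidates),
        "| marker panel:", paste(x$marker_panel$gene, collapse = ", "), "\n")
  } else {
    cat("  samples:", x$n_samples, "\n")
    sig <- x$associations[!is.na(x$associations$p) & x$associations$p < 0.05, ]
    cat("  associations with p < 0.05:", nrow(sig), "\n")
  }
  cat("  config hash:", x$provenance$config_hash, "\n")
  invisible(x)
}
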