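# The marker-selection cascade: direction-consistent genes -> gene-level
# group medians and the median difference (MD) -> MD threshold -> CpG-density
# prioritisation.

#' Genes whose significant probes all share one methylation direction
#'
#' First step of the marker cascade: candidate biomarkers must be purely
#' hyper- or purely hypomethylated; genes with probes in both directions
#' are dropped.
#'
#' @param records Probe-level tibble from [call_dmrs()].
#' @return A tibble with `gene`, `direction` and `n_probes` for the
#'   direction-consistent genes.
#' @export
filter_consistent_genes <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(gene = character(), direction = character(),
                          n_probes = integer()))
  }
  records |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_dir = dplyr::n_distinct(.data$direction),
      direction = .data$direction[1],
      n_probes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_dir == 1L) |>
    dplyr::select("gene", "direction", "n_probes")
}

#' Gene-level group medians and the median difference (MD)
#'
#' Collapses BW values to genes in two median steps: per sample, a gene's
#' value is the median of its probes' BW values; per group, the gene value
#' is the median across that group's samples. MD is the absolute difference
#' between the TR and CR group medians — the cascade's ranking score.
#'
#' When probe-level differential calls are supplied, each gene also gets a
#' `consistent` flag: `TRUE` when the gene has at least one significant
#' probe and all its significant probes share one direction.
#'
#' @param bw Long BW tibble from [compute_bw_matrix()] (gene-annotated).
#' @param labels Tibble with `sample_id`, `group`.
#' @param dmrs Optional probe-level tibble from [call_dmrs()].
#' @return A tibble with `gene`, `median_cr`, `median_tr`, `md`,
#'   `consistent` (`NA` when `dmrs` is absent) and `n_probes`.
#' @export
gene_group_medians <- function(bw, labels, dmrs = NULL) {
  bw <- tibble::as_tibble(bw)
  if (!"gene" %in% names(bw)) bw$gene <- bw$region_id
  if (any(is.na(bw$gene))) {
    abort("every probe must be annotated with a gene",
          class = "methcascade_validation_error")
  }
  labels <- check_labels(bw, labels)
  per_sample <- bw |>
    dplyr::group_by(.data$gene, .data$sample_id) |>
    dplyr::summarise(value = median(.data$bw),
                     n_probes = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(labels, by = "sample_id")
  out <- per_sample |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      median_cr = median(.data$value[.data$group == "CR"]),
      median_tr = median(.data$value[.data$group == "TR"]),
      n_probes = .data$n_probes[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(md = abs(.data$median_tr - .data$median_cr))

  if (is.null(dmrs)) {
    out$consistent <- NA
  } else {
    cons <- filter_consistent_genes(dmrs)
    out$consistent <- out$gene %in% cons$gene
  }
  dplyr::select(out, "gene", "median_cr", "median_tr", "md", "consistent",
                "n_probes")
}

#' Select marker candidates by the MD threshold
#'
#' Keeps direction-consistent genes whose median difference exceeds the
#' threshold (strictly), ranked by MD descending with ties broken by gene
#' name. Rows whose `consistent` flag is `NA` (or when the column is
#' absent) are treated as already pre-filtered for consistency.
#'
#' @param summaries Tibble from [gene_group_medians()], or any tibble with
#'   `gene` and `md` columns.
#' @param threshold Strict lower bound on MD; default 1.4.
#' @return The filtered, ranked tibble.
#' @export
#' @examples
#' select_md_candidates(tibble::tibble(gene = c("A", "B", "C"),
#'                                     md = c(1.5, 1.3, 2.0)))
select_md_candidates <- function(summaries, threshold = 1.4) {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be > 0", class = "methcascade_config_error")
  }
  summaries <- tibble::as_tibble(summaries)
  if (!"consistent" %in% names(summaries)) summaries$consistent <- NA
  summaries |>
    dplyr::filter(.data$md > threshold,
                  is.na(.data$consistent) | .data$consistent) |>
    dplyr::arrange(dplyr::desc(.data$md), .data$gene)
}

#' Prioritise marker candidates by promoter CpG density
#'
#' Final cascade step: candidates whose promoter CpG density (percent of
#' the 2 kb window covered by CpG islands) strictly exceeds the gate are
#' ranked by density descending (ties by MD descending, then gene name) and
#' truncated to the top `k`.
#'
#' @param candidates Tibble from [select_md_candidates()] (`gene`, `md`).
#' @param densities Gene-to-percent map: a named numeric vector or a tibble
#'   with `gene` and `cpg_density_percent`.
#' @param min_density Strict lower gate on density, percent; default 60.
#' @param k Panel size; default 3.
#' @return A tibble of class `marker_panel` with `gene`, `md`,
#'   `cpg_density_percent`.
#' @export
prioritize_by_cpg_density <- function(candidates, densities,
                                      min_density = 60, k = 3L) {
  candidates <- tibble::as_tibble(candidates)
  if (is.numeric(densities) && !is.null(names(densities))) {
    densities <- tibble::tibble(gene = names(densities),
                                cpg_density_percent = unname(densities))
  }
  densities <- tibble::as_tibble(densities)
  missing <- setdiff(candidates$gene, densities$gene)
  if (length(missing) > 0) {
    abort(paste0("no CpG density for candidate gene(s): ",
                 paste(missing, collapse = ", ")),
          class = "methcascade_validation_error")
  }
  panel <- candidates |>
    dplyr::left_join(densities, by = "gene") |>
    dplyr::filter(.data$cpg_density_percent > min_density) |>
    dplyr::arrange(dplyr::desc(.data$cpg_density_percent),
                   dplyr::desc(.data$md), .data$gene) |>
    utils::head(k) |>
    dplyr::select("gene", "md", "cpg_density_percent")
  class(panel) <- c("marker_panel", class(panel))
  panel
}
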