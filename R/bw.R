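# The bi-weight (BW) two-channel statistic, intensity-table IO and the
# per-probe Z-score transform.

bw_formulas <- c("literal_quotient", "log_ratio")

#' Bi-weight (BW) methylation ratio for a two-channel probe
#'
#' The BW statistic summarises relative methylation from the two channel
#' intensities of a competitively hybridised probe: Cy3 carries the
#' unmethylated DNA fraction and Cy5 the methylated fraction.
#' Two parameterisations are available:
#'
#' * `literal_quotient` (default): `log2(cy3) / log2(cy5)`, the quotient of
#'   logs. Larger methylated-channel signal *lowers* BW; equal channels give
#'   BW = 1.
#' * `log_ratio`: `log2(cy5 / cy3)`, the conventional two-channel log-ratio.
#'   Larger methylated-channel signal raises it; equal channels give 0.
#'
#' Both channels must be at least 2 fluorescence units so that
#' `log2(cy5) >= 1` and the quotient is never singular; feed lower values
#' through a floor upstream or reject them.
#'
#' @param cy3,cy5 Numeric vectors of unmethylated- and methylated-channel
#'   fluorescence intensities (recycled to common length).
#' @param formula `"literal_quotient"` or `"log_ratio"`.
#' @return Numeric vector of BW values.
#' @export
#' @examples
#' compute_bw(4, 4)    # 1
#' compute_bw(16, 4)   # 2
#' compute_bw(8, 2)    # 3
compute_bw <- function(cy3, cy5, formula = c("literal_quotient", "log_ratio")) {
  formula <- match.arg(formula)
  if (any(cy3 < 2, na.rm = TRUE) || any(cy5 < 2, na.rm = TRUE)) {
    abort("intensities below 2 fluorescence units are outside the BW domain",
          class = "methcascade_domain_error")
  }
  if (any(is.na(cy3)) || any(is.na(cy5))) {
    abort("missing intensities are not admissible",
          class = "methcascade_domain_error")
  }
  if (formula == "literal_quotient") log2(cy3) / log2(cy5) else log2(cy5 / cy3)
}

#' Read and validate a long-form two-channel intensity table
#'
#' Reads the TSV written by [write_array_sim()] (columns `region_id`,
#' `probe_id`, `sample_id`, `cy3`, `cy5`) together with a BED-like region
#' annotation whose name column holds the region id and whose seventh
#' column holds the gene symbol, and returns a validated, gene-annotated
#' intensity tibble.
#'
#' Validation rejects, with messages naming the offending probes and
#' samples: missing cells (the probe-by-sample grid must be complete),
#' duplicated (probe, sample) pairs, intensities below 2 fluorescence
#' units, and probes whose region is absent from the annotation.
#'
#' @param path Path to the intensity TSV.
#' @param annotation_path Path to the BED-like annotation
#'   (`chrom`, `start`, `end`, `region_id`, `score`, `strand`, `gene`,
#'   no header).
#' @return A tibble with columns `probe_id`, `region_id`, `gene`,
#'   `sample_id`, `cy3`, `cy5`.
#' @export
read_intensity_table <- function(path, annotation_path) {
  ints <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            region_id = readr::col_character(),
                            probe_id = readr::col_character(),
                            sample_id = readr::col_character(),
                            cy3 = readr::col_double(),
                            cy5 = readr::col_double()
                          ))
  regions <- read_region_annotation(annotation_path)
  annotate_intensities(ints, regions)
}

#' @rdname read_intensity_table
#' @export
read_region_annotation <- function(annotation_path) {
  readr::read_tsv(annotation_path,
                  col_names = c("chrom", "start", "end", "region_id",
                                "score", "strand", "gene"),
                  show_col_types = FALSE,
                  col_types = "ciicicc")
}

#' Attach gene annotation to an intensity table and validate it
#'
#' @param intensities Long-form intensity tibble (`region_id`, `probe_id`,
#'   `sample_id`, `cy3`, `cy5`).
#' @param regions Region annotation tibble with `region_id` and `gene`.
#' @return The validated intensity tibble with a `gene` column.
#' @export
annotate_intensities <- function(intensities, regions) {
  ints <- tibble::as_tibble(intensities)
  req <- c("region_id", "probe_id", "sample_id", "cy3", "cy5")
  if (!all(req %in% names(ints))) {
    abort(paste0("intensity table must have columns ",
                 paste(req, collapse = ", ")),
          class = "methcascade_validation_error")
  }

  dup <- ints |>
    dplyr::count(.data$probe_id, .data$sample_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated (probe, sample) pairs: ",
                 paste(utils::head(paste0(dup$probe_id, "/", dup$sample_id), 5),
                       collapse = ", ")),
          class = "methcascade_validation_error")
  }

  bad <- ints |>
    dplyr::filter(is.na(.data$cy3) | is.na(.data$cy5) |
                    .data$cy3 < 2 | .data$cy5 < 2)
  if (nrow(bad) > 0) {
    abort(paste0("missing or sub-threshold (< 2) intensities at: ",
                 paste(utils::head(paste0(bad$probe_id, "/", bad$sample_id), 5),
                       collapse = ", ")),
          class = "methcascade_validation_error")
  }

  n_probe <- dplyr::n_distinct(ints$probe_id)
  n_sample <- dplyr::n_distinct(ints$sample_id)
  if (nrow(ints) != n_probe * n_sample) {
    abort(paste0("incomplete probe-by-sample grid: ", nrow(ints), " rows for ",
                 n_probe, " probes x ", n_sample, " samples"),
          class = "methcascade_validation_error")
  }

  unknown <- setdiff(unique(ints$region_id), regions$region_id)
  if (length(unknown) > 0) {
    abort(paste0("unannotated regions: ",
                 paste(utils::head(unknown, 5), collapse = ", ")),
          class = "methcascade_validation_error")
  }

  out <- ints |>
    dplyr::left_join(dplyr::select(regions, "region_id", "gene"),
                     by = "region_id") |>
    dplyr::select("probe_id", "region_id", "gene", "sample_id", "cy3", "cy5")
  inform(paste0("intensity table: ", n_probe, " probes, ", n_sample,
                " samples"))
  out
}

#' Compute the BW matrix for a whole intensity table
#'
#' Applies [compute_bw()] cell-wise to a long-form intensity tibble. The
#' chosen formula is recorded as the `bw_formula` attribute of the result,
#' which downstream direction labelling in [call_dmrs()] consults so that
#' "hyper"/"hypo" always refer to methylation rather than the sign of BW.
#'
#' @param intensities Gene-annotated long intensity tibble (see
#'   [read_intensity_table()] / [annotate_intensities()]).
#' @inheritParams compute_bw
#' @return The input tibble with `cy3`/`cy5` replaced by a `bw` column.
#' @export
compute_bw_matrix <- function(intensities,
                              formula = c("literal_quotient", "log_ratio")) {
  formula <- match.arg(formula)
  ints <- tibble::as_tibble(intensities)
  bw <- tryCatch(
    compute_bw(ints$cy3, ints$cy5, formula),
    error = function(e) e
  )
  if (inherits(bw, "error")) {
    bad <- which(ints$cy3 < 2 | ints$cy5 < 2 | is.na(ints$cy3) | is.na(ints$cy5))
    abort(paste0("inadmissible intensities at: ",
                 paste(utils::head(
                   paste0(ints$probe_id[bad], "/", ints$sample_id[bad]), 5),
                   collapse = ", ")),
          class = "methcascade_domain_error")
  }
  out <- ints |>
    dplyr::mutate(bw = bw) |>
    dplyr::select(-"cy3", -"cy5")
  attr(out, "bw_formula") <- formula
  out
}

#' Per-probe Z-score transform of a BW table
#'
#' Standardises each probe's BW values across samples (mean 0, sample SD 1,
#' denominator n - 1), the transform used to visualise differentially
#' methylated probes in a heatmap. Probes that are constant across samples
#' map to all-zero rows.
#'
#' @param bw Long BW tibble from [compute_bw_matrix()].
#' @return The input tibble with an additional `z` column; the `bw_formula`
#'   attribute is carried over.
#' @export
zscore_transform <- function(bw) {
  bw <- tibble::as_tibble(bw)
  if (dplyr::n_distinct(bw$sample_id) < 2) {
    abort("Z-score transform needs at least 2 samples",
          class = "methcascade_validation_error")
  }
  out <- bw |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::mutate(
      z = {
        s <- sd(.data$bw)
        if (is.na(s) || s == 0) rep(0, dplyr::n())
        else (.data$bw - mean(.data$bw)) / s
      }
    ) |>
    dplyr::ungroup()
  attr(out, "bw_formula") <- attr(bw, "bw_formula")
  out
}

#' Pivot a long BW/Z table to a probe-by-sample matrix
#'
#' @param bw Long tibble with `probe_id`, `sample_id` and a value column.
#' @param value Name of the value column (`"bw"` or `"z"`).
#' @return A numeric matrix, probes in rows, samples in columns.
#' @export
bw_wide <- function(bw, value = "bw") {
  wide <- bw |>
    dplyr::select("probe_id", "sample_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$probe_id
  m
}

#' Write a BW or Z matrix as wide-form TSV (probes x samples)
#'
#' @inheritParams bw_wide
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_bw_matrix <- function(bw, path, value = "bw") {
  m <- bw_wide(bw, value)
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(probe_id = rownames(m)),
                     tibble::as_tibble(m)),
    path
  )
  invisible(path)
}
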