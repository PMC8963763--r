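# Seeded simulators with planted ground truth: two-channel methylation arrays,
# promoter sequences with CpG islands, and MSP/clinical validation cohorts.

#' Configuration for the two-channel methylation array simulator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_methylation_array()]. The defaults emulate a discovery cohort of
#' 22 tumour biopsies (12 complete responders, CR; 10 therapy-resistant, TR)
#' hybridised to a two-channel CpG-island promoter array with two probes per
#' region.
#'
#' Planted regions shift the methylated-channel (Cy5) log2 intensity of TR
#' samples by `effect_size` (up for hypermethylated regions, down for
#' hypomethylated ones), so `effect_size` is exactly the planted group
#' difference on the log2(Cy5/Cy3) scale. `noise_sd` is the standard
#' deviation of that per-cell log-ratio signal; each channel receives
#' independent normal noise with SD `noise_sd / sqrt(2)`.
#'
#' @param n_regions Number of promoter regions on the array.
#' @param probes_per_region Probes tiling each region. Default 2, so that
#'   probe-level and region-level differential counts can differ.
#' @param n_cr,n_tr Number of CR and TR samples.
#' @param frac_hyper,frac_hypo Fractions of regions planted as hyper- or
#'   hypomethylated in TR relative to CR. Must sum to at most 1.
#' @param effect_size Planted shift of the methylated-channel log2 intensity
#'   in TR samples (log2 fluorescence units; non-negative).
#' @param noise_sd Standard deviation of the per-cell log-ratio signal.
#' @param baseline_log_intensity Mean log2 fluorescence of both channels.
#'   Must exceed `effect_size + 1` so fluorescence stays at or above 2 units.
#' @param seed Integer seed. Identical configurations produce identical
#'   datasets.
#'
#' @return A validated list of class `array_sim_config`.
#' @seealso [simulate_methylation_array()]
#' @export
#' @examples
#' array_sim_config(n_regions = 100, frac_hyper = 0.1, frac_hypo = 0.1, seed = 1)
array_sim_config <- function(n_regions,
                             probes_per_region = 2L,
                             n_cr = 12L,
                             n_tr = 10L,
                             frac_hyper = 0.05,
                             frac_hypo = 0.05,
                             effect_size = 1,
                             noise_sd = 0.5,
                             baseline_log_intensity = 10,
                             seed = 1L) {
  cfg <- list(
    n_regions = n_regions, probes_per_region = probes_per_region,
    n_cr = n_cr, n_tr = n_tr,
    frac_hyper = frac_hyper, frac_hypo = frac_hypo,
    effect_size = effect_size, noise_sd = noise_sd,
    baseline_log_intensity = baseline_log_intensity, seed = seed
  )
  for (fld in c("n_regions", "probes_per_region", "n_cr", "n_tr")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != floor(v)) {
      abort(paste0("`", fld, "` must be a single integer >= 1"),
            class = "methcascade_config_error")
    }
    cfg[[fld]] <- as.integer(v)
  }
  for (fld in c("frac_hyper", "frac_hypo")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", fld, "` must be a fraction in [0, 1]"),
            class = "methcascade_config_error")
    }
  }
  if (cfg$frac_hyper + cfg$frac_hypo > 1 + 1e-12) {
    abort("`frac_hyper` + `frac_hypo` must not exceed 1",
          class = "methcascade_config_error")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0) {
    abort("`noise_sd` must be > 0", class = "methcascade_config_error")
  }
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0) {
    abort("`effect_size` must be >= 0", class = "methcascade_config_error")
  }
  if (cfg$baseline_log_intensity - cfg$effect_size < 1) {
    abort(paste0("`baseline_log_intensity` must exceed `effect_size` + 1 ",
                 "so that simulated intensities stay >= 2"),
          class = "methcascade_config_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    abort("`seed` must be a single integer", class = "methcascade_config_error")
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "array_sim_config")
}

#' Simulate a two-channel methylation array experiment
#'
#' Draws a long-form two-channel intensity table with planted hyper- and
#' hypomethylated regions, together with its region annotation, sample
#' labels, and the planted ground truth. For every probe and sample the
#' unmethylated-channel (Cy3) and methylated-channel (Cy5) log2 intensities
#' are `baseline + noise`; in TR samples the Cy5 log2 intensity of planted
#' regions is additionally shifted by `effect_size` (up = hyper, down =
#' hypo). Intensities are floored at 2 fluorescence units, the admissible
#' minimum for the bi-weight ratio.
#'
#' @param config An [array_sim_config()].
#'
#' @return A list of class `meth_array_sim` with elements
#'   * `intensities`: tibble (`region_id`, `probe_id`, `sample_id`, `cy3`, `cy5`),
#'   * `regions`: BED-like tibble (`chrom`, `start`, `end`, `region_id`,
#'     `score`, `strand`, `gene`),
#'   * `labels`: tibble (`sample_id`, `group`),
#'   * `truth`: tibble (`region_id`, `gene`, `direction`) with direction in
#'     `hyper`/`hypo`/`null`,
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sim <- simulate_methylation_array(array_sim_config(n_regions = 50, seed = 7))
#' dplyr::count(sim$truth, direction)
simulate_methylation_array <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  withr::with_seed(config$seed, {
    n_reg <- config$n_regions
    ppr <- config$probes_per_region
    n_s <- config$n_cr + config$n_tr
    n_p <- n_reg * ppr

    region_id <- sprintf("R%05d", seq_len(n_reg))
    gene <- sprintf("G%05d", seq_len(n_reg))
    sample_id <- c(sprintf("CR%02d", seq_len(config$n_cr)),
                   sprintf("TR%02d", seq_len(config$n_tr)))
    group <- rep(c("CR", "TR"), c(config$n_cr, config$n_tr))

    n_hyper <- round(config$frac_hyper * n_reg)
    n_hypo <- round(config$frac_hypo * n_reg)
    direction <- rep("null", n_reg)
    planted <- sample.int(n_reg, n_hyper + n_hypo)
    direction[planted[seq_len(n_hyper)]] <- "hyper"
    direction[planted[seq_len(n_hypo) + n_hyper]] <- "hypo"

    ch_sd <- config$noise_sd / sqrt(2)
    b <- config$baseline_log_intensity
    log_cy3 <- matrix(rnorm(n_p * n_s, b, ch_sd), n_p, n_s)
    log_cy5 <- matrix(rnorm(n_p * n_s, b, ch_sd), n_p, n_s)

    # per-probe signed shift, applied to TR columns of the methylated channel
    sign_reg <- c(hyper = 1, hypo = -1, null = 0)[direction]
    shift <- rep(sign_reg, each = ppr) * config$effect_size
    tr_cols <- which(group == "TR")
    log_cy5[, tr_cols] <- log_cy5[, tr_cols] + shift

    probe_id <- sprintf("%s_p%d", rep(region_id, each = ppr),
                        rep(seq_len(ppr), n_reg))
    intensities <- tibble::tibble(
      region_id = rep(rep(region_id, each = ppr), n_s),
      probe_id = rep(probe_id, n_s),
      sample_id = rep(sample_id, each = n_p),
      cy3 = pmax(2, as.vector(2^log_cy3)),
      cy5 = pmax(2, as.vector(2^log_cy5))
    )

    regions <- tibble::tibble(
      chrom = paste0("chr", (seq_len(n_reg) - 1L) %% 22L + 1L),
      start = 2000L * (seq_len(n_reg) - 1L),
      end = 2000L * seq_len(n_reg),
      region_id = region_id,
      score = 0L,
      strand = "+",
      gene = gene
    )

    structure(
      list(
        intensities = intensities,
        regions = regions,
        labels = tibble::tibble(sample_id = sample_id, group = group),
        truth = tibble::tibble(region_id = region_id, gene = gene,
                               direction = direction),
        config = config
      ),
      class = "meth_array_sim"
    )
  })
}

#' Write a simulated array dataset to disk
#'
#' Writes the long-form intensity table and truth/labels as TSV and the
#' region annotation as a headerless 7-column BED-like file (0-based,
#' half-open; the seventh column is the gene symbol).
#'
#' @param sim A `meth_array_sim` from [simulate_methylation_array()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_array_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "meth_array_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    intensities = file.path(dir, "intensities.tsv"),
    regions = file.path(dir, "regions.bed"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$intensities, paths[["intensities"]])
  readr::write_tsv(sim$regions, paths[["regions"]], col_names = FALSE)
  readr::write_tsv(sim$labels, paths[["labels"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Simulate promoter sequences with planted CpG islands
#'
#' Generates one 2,000 bp promoter window per gene. A CpG island of the
#' requested length and GC composition is planted at the centre of the
#' window; the flanks are drawn base-by-base with the requested flank GC
#' fraction. Island sequence is built from dinucleotide slots that are `CG`
#' with probability `island_gc` (exact count, shuffled positions) and `AT`
#' otherwise, which makes planted islands CpG-dense (observed/expected CpG
#' ratio about `2 / island_gc`) and hence detectable by [find_cpg_islands()]
#' whenever `island_gc >= 0.5`.
#'
#' @param gene_specs Tibble or data frame with columns `gene`,
#'   `island_length` (even, 0 to 2000), `island_gc` and `flank_gc`
#'   (fractions in `[0, 1]`).
#' @param seed Integer seed.
#' @param window_length Promoter window size in bp (default 2000).
#'
#' @return A list of class `promoter_sim` with
#'   * `sequences`: tibble (`gene`, `sequence`),
#'   * `truth`: tibble (`gene`, `island_start`, `island_end`) — 0-based
#'     half-open coordinates of the planted island (`NA` when none).
#' @export
#' @examples
#' specs <- tibble::tibble(gene = "GX", island_length = 600,
#'                         island_gc = 0.6, flank_gc = 0.2)
#' sim <- simulate_promoters(specs, seed = 1)
#' nchar(sim$sequences$sequence)
simulate_promoters <- function(gene_specs, seed = 1L, window_length = 2000L) {
  gene_specs <- tibble::as_tibble(gene_specs)
  req <- c("gene", "island_length", "island_gc", "flank_gc")
  if (!all(req %in% names(gene_specs))) {
    abort(paste0("`gene_specs` must have columns ",
                 paste(req, collapse = ", ")),
          class = "methcascade_config_error")
  }
  if (any(gene_specs$island_length > window_length)) {
    abort("`island_length` must not exceed the promoter window length",
          class = "methcascade_config_error")
  }
  if (any(gene_specs$island_length < 0) ||
      any(gene_specs$island_length %% 2 != 0)) {
    abort("`island_length` must be an even non-negative number of bases",
          class = "methcascade_config_error")
  }
  if (any(gene_specs$island_gc < 0 | gene_specs$island_gc > 1) ||
      any(gene_specs$flank_gc < 0 | gene_specs$flank_gc > 1)) {
    abort("`island_gc` and `flank_gc` must be fractions in [0, 1]",
          class = "methcascade_config_error")
  }

  withr::with_seed(seed, {
    rows <- purrr::pmap(gene_specs[req], function(gene, island_length,
                                                  island_gc, flank_gc) {
      isl_start <- (window_length - island_length) %/% 2L
      isl <- character(0)
      if (island_length > 0) {
        n2 <- island_length %/% 2L
        n_cg <- round(island_gc * n2)
        slots <- sample(rep(c("CG", "AT"), c(n_cg, n2 - n_cg)))
        isl <- slots
      }
      flank_n <- window_length - island_length
      p <- c(flank_gc / 2, flank_gc / 2, (1 - flank_gc) / 2, (1 - flank_gc) / 2)
      flank <- sample(c("C", "G", "A", "T"), flank_n, replace = TRUE, prob = p)
      seq <- paste0(
        paste(flank[seq_len(isl_start)], collapse = ""),
        paste(isl, collapse = ""),
        paste(flank[seq_len(flank_n - isl_start) + isl_start], collapse = "")
      )
      list(
        sequence = seq,
        island_start = if (island_length > 0) isl_start else NA_integer_,
        island_end = if (island_length > 0) isl_start + island_length else NA_integer_
      )
    })
    structure(
      list(
        sequences = tibble::tibble(
          gene = gene_specs$gene,
          sequence = purrr::map_chr(rows, "sequence")
        ),
        truth = tibble::tibble(
          gene = gene_specs$gene,
          island_start = purrr::map_int(rows, "island_start"),
          island_end = purrr::map_int(rows, "island_end")
        )
      ),
      class = "promoter_sim"
    )
  })
}

#' Write simulated promoters as FASTA plus a truth table
#'
#' @param sim A `promoter_sim` from [simulate_promoters()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional TSV path for the planted-island truth.
#' @return Invisibly, `fasta_path`.
#' @export
write_promoters <- function(sim, fasta_path, truth_path = NULL) {
  stopifnot(inherits(sim, "promoter_sim"))
  seqs <- Biostrings::DNAStringSet(setNames(sim$sequences$sequence,
                                            sim$sequences$gene))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(truth_path)) readr::write_tsv(sim$truth, truth_path)
  invisible(fasta_path)
}

default_status_probabilities <- function() {
  tibble::tribble(
    ~gene,   ~group, ~M,      ~HM,     ~U,
    "BRD9",  "CR",   1,       0,       0,
    "BRD9",  "TR",   0,       25 / 30, 5 / 30,
    "CTU1",  "CR",   0,       0,       1,
    "CTU1",  "TR",   1 / 30,  27 / 30, 2 / 30,
    "DOCK8", "CR",   0,       31 / 40, 9 / 40,
    "DOCK8", "TR",   0,       1 / 30,  29 / 30
  )
}

#' Configuration for the MSP validation-cohort simulator
#'
#' Parameters for [simulate_msp_cohort()]. Defaults emulate a 70-sample
#' validation cohort (40 CR, 30 TR) genotyped by methylation-specific PCR at
#' three marker genes, with per-group status frequencies mirroring those
#' observed in the original validation cohort, and survival driven by the
#' MSP status of a designated driver gene.
#'
#' Progression-free survival is exponential with the status-specific hazard
#' of the driver gene; overall survival adds an exponential post-progression
#' time with hazard `os_hazard_by_status`. Both are administratively
#' censored at `censor_horizon` months.
#'
#' @param n_cr,n_tr Samples per response group.
#' @param status_probabilities Tibble with columns `gene`, `group` and the
#'   three status probabilities `M`, `HM`, `U` (each row summing to 1).
#' @param hazard_by_status Named numeric: PFS events per month for driver
#'   status `M`, `HM` and `U`.
#' @param os_hazard_by_status Named numeric: post-progression hazard per
#'   status (events per month).
#' @param driver_gene Gene whose status determines the hazards; defaults to
#'   the first gene in `status_probabilities`.
#' @param stage2_prob,small_tumor_prob Named numeric (`CR`, `TR`):
#'   probability of FIGO stage II and of tumour size < 5 cm per response
#'   group.
#' @param censor_horizon Administrative censoring time in months.
#' @param seed Integer seed.
#'
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cr = 40L,
                              n_tr = 30L,
                              status_probabilities = default_status_probabilities(),
                              hazard_by_status = c(M = 0.01, HM = 0.30, U = 0.20),
                              os_hazard_by_status = c(M = 0.005, HM = 0.10, U = 0.06),
                              driver_gene = NULL,
                              stage2_prob = c(CR = 0.75, TR = 0.30),
                              small_tumor_prob = c(CR = 0.70, TR = 0.45),
                              censor_horizon = 60,
                              seed = 1L) {
  for (fld in c("n_cr", "n_tr")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      abort(paste0("`", fld, "` must be a single integer >= 1"),
            class = "methcascade_config_error")
    }
  }
  sp <- tibble::as_tibble(status_probabilities)
  if (!all(c("gene", "group", "M", "HM", "U") %in% names(sp))) {
    abort("`status_probabilities` needs columns gene, group, M, HM, U",
          class = "methcascade_config_error")
  }
  sums <- sp$M + sp$HM + sp$U
  if (any(abs(sums - 1) > 1e-9)) {
    bad <- paste(sp$gene[abs(sums - 1) > 1e-9], sp$group[abs(sums - 1) > 1e-9],
                 sep = "/", collapse = ", ")
    abort(paste0("status probabilities must sum to 1 (violated for ", bad, ")"),
          class = "methcascade_config_error")
  }
  for (hz in list(hazard_by_status, os_hazard_by_status)) {
    if (!all(c("M", "HM", "U") %in% names(hz)) || any(hz <= 0)) {
      abort("hazards must be positive and named M, HM, U",
            class = "methcascade_config_error")
    }
  }
  if (censor_horizon <= 0) {
    abort("`censor_horizon` must be > 0", class = "methcascade_config_error")
  }
  driver_gene <- driver_gene %||% sp$gene[[1]]
  if (!driver_gene %in% sp$gene) {
    abort("`driver_gene` must appear in `status_probabilities`",
          class = "methcascade_config_error")
  }
  structure(
    list(n_cr = as.integer(n_cr), n_tr = as.integer(n_tr),
         status_probabilities = sp,
         hazard_by_status = hazard_by_status,
         os_hazard_by_status = os_hazard_by_status,
         driver_gene = driver_gene,
         stage2_prob = stage2_prob, small_tumor_prob = small_tumor_prob,
         censor_horizon = censor_horizon, seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

#' Simulate an MSP-typed validation cohort with survival
#'
#' Draws per-sample, per-gene MSP statuses from group-specific M/HM/U
#' distributions, derives the corresponding methylated/unmethylated PCR
#' bands, and generates stage, tumour size and exponential survival times
#' whose hazard depends on the driver gene's status (administratively
#' censored at the configured horizon).
#'
#' @param config A [cohort_sim_config()].
#' @return A list of class `msp_cohort_sim` with `msp` (tibble: `sample_id`,
#'   `gene`, `band_m`, `band_u`, `status`) and `clinical` (tibble:
#'   `sample_id`, `response`, `stage_group`, `tumor_size_group`,
#'   `os_months`, `os_event`, `pfs_months`, `pfs_event`).
#' @export
#' @examples
#' sim <- simulate_msp_cohort(cohort_sim_config(seed = 3))
#' nrow(sim$clinical)
simulate_msp_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_cr + config$n_tr
    sample_id <- c(sprintf("V_CR%02d", seq_len(config$n_cr)),
                   sprintf("V_TR%02d", seq_len(config$n_tr)))
    response <- rep(c("CR", "TR"), c(config$n_cr, config$n_tr))

    sp <- config$status_probabilities
    msp <- tidyr::crossing(sample_id = sample_id,
                           gene = unique(sp$gene)) |>
      dplyr::left_join(tibble::tibble(sample_id = sample_id,
                                      group = response),
                       by = "sample_id") |>
      dplyr::left_join(sp, by = c("gene", "group")) |>
      dplyr::arrange(.data$gene, .data$sample_id)
    status <- purrr::pmap_chr(
      msp[, c("M", "HM", "U")],
      function(M, HM, U) sample(c("M", "HM", "U"), 1L, prob = c(M, HM, U))
    )
    msp <- msp |>
      dplyr::transmute(
        sample_id = .data$sample_id, gene = .data$gene,
        band_m = status %in% c("M", "HM"),
        band_u = status %in% c("U", "HM"),
        status = status
      )

    driver <- msp$status[match(paste(sample_id, config$driver_gene),
                               paste(msp$sample_id, msp$gene))]
    pfs_haz <- config$hazard_by_status[driver]
    os_haz <- config$os_hazard_by_status[driver]
    pfs_raw <- rexp(n, rate = pfs_haz)
    os_raw <- pfs_raw + rexp(n, rate = os_haz)
    horizon <- config$censor_horizon

    clinical <- tibble::tibble(
      sample_id = sample_id,
      response = response,
      stage_group = ifelse(runif(n) < config$stage2_prob[response],
                           "II", "III-IV"),
      tumor_size_group = ifelse(runif(n) < config$small_tumor_prob[response],
                                "<5cm", ">=5cm"),
      os_months = pmin(os_raw, horizon),
      os_event = os_raw < horizon,
      pfs_months = pmin(pfs_raw, horizon),
      pfs_event = pfs_raw < horizon
    )
    structure(list(msp = msp, clinical = clinical, config = config),
              class = "msp_cohort_sim")
  })
}

#' Write a simulated MSP cohort as CSV
#'
#' @param sim An `msp_cohort_sim` from [simulate_msp_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of file paths.
#' @export
write_msp_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "msp_cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(msp = file.path(dir, "msp_calls.csv"),
             clinical = file.path(dir, "clinical.csv"))
  readr::write_csv(sim$msp, paths[["msp"]])
  readr::write_csv(sim$clinical, paths[["clinical"]])
  invisible(paths)
}
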