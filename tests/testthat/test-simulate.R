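# Simulators: dimensions, planted truth, determinism, validation guards.

test_that("array simulator produces the configured dimensions and truth", {
  cfg <- array_sim_config(n_regions = 1000, probes_per_region = 2,
                          frac_hyper = 0.05, frac_hypo = 0.05, seed = 42)
  sim <- simulate_methylation_array(cfg)
  expect_equal(nrow(sim$intensities), 2000 * 22)
  expect_equal(dplyr::n_distinct(sim$intensities$probe_id), 2000)
  expect_equal(dplyr::n_distinct(sim$intensities$sample_id), 22)
  expect_equal(sum(sim$truth$direction == "hyper"), 50)
  expect_equal(sum(sim$truth$direction == "hypo"), 50)
  expect_equal(sort(sim$truth$region_id), sort(sim$regions$region_id))
  expect_false(any(duplicated(sim$truth$region_id)))
  expect_true(all(sim$intensities$cy3 >= 2))
  expect_true(all(sim$intensities$cy5 >= 2))
  expect_equal(nrow(sim$labels), 22)
  expect_equal(sum(sim$labels$group == "CR"), 12)
})

test_that("array simulator is deterministic given seed and config", {
  cfg <- array_sim_config(n_regions = 50, seed = 7)
  a <- simulate_methylation_array(cfg)
  b <- simulate_methylation_array(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_array_sim(a, d1)
  write_array_sim(b, d2)
  for (f in c("intensities.tsv", "regions.bed", "labels.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("invalid array configurations are rejected naming the field", {
  expect_error(array_sim_config(n_regions = 0), "n_regions",
               class = "methcascade_config_error")
  expect_error(array_sim_config(n_regions = 10, frac_hyper = 0.7,
                                frac_hypo = 0.7),
               "frac_hyper",
               class = "methcascade_config_error")
  expect_error(array_sim_config(n_regions = 10, frac_hyper = 1.3),
               "frac_hyper", class = "methcascade_config_error")
  expect_error(array_sim_config(n_regions = 10, noise_sd = 0),
               "noise_sd", class = "methcascade_config_error")
  expect_error(array_sim_config(n_regions = 10, n_tr = 0.5), "n_tr",
               class = "methcascade_config_error")
})

test_that("planted regions shift the methylated channel with the stated sign", {
  cfg <- array_sim_config(n_regions = 200, frac_hyper = 0.25,
                          frac_hypo = 0.25, effect_size = 3,
                          noise_sd = 0.5, seed = 5)
  sim <- simulate_methylation_array(cfg)
  joined <- sim$intensities |>
    dplyr::left_join(sim$truth, by = "region_id") |>
    dplyr::left_join(sim$labels, by = "sample_id") |>
    dplyr::group_by(.data$direction, .data$group) |>
    dplyr::summarise(m5 = mean(log2(cy5)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "m5")
  shift <- setNames(joined$TR - joined$CR, joined$direction)
  expect_equal(unname(shift["hyper"]), 3, tolerance = 0.05)
  expect_equal(unname(shift["hypo"]), -3, tolerance = 0.05)
  expect_equal(unname(shift["null"]), 0, tolerance = 0.05)
})

test_that("promoter simulator honours trivial compositions", {
  specs <- tibble::tibble(
    gene = c("geneX", "geneY"),
    island_length = c(0L, 2000L),
    island_gc = c(0, 1),
    flank_gc = c(0, 0)
  )
  sim <- simulate_promoters(specs, seed = 3)
  expect_equal(nchar(sim$sequences$sequence), c(2000L, 2000L))
  # no island: A/T only
  expect_false(grepl("[CG]", sim$sequences$sequence[1]))
  expect_true(is.na(sim$truth$island_start[1]))
  # full-window island at gc 1: alternating CG covering [0, 2000)
  expect_equal(sim$sequences$sequence[2], strrep("CG", 1000))
  expect_equal(sim$truth$island_start[2], 0L)
  expect_equal(sim$truth$island_end[2], 2000L)
  expect_error(
    simulate_promoters(tibble::tibble(gene = "g", island_length = 2200,
                                      island_gc = 0.5, flank_gc = 0.5)),
    "island_length", class = "methcascade_config_error"
  )
})

test_that("planted islands are recovered with reciprocal overlap >= 0.8", {
  withr::local_seed(91)
  n_spec <- 50
  specs <- tibble::tibble(
    gene = sprintf("g%02d", seq_len(n_spec)),
    island_length = 2L * sample(600:850, n_spec, replace = TRUE),
    island_gc = runif(n_spec, 0.55, 0.62),
    flank_gc = runif(n_spec, 0.05, 0.20)
  )
  sim <- simulate_promoters(specs, seed = 17)
  for (i in seq_len(n_spec)) {
    isl <- find_cpg_islands(sim$sequences$sequence[i])
    truth <- sim$truth[i, ]
    ov <- pmax(0, pmin(isl$end, truth$island_end) -
                    pmax(isl$start, truth$island_start))
    recip <- ov / pmax(isl$end - isl$start,
                       truth$island_end - truth$island_start)
    expect_true(any(recip >= 0.8),
                label = paste0("planted island recovered for ", specs$gene[i]))
  }
})

test_that("cohort simulator produces the configured cohort deterministically", {
  cfg <- cohort_sim_config(n_cr = 40, n_tr = 30, seed = 8)
  sim <- simulate_msp_cohort(cfg)
  expect_equal(nrow(sim$clinical), 70)
  expect_equal(sum(sim$clinical$response == "CR"), 40)
  expect_equal(nrow(sim$msp), 70 * 3)
  expect_true(all(sim$msp$status %in% c("M", "HM", "U")))
  # band encoding matches status semantics
  expect_true(all((sim$msp$status == "M") == (sim$msp$band_m & !sim$msp$band_u)))
  expect_true(all((sim$msp$status == "HM") == (sim$msp$band_m & sim$msp$band_u)))
  expect_true(all(sim$clinical$pfs_months >= 0))
  expect_true(all(sim$clinical$pfs_months <= cfg$censor_horizon))
  expect_true(all(sim$clinical$os_months >= sim$clinical$pfs_months |
                    !sim$clinical$os_event))
  sim2 <- simulate_msp_cohort(cfg)
  expect_identical(sim$msp, sim2$msp)
  expect_identical(sim$clinical, sim2$clinical)
})

test_that("cohort simulator rejects malformed status probabilities", {
  bad <- tibble::tibble(gene = "G", group = c("CR", "TR"),
                        M = c(0.5, 0.2), HM = c(0.2, 0.2), U = c(0.2, 0.6))
  expect_error(cohort_sim_config(status_probabilities = bad),
               "sum to 1", class = "methcascade_config_error")
  expect_error(cohort_sim_config(hazard_by_status = c(M = 0, HM = 1, U = 1)),
               "hazard", class = "methcascade_config_error")
})

test_that("deterministic status assignment yields a diagonal response table", {
  probs <- tibble::tibble(gene = "GX", group = c("CR", "TR"),
                          M = c(1, 0), HM = c(0, 0), U = c(0, 1))
  sim <- simulate_msp_cohort(cohort_sim_config(status_probabilities = probs,
                                               seed = 2))
  tab <- build_contingency(sim$msp, sim$clinical, "GX", "response")
  expect_equal(tab["CR", "M"], 40L)
  expect_equal(tab["TR", "U"], 30L)
  expect_equal(sum(tab), 70L)
  fit <- chi_square_test(tab)
  expect_lt(fit$p_value, 0.001)
})
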