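# Differential calling: t-test machinery, direction orientation, region
# summarisation and clustering.

test_that("t_test_probe matches hand computation and a reference implementation", {
  # identical groups: t = 0, p = 1
  same <- t_test_probe(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # (1,2,3) vs (4,5,6): pooled variance 1, se = sqrt(2/3),
  # t = -3 / 0.8165 = -3.6742, df = 4, p = 0.0213
  res <- t_test_probe(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  # group swap negates t, keeps p
  swap <- t_test_probe(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  expect_error(t_test_probe(1, c(1, 2)), "at least 2",
               class = "methcascade_validation_error")

  # random fixtures against stats::t.test, both variants
  withr::local_seed(21)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    student <- t_test_probe(a, b, "student")
    ref_s <- t.test(a, b, var.equal = TRUE)
    expect_equal(student$t, unname(ref_s$statistic), tolerance = 1e-10)
    expect_equal(student$p, ref_s$p.value, tolerance = 1e-10)
    welch <- t_test_probe(a, b, "welch")
    ref_w <- t.test(a, b)
    expect_equal(welch$t, unname(ref_w$statistic), tolerance = 1e-10)
    expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-10)
    expect_equal(welch$p, ref_w$p.value, tolerance = 1e-10)
  }
})

make_labelled_bw <- function(n_probes = 40, n_cr = 6, n_tr = 6, seed = 1,
                             formula = "literal_quotient") {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_probes * (n_cr + n_tr), 1, 0.2), n_probes,
                dimnames = list(
                  sprintf("p%03d", seq_len(n_probes)),
                  c(sprintf("c%02d", seq_len(n_cr)),
                    sprintf("t%02d", seq_len(n_tr)))
                ))
    list(
      bw = make_bw_fixture(m, formula = formula),
      labels = tibble::tibble(
        sample_id = colnames(m),
        group = rep(c("CR", "TR"), c(n_cr, n_tr))
      )
    )
  })
}

test_that("call_dmrs validates alpha and orients direction by the BW formula", {
  fx <- make_labelled_bw(seed = 2)
  expect_error(call_dmrs(fx$bw, fx$labels, alpha = 0),
               class = "methcascade_config_error")
  expect_error(call_dmrs(fx$bw, fx$labels, alpha = 1),
               class = "methcascade_config_error")

  all_probes <- call_dmrs(fx$bw, fx$labels, keep_all = TRUE)
  # literal quotient: more methylation lowers BW, so hyper <=> mean_diff < 0
  expect_true(all(all_probes$direction[all_probes$mean_diff < 0] == "hyper"))
  expect_true(all(all_probes$direction[all_probes$mean_diff > 0] == "hypo"))

  lr <- fx$bw
  attr(lr, "bw_formula") <- "log_ratio"
  all_lr <- call_dmrs(lr, fx$labels, keep_all = TRUE)
  expect_true(all(all_lr$direction[all_lr$mean_diff > 0] == "hyper"))

  # sorted by mean_diff descending
  sig <- call_dmrs(fx$bw, fx$labels, alpha = 0.5)
  expect_true(all(diff(sig$mean_diff) <= 0))
})

test_that("label swap flips directions; column order is irrelevant", {
  fx <- make_labelled_bw(seed = 3)
  sig <- call_dmrs(fx$bw, fx$labels, alpha = 0.2)
  swapped <- dplyr::mutate(fx$labels,
                           group = ifelse(group == "CR", "TR", "CR"))
  sig_sw <- call_dmrs(fx$bw, swapped, alpha = 0.2)
  expect_setequal(sig$probe_id, sig_sw$probe_id)
  m <- match(sig$probe_id, sig_sw$probe_id)
  expect_true(all(sig$direction != sig_sw$direction[m]))
  expect_equal(sig$mean_diff, -sig_sw$mean_diff[m])

  withr::local_seed(9)
  shuffled <- fx$bw[sample(nrow(fx$bw)), ]
  attr(shuffled, "bw_formula") <- "literal_quotient"
  sig_sh <- call_dmrs(shuffled, fx$labels, alpha = 0.2)
  expect_equal(as.data.frame(sig), as.data.frame(sig_sh))
})

test_that("summarize_dmrs partitions regions like a brute-force re-count", {
  recs <- tibble::tibble(
    probe_id = paste0("p", 1:4),
    region_id = c("r1", "r1", "r2", "r3"),
    gene = c("g1", "g1", "g2", "g3"),
    direction = c("hyper", "hyper", "hyper", "hypo")
  )
  s <- summarize_dmrs(recs)
  expect_equal(s$n_hyper_regions, 2L)
  expect_equal(s$n_hypo_regions, 1L)
  expect_equal(s$n_both_regions, 0L)

  mixed <- dplyr::mutate(recs, direction = c("hyper", "hypo", "hyper", "hypo"))
  expect_equal(summarize_dmrs(mixed)$n_both_regions, 1L)

  expect_equal(summarize_dmrs(recs[0, ])$n_sig_probes, 0L)

  # property: partition identities against an independent dictionary oracle
  withr::local_seed(31)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    fake <- tibble::tibble(
      probe_id = paste0("p", seq_len(n)),
      region_id = paste0("r", sample.int(max(2, n %/% 3), n, replace = TRUE)),
      gene = "g",
      direction = sample(c("hyper", "hypo"), n, replace = TRUE)
    )
    s <- summarize_dmrs(fake)
    expect_equal(s$n_hyper_probes + s$n_hypo_probes, s$n_sig_probes)
    expect_equal(s$n_hyper_regions + s$n_hypo_regions + s$n_both_regions,
                 s$n_unique_regions)
    oracle <- tapply(fake$direction, fake$region_id,
                     function(d) {
                       u <- unique(d)
                       if (length(u) == 2) "both" else u
                     })
    expect_equal(s$n_unique_regions, length(oracle))
    expect_equal(s$n_hyper_regions, sum(oracle == "hyper"))
    expect_equal(s$n_hypo_regions, sum(oracle == "hypo"))
    expect_equal(s$n_both_regions, sum(oracle == "both"))
  }
})

test_that("clustering separates well-separated groups and behaves metrically", {
  cfg <- array_sim_config(n_regions = 150, frac_hyper = 0.2, frac_hypo = 0.2,
                          effect_size = 2, noise_sd = 0.5, seed = 11)
  sim <- simulate_methylation_array(cfg)
  ints <- suppressMessages(annotate_intensities(sim$intensities, sim$regions))
  bw <- compute_bw_matrix(ints)
  dmrs <- call_dmrs(bw, sim$labels)
  z <- zscore_transform(dplyr::semi_join(bw, dmrs, by = "probe_id"))
  cl <- cluster_samples(z, sim$labels)
  expect_equal(cl$rand_index, 1.0)
  expect_setequal(cl$leaf_order, sim$labels$sample_id)

  d <- as.matrix(cl$distance)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # duplicate sample columns merge first (distance zero)
  first_sample <- z$sample_id[1]
  zdup <- dplyr::bind_rows(
    z,
    dplyr::mutate(dplyr::filter(z, sample_id == first_sample),
                  sample_id = "dup")
  )
  cl2 <- cluster_samples(zdup)
  dd <- as.matrix(cl2$distance)
  expect_equal(dd[first_sample, "dup"], 0)
  first_merge <- cl2$hclust$merge[1, ]
  merged_ids <- cl2$hclust$labels[-first_merge]
  expect_setequal(merged_ids, c(first_sample, "dup"))

  expect_error(cluster_samples(dplyr::filter(z, sample_id == first_sample)),
               "2 samples", class = "methcascade_validation_error")
})
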