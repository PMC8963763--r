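# Differential methylation calling between responder groups, probe-to-region
# summarisation and sample clustering.

#' Two-sample t-test for one probe
#'
#' Two-sided two-sample t-test of BW values between the CR and TR groups.
#' `student` (default) uses the pooled-variance statistic; `welch` the
#' unequal-variance variant. The statistic is oriented as
#' `mean(values_cr) - mean(values_tr)` over its standard error, so swapping
#' the groups negates `t` and leaves `p` unchanged.
#'
#' @param values_cr,values_tr Numeric vectors of BW values (each of length
#'   at least 2).
#' @param variant `"student"` or `"welch"`.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
#' @examples
#' t_test_probe(c(1, 2, 3), c(4, 5, 6))
t_test_probe <- function(values_cr, values_tr,
                         variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(values_cr) < 2 || length(values_tr) < 2) {
    abort("each group needs at least 2 values",
          class = "methcascade_validation_error")
  }
  res <- t_stats(mean(values_cr), mean(values_tr),
                 stats::var(values_cr), stats::var(values_tr),
                 length(values_cr), length(values_tr), variant)
  tibble::tibble(t = res$t, df = res$df, p = res$p)
}

# vectorised pooled/Welch t machinery shared by t_test_probe and call_dmrs;
# oriented first-group-minus-second-group
t_stats <- function(m1, m2, v1, v2, n1, n2, variant) {
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  p <- 2 * pt(-abs(t), df)
  p[t == 0] <- 1
  list(t = t, df = df, p = p)
}

check_labels <- function(bw, labels) {
  labels <- tibble::as_tibble(labels)
  if (!all(c("sample_id", "group") %in% names(labels))) {
    abort("`labels` must have columns sample_id and group",
          class = "methcascade_validation_error")
  }
  if (!all(labels$group %in% c("CR", "TR"))) {
    abort("groups must be CR or TR", class = "methcascade_validation_error")
  }
  missing <- setdiff(unique(bw$sample_id), labels$sample_id)
  if (length(missing) > 0) {
    abort(paste0("unlabelled samples: ", paste(missing, collapse = ", ")),
          class = "methcascade_validation_error")
  }
  if (dplyr::n_distinct(labels$group) < 2) {
    abort("both CR and TR groups must be non-empty",
          class = "methcascade_validation_error")
  }
  labels
}

#' Call differentially methylated probes between CR and TR
#'
#' Runs one two-sample t-test per probe on its BW values, keeps probes with
#' `p < alpha`, and labels each retained probe `hyper` (more methylation in
#' TR than CR) or `hypo` (less). The methylation orientation is derived
#' from the BW formula recorded on the input: under the literal
#' quotient-of-logs, more methylated-channel signal *lowers* BW, so `hyper`
#' corresponds to a negative TR-minus-CR mean difference; under the
#' log-ratio it corresponds to a positive one.
#'
#' No multiple-testing correction is applied by default; set
#' `adjust = "BH"` to filter on Benjamini-Hochberg adjusted p-values
#' instead.
#'
#' @param bw Long BW tibble from [compute_bw_matrix()].
#' @param labels Tibble with `sample_id` and `group` (`CR`/`TR`).
#' @param alpha Significance level in (0, 1); default 0.01.
#' @param variant t-test variant, `"student"` (default) or `"welch"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param keep_all Return all probes (with a `significant` flag) instead of
#'   only the significant ones. Default `FALSE`.
#'
#' @return A tibble with one row per (significant) probe: `probe_id`,
#'   `region_id`, `gene`, `t`, `df`, `p` (and `p_adj` when adjusted),
#'   `mean_diff` (TR mean minus CR mean, BW units) and `direction`,
#'   sorted by `mean_diff` descending with ties broken by `probe_id`.
#' @export
call_dmrs <- function(bw, labels, alpha = 0.01,
                      variant = c("student", "welch"),
                      adjust = c("none", "BH"),
                      keep_all = FALSE) {
  variant <- match.arg(variant)
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1",
          class = "methcascade_config_error")
  }
  bw <- tibble::as_tibble(bw)
  formula <- attr(bw, "bw_formula") %||% "literal_quotient"
  if (!"gene" %in% names(bw)) bw$gene <- bw$region_id
  labels <- check_labels(bw, labels)

  grp <- bw |>
    dplyr::left_join(labels, by = "sample_id") |>
    dplyr::group_by(.data$probe_id, .data$region_id, .data$gene, .data$group) |>
    dplyr::summarise(n = dplyr::n(), m = mean(.data$bw),
                     v = stats::var(.data$bw), .groups = "drop")
  if (any(grp$n < 2)) {
    abort("each group needs at least 2 samples per probe",
          class = "methcascade_validation_error")
  }
  wide <- grp |>
    tidyr::pivot_wider(names_from = "group", values_from = c("n", "m", "v"))
  ts <- t_stats(wide$m_CR, wide$m_TR, wide$v_CR, wide$v_TR,
                wide$n_CR, wide$n_TR, variant)

  res <- wide |>
    dplyr::transmute(
      probe_id = .data$probe_id, region_id = .data$region_id,
      gene = .data$gene,
      t = ts$t, df = ts$df, p = ts$p,
      mean_diff = .data$m_TR - .data$m_CR
    )
  orient <- if (formula == "literal_quotient") -1 else 1
  res$direction <- ifelse(orient * res$mean_diff > 0, "hyper", "hypo")
  if (adjust == "BH") {
    res$p_adj <- p.adjust(res$p, method = "BH")
    res$significant <- res$p_adj < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res <- res |>
    dplyr::arrange(dplyr::desc(.data$mean_diff), .data$probe_id)
  if (!keep_all) {
    res <- dplyr::filter(res, .data$significant)
    res$significant <- NULL
  }
  attr(res, "bw_formula") <- formula
  attr(res, "alpha") <- alpha
  res
}

#' Summarise probe-level differential calls to regions
#'
#' Collapses significant probes to unique regions and partitions the
#' regions into purely hypermethylated, purely hypomethylated, and mixed
#' ("both") classes: a region counts as `hyper` when every one of its
#' significant probes is hyper, `hypo` when every one is hypo, and `both`
#' otherwise. The counts satisfy
#' `n_hyper_probes + n_hypo_probes = n_sig_probes` and
#' `n_hyper_regions + n_hypo_regions + n_both_regions = n_unique_regions`.
#'
#' @param records Probe-level tibble from [call_dmrs()].
#' @return A one-row tibble with the seven counts above.
#' @export
summarize_dmrs <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      n_sig_probes = 0L, n_hyper_probes = 0L, n_hypo_probes = 0L,
      n_unique_regions = 0L, n_hyper_regions = 0L, n_hypo_regions = 0L,
      n_both_regions = 0L
    ))
  }
  reg <- records |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(
      class = if (all(.data$direction == "hyper")) "hyper"
              else if (all(.data$direction == "hypo")) "hypo"
              else "both",
      .groups = "drop"
    )
  tibble::tibble(
    n_sig_probes = nrow(records),
    n_hyper_probes = sum(records$direction == "hyper"),
    n_hypo_probes = sum(records$direction == "hypo"),
    n_unique_regions = nrow(reg),
    n_hyper_regions = sum(reg$class == "hyper"),
    n_hypo_regions = sum(reg$class == "hypo"),
    n_both_regions = sum(reg$class == "both")
  )
}

#' Agglomerative clustering of samples on Z-scored probes
#'
#' Clusters samples by Euclidean distance on per-probe Z-scores (typically
#' restricted to significant probes) with agglomerative linkage, and, when
#' labels are supplied, reports how well cutting the tree into two clusters
#' recovers the CR/TR split (Rand index).
#'
#' @param z Long tibble with a `z` column from [zscore_transform()].
#' @param labels Optional tibble with `sample_id`, `group`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`
#'   (Ward.D2).
#' @return A list of class `sample_clustering`: `hclust`, `leaf_order`
#'   (sample ids left to right), `clusters` (2-cut membership) and
#'   `rand_index` (`NA` without labels).
#' @export
cluster_samples <- function(z, labels = NULL,
                            linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  m <- bw_wide(z, "z")
  if (ncol(m) < 2) {
    abort("clustering needs at least 2 samples",
          class = "methcascade_validation_error")
  }
  d <- dist(t(m), method = "euclidean")
  hc <- hclust(d, method = c(average = "average", complete = "complete",
                             ward = "ward.D2")[[linkage]])
  clusters <- cutree(hc, k = 2)
  ri <- NA_real_
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    grp <- labels$group[match(names(clusters), labels$sample_id)]
    ri <- rand_index(clusters, grp)
  }
  structure(
    list(hclust = hc, leaf_order = hc$labels[hc$order],
         clusters = clusters, rand_index = ri, distance = d),
    class = "sample_clustering"
  )
}

# Rand index between two partitions (pair-counting agreement)
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(NA_real_)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}

#' Export a sample dendrogram in Newick format
#'
#' @param clustering A `sample_clustering` from [cluster_samples()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "sample_clustering"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the ape package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("Sample clustering (", x$hclust$method, " linkage, Euclidean)\n",
      sep = "")
  cat("  samples:", length(x$leaf_order), "\n")
  if (!is.na(x$rand_index)) {
    cat("  2-cut Rand index vs labels:", format(x$rand_index, digits = 4),
        "\n")
  }
  invisible(x)
}
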