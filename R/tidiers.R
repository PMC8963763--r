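# broom-style tidiers for the fitted objects of the package.

#' Tidy a chi-square association result
#'
#' @param x An `mc_chisq` from [chi_square_test()].
#' @param ... Unused.
#' @return One row per table cell: row level, column level, observed and
#'   expected count, Pearson residual.
#' @export
tidy.mc_chisq <- function(x, ...) {
  m <- x$table
  exp <- outer(rowSums(m), colSums(m)) / sum(m)
  tibble::tibble(
    row = rep(rownames(m) %||% as.character(seq_len(nrow(m))), ncol(m)),
    column = rep(colnames(m) %||% as.character(seq_len(ncol(m))),
                 each = nrow(m)),
    observed = as.vector(m),
    expected = as.vector(exp),
    residual = as.vector((m - exp) / sqrt(exp))
  )
}

#' @rdname tidy.mc_chisq
#' @export
glance.mc_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 mc_p_value = x$mc_p_value %||% NA_real_,
                 n = sum(x$table))
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit` from [km_estimate()].
#' @param ... Unused.
#' @return The step tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
tidy.km_fit <- function(x, ...) x$steps

#' @rdname tidy.km_fit
#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, median = x$median)
}

#' Tidy a log-rank test result
#'
#' @param x A `logrank_result` from [logrank_test()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_a = unname(x$n["a"]), n_b = unname(x$n["b"]))
}

#' @rdname tidy.logrank_result
#' @export
glance.logrank_result <- function(x, ...) tidy(x)

#' Tidy a survival comparison
#'
#' @param x A `survival_comparison` from [compare_survival()].
#' @param ... Unused.
#' @return Survival steps of both groups with a `status` column.
#' @export
tidy.survival_comparison <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$km, function(km, nm) {
    dplyr::mutate(km$steps, status = nm, .before = 1)
  }))
}

#' @rdname tidy.survival_comparison
#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(
    gene = x$gene, endpoint = x$endpoint,
    group1 = x$groups[1], group2 = x$groups[2],
    median1 = x$km[[1]]$median, median2 = x$km[[2]]$median,
    statistic = x$logrank$statistic, p_value = x$logrank$p_value
  )
}
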