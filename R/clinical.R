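# MSP status calls, chi-square association tests and Kaplan-Meier /
# log-rank survival comparisons for the validation cohort.

msp_status_levels <- c("M", "HM", "U")

#' Classify a methylation-specific PCR result
#'
#' Two PCR reactions are run per sample on bisulfite-converted DNA, one
#' with methylated-specific primers and one with unmethylated-specific
#' primers. A band in only the methylated reaction is `M` (methylated),
#' only the unmethylated reaction `U` (unmethylated), and both `HM`
#' (hemimethylated). Neither band is an indeterminate assay result:
#' an error by default, or `NA` with `on_indeterminate = "na"` so callers
#' can drop and count such samples.
#'
#' @param band_m,band_u Logical vectors: product present in the methylated-
#'   and unmethylated-primer reactions.
#' @param on_indeterminate `"error"` (default) or `"na"`.
#' @return Character vector of statuses in `M`/`HM`/`U`.
#' @export
#' @examples
#' call_msp_status(TRUE, FALSE)  # "M"
#' call_msp_status(TRUE, TRUE)   # "HM"
call_msp_status <- function(band_m, band_u,
                            on_indeterminate = c("error", "na")) {
  on_indeterminate <- match.arg(on_indeterminate)
  stopifnot(is.logical(band_m), is.logical(band_u))
  bad <- !band_m & !band_u
  if (any(bad)) {
    if (on_indeterminate == "error") {
      abort(paste0("indeterminate MSP result (no band in either reaction) ",
                   "at position(s) ", paste(which(bad), collapse = ", ")),
            class = "methcascade_validation_error")
    }
    warn(paste0(sum(bad), " indeterminate MSP result(s) set to NA"))
  }
  dplyr::case_when(
    band_m & !band_u ~ "M",
    band_m & band_u ~ "HM",
    !band_m & band_u ~ "U",
    TRUE ~ NA_character_
  )
}

clinical_variable_levels <- list(
  response = c("CR", "TR"),
  stage_group = c("II", "III-IV"),
  tumor_size_group = c("<5cm", ">=5cm")
)

#' Contingency table of MSP status versus a clinical variable
#'
#' Joins per-sample MSP calls for one gene with the clinical table and
#' cross-tabulates the clinical variable (rows) against methylation status
#' (columns, fixed order M / HM / U). Every classified sample is counted
#' exactly once; samples with `NA` status are excluded with a message.
#'
#' @param calls Tibble with `sample_id`, `gene`, `status` (or `band_m` /
#'   `band_u`, from which statuses are derived).
#' @param clinical Tibble with `sample_id` and the clinical variables.
#' @param gene Gene to tabulate.
#' @param variable One of `"response"`, `"stage_group"`,
#'   `"tumor_size_group"`.
#' @return An integer matrix (variable levels x M/HM/U).
#' @export
build_contingency <- function(calls, clinical, gene,
                              variable = c("response", "stage_group",
                                           "tumor_size_group")) {
  variable <- match.arg(variable)
  calls <- tibble::as_tibble(calls)
  clinical <- tibble::as_tibble(clinical)
  calls <- dplyr::filter(calls, .data$gene == !!gene)
  if (!"status" %in% names(calls)) {
    calls$status <- call_msp_status(calls$band_m, calls$band_u,
                                    on_indeterminate = "na")
  }
  n_na <- sum(is.na(calls$status))
  if (n_na > 0) {
    inform(paste0(n_na, " sample(s) with indeterminate MSP status excluded"))
    calls <- dplyr::filter(calls, !is.na(.data$status))
  }
  missing <- setdiff(calls$sample_id, clinical$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples absent from the clinical table: ",
                 paste(missing, collapse = ", ")),
          class = "methcascade_validation_error")
  }
  joined <- dplyr::left_join(calls, clinical, by = "sample_id")
  lv <- clinical_variable_levels[[variable]]
  tab <- table(
    factor(joined[[variable]], levels = lv),
    factor(joined$status, levels = msp_status_levels)
  )
  m <- matrix(as.integer(tab), nrow = length(lv),
              dimnames = list(lv, msp_status_levels))
  m
}

#' Pearson chi-square test with optional Monte-Carlo p-value
#'
#' Pearson's chi-square without continuity correction. All-zero rows and
#' columns are dropped before computing expected counts and degrees of
#' freedom (an all-zero status column otherwise yields undefined expected
#' counts). An optional Monte-Carlo p-value is computed by resampling
#' tables with fixed margins (seeded), which is the honest choice when
#' expected counts fall below 5.
#'
#' @param table A counts matrix.
#' @param drop_empty Drop all-zero rows/columns first (default `TRUE`).
#' @param mc_replicates Number of Monte-Carlo replicates, or `NULL` for
#'   the asymptotic p-value only.
#' @param seed Seed for the Monte-Carlo resampling.
#' @return A list of class `mc_chisq`: `table`, `statistic`, `df`,
#'   `p_value`, and (when requested) `mc_p_value`, `mc_replicates`,
#'   `mc_seed`.
#' @export
#' @examples
#' chi_square_test(matrix(c(10, 0, 0, 10), 2))
chi_square_test <- function(table, drop_empty = TRUE, mc_replicates = NULL,
                            seed = 1L) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != floor(m))) {
    abort("counts must be non-negative integers",
          class = "methcascade_validation_error")
  }
  if (drop_empty) {
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("degenerate table: need at least 2 non-empty rows and columns",
          class = "methcascade_validation_error")
  }
  fit <- suppressWarnings(chisq.test(m, correct = FALSE))
  out <- list(table = m,
              statistic = unname(fit$statistic),
              df = unname(fit$parameter),
              p_value = unname(fit$p.value))
  if (!is.null(mc_replicates)) {
    mc <- withr::with_seed(seed, suppressWarnings(
      chisq.test(m, simulate.p.value = TRUE, B = mc_replicates)
    ))
    out$mc_p_value <- unname(mc$p.value)
    out$mc_replicates <- mc_replicates
    out$mc_seed <- seed
  }
  structure(out, class = "mc_chisq")
}

#' @export
print.mc_chisq <- function(x, ...) {
  cat("Pearson chi-square (no continuity correction)\n")
  cat("  X-squared =", format(x$statistic, digits = 5),
      " df =", x$df,
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$mc_p_value)) {
    cat("  Monte-Carlo p =", format(x$mc_p_value, digits = 4),
        " (", x$mc_replicates, "replicates )\n")
  }
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate for one group. The reported median
#' survival is the smallest observed time at which the survival estimate
#' drops to 0.5 or below (`NA` when never reached).
#'
#' @param times Non-negative event/censoring times (months).
#' @param events Logical or 0/1 event indicators.
#' @return A list of class `km_fit`: the underlying
#'   [survival::survfit] object, a step tibble (`time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`), `median` and `n`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$steps$survival  # 2/3, 1/3, 0
km_estimate <- function(times, events) {
  if (length(times) == 0) {
    abort("survival input is empty", class = "methcascade_validation_error")
  }
  if (length(times) != length(events)) {
    abort("`times` and `events` must have equal length",
          class = "methcascade_validation_error")
  }
  if (any(times < 0)) {
    abort("times must be non-negative", class = "methcascade_validation_error")
  }
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  steps <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  med <- steps$time[steps$survival <= 0.5]
  med <- if (length(med) > 0) min(med) else NA_real_
  structure(list(survfit = fit, steps = steps, median = med,
                 n = length(times), n_events = sum(events)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, ", events =", x$n_events, "\n")
  cat("  median survival:",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 4),
      "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank comparison of two survival curves; the
#' statistic is referred to a chi-square distribution with 1 degree of
#' freedom.
#'
#' @param times_a,events_a,times_b,events_b Times and event indicators for
#'   the two groups (both non-empty).
#' @return A list of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   `n` (per-group sizes).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    abort("both groups must be non-empty",
          class = "methcascade_validation_error")
  }
  time <- c(times_a, times_b)
  event <- as.integer(as.logical(c(events_a, events_b)))
  group <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(
    list(statistic = unname(fit$chisq), df = 1L,
         p_value = unname(pchisq(fit$chisq, df = 1, lower.tail = FALSE)),
         n = c(a = length(times_a), b = length(times_b))),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 5),
      " df = 1, p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Compare survival between the two most frequent MSP status groups
#'
#' For one gene, selects the two most frequent methylation statuses in the
#' cohort (ties resolved in M, HM, U order), estimates a Kaplan-Meier
#' curve per status, and compares them with the log-rank test — mirroring
#' per-gene two-group survival panels. The grouping can be overridden.
#'
#' @param msp Tibble with `sample_id`, `gene`, `status`.
#' @param clinical Tibble with `sample_id` and survival columns.
#' @param gene Gene to analyse.
#' @param endpoint `"os"` or `"pfs"` (expects `<endpoint>_months` and
#'   `<endpoint>_event` columns).
#' @param groups Optional character vector of two statuses to compare.
#' @return A list of class `survival_comparison`: `gene`, `endpoint`,
#'   `groups`, per-group `km` fits, `logrank`.
#' @export
compare_survival <- function(msp, clinical, gene,
                             endpoint = c("os", "pfs"), groups = NULL) {
  endpoint <- match.arg(endpoint)
  msp <- dplyr::filter(tibble::as_tibble(msp), .data$gene == !!gene)
  joined <- dplyr::inner_join(msp, tibble::as_tibble(clinical),
                              by = "sample_id")
  if (is.null(groups)) {
    freq <- table(factor(joined$status, levels = msp_status_levels))
    groups <- names(sort(freq, decreasing = TRUE))[1:2]
  }
  if (length(groups) != 2 || any(!groups %in% joined$status)) {
    abort("need two status groups with observations",
          class = "methcascade_validation_error")
  }
  tcol <- paste0(endpoint, "_months")
  ecol <- paste0(endpoint, "_event")
  sub <- dplyr::filter(joined, .data$status %in% groups)
  km <- purrr::map(setNames(groups, groups), function(g) {
    gi <- sub$status == g
    km_estimate(sub[[tcol]][gi], sub[[ecol]][gi])
  })
  lr <- logrank_test(sub[[tcol]][sub$status == groups[1]],
                     sub[[ecol]][sub$status == groups[1]],
                     sub[[tcol]][sub$status == groups[2]],
                     sub[[ecol]][sub$status == groups[2]])
  structure(list(gene = gene, endpoint = endpoint, groups = groups,
                 km = km, logrank = lr),
            class = "survival_comparison")
}

#' Read MSP calls and clinical tables from CSV
#'
#' @param msp_path CSV with `sample_id`, `gene`, `band_m`, `band_u` and
#'   optionally `status`.
#' @param clinical_path CSV with `sample_id`, `response`, `stage_group`,
#'   `tumor_size_group`, `os_months`, `os_event`, `pfs_months`,
#'   `pfs_event`.
#' @return A list with `msp` and `clinical` tibbles.
#' @export
read_msp_cohort <- function(msp_path, clinical_path) {
  for (p in c(msp_path, clinical_path)) {
    if (!file.exists(p)) {
      abort(paste0("file not found: ", p), class = "methcascade_config_error")
    }
  }
  msp <- readr::read_csv(msp_path, show_col_types = FALSE)
  clinical <- readr::read_csv(clinical_path, show_col_types = FALSE)
  if (!"status" %in% names(msp)) {
    msp$status <- call_msp_status(msp$band_m, msp$band_u,
                                  on_indeterminate = "na")
  }
  list(msp = msp, clinical = clinical)
}
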