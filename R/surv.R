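#' Composite activity score across selected subnetworks
#'
#' Per sample, the mean of z-standardized activity scores over the
#' selected subnetworks, each subnetwork oriented so that higher means
#' more tumor-like (rows whose training Welch t is negative are flipped).
#' Zero-variance subnetworks are excluded with a warning.
#'
#' @param activity activity matrix (subnetworks x samples).
#' @param selected character vector of subnetwork ids to combine.
#' @param orientation optional named numeric (e.g. training Welch t per
#'   subnetwork); negative entries flip the corresponding z-scores.
#' @return named numeric vector, one composite score per sample.
#' @export
composite_score <- function(activity, selected, orientation = NULL) {
  if (!length(selected))
    snm_error("snm_invalid_input", "selected must be non-empty")
  rows <- activity[selected, , drop = FALSE]
  sds <- apply(rows, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding zero-variance subnetwork(s): %s",
                    paste(selected[sds == 0], collapse = ", ")))
    rows <- rows[sds > 0, , drop = FALSE]
    selected <- selected[sds > 0]
    sds <- sds[sds > 0]
    if (!nrow(rows))
      snm_error("snm_invalid_input", "all selected subnetworks have zero variance")
  }
  z <- (rows - rowMeans(rows)) / sds
  if (!is.null(orientation)) {
    flip <- selected[!is.na(orientation[selected]) & orientation[selected] < 0]
    z[flip, ] <- -z[flip, , drop = FALSE]
  }
  colMeans(z)
}

#' Assign high/low risk groups by median split
#'
#' `high_risk` for scores strictly above the median; scores exactly at the
#' median go to `low_risk`. A degenerate input (all scores equal) yields
#' all `low_risk` with a `degenerate` attribute.
#'
#' @param scores named numeric vector of composite scores (>= 2 samples).
#' @param quantile_cut split quantile (default 0.5 = median).
#' @return character vector (`"high_risk"`/`"low_risk"`) with attribute
#'   `degenerate`.
#' @export
assign_risk_groups <- function(scores, quantile_cut = 0.5) {
  if (length(scores) < 2L)
    snm_error("snm_invalid_input", "need at least 2 samples")
  cut <- stats::quantile(scores, quantile_cut, names = FALSE, type = 7)
  out <- ifelse(scores > cut, "high_risk", "low_risk")
  attr(out, "degenerate") <- length(unique(scores)) == 1L
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times with
#' `d_i` events among `n_i` at risk; censored records leave the risk set
#' after their time (censored at t remain at risk for events at t).
#'
#' @param time non-negative times (months).
#' @param event 0/1 event indicators (1 = observed).
#' @return a `km_curve` list: `event_times` (ascending), `survival_prob`
#'   (nonincreasing), `at_risk`, `n_events`, `n`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time))
    snm_error("snm_invalid_input", "need at least one record")
  if (any(time < 0))
    snm_error("snm_invalid_input", "negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  structure(list(event_times = fit$time[keep],
                 survival_prob = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n_events = fit$n.event[keep],
                 n = length(time)), class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) with a two-sided p-value: at each
#' distinct event time the observed events in one group are compared with
#' their hypergeometric expectation and the variance summed. With no
#' events in either group the test is flagged and `p = 1` by convention.
#'
#' @param time,event survival data for all samples.
#' @param group two-level grouping vector.
#' @return list with `chi_square`, `p`, `degenerate`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2L)
    snm_error("snm_invalid_input", "exactly two groups required")
  if (sum(event) == 0L)
    return(list(chi_square = 0, p = 1, degenerate = TRUE))
  sd <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group),
    error = function(e) NULL)
  if (is.null(sd))
    return(list(chi_square = 0, p = 1, degenerate = TRUE))
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Risk-group survival analysis with optional ER stratification
#'
#' Builds per-sample survival records from clinical data and a composite
#' score, splits into high/low risk groups, and runs Kaplan-Meier
#' estimation plus the log-rank test overall and within each requested
#' stratum. Strata with a single risk group are skipped with a warning;
#' empty strata are omitted.
#'
#' @param clinical data.frame with `sample_id`, `survival_time`, `event`
#'   and optionally `er_status`.
#' @param scores named composite scores covering the clinical samples.
#' @param strata `"all"` only, or also per ER level when available.
#' @param alpha significance threshold on the log-rank p (default 0.05).
#' @param quantile_cut risk-split quantile (default median).
#' @return a `survival_report`: per-stratum list with `n_high`, `n_low`,
#'   `km_high`, `km_low`, `chi_square`, `p`, `significant`.
#' @export
stratified_analysis <- function(clinical, scores,
                                strata = c("all", "er"),
                                alpha = 0.05, quantile_cut = 0.5) {
  strata <- match.arg(strata, several.ok = TRUE)
  ids <- clinical$sample_id
  if (!all(ids %in% names(scores)))
    snm_error("snm_invalid_input", "scores missing for some clinical samples")
  sc <- scores[ids]
  group <- assign_risk_groups(sc, quantile_cut)
  records <- data.frame(sample_id = ids,
                        time = clinical$survival_time,
                        event = clinical$event,
                        group = unname(group),
                        stringsAsFactors = FALSE)
  records$er_status <- if ("er_status" %in% names(clinical))
    clinical$er_status else NA_character_

  stratum_sets <- list(all = records)
  if ("er" %in% strata && any(!is.na(records$er_status))) {
    for (lev in sort(unique(stats::na.omit(records$er_status)))) {
      stratum_sets[[paste0("er_", lev)]] <-
        records[records$er_status %in% lev, , drop = FALSE]
    }
  }
  out <- list()
  for (nm in names(stratum_sets)) {
    rec <- stratum_sets[[nm]]
    if (!nrow(rec)) next
    if (length(unique(rec$group)) < 2L) {
      warning(sprintf("stratum '%s' has a single risk group; skipped", nm))
      next
    }
    hi <- rec[rec$group == "high_risk", ]
    lo <- rec[rec$group == "low_risk", ]
    lr <- logrank_test(rec$time, rec$event, rec$group)
    out[[nm]] <- list(
      n_high = nrow(hi), n_low = nrow(lo),
      km_high = km_estimate(hi$time, hi$event),
      km_low = km_estimate(lo$time, lo$event),
      chi_square = lr$chi_square, p = lr$p,
      degenerate = lr$degenerate,
      significant = lr$p < alpha)
  }
  structure(out, class = "survival_report")
}
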