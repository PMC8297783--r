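#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator over distinct event times; ties between events and
#' censorings at the same time follow the standard convention (events first).
#' The median is the smallest time with S(t) <= 0.5, `NA` if S never drops
#' that far.
#'
#' @param time event/censoring times in months (>= 0, finite).
#' @param event logical event indicators.
#' @return a `km_estimate` list with a per-time table (time, n_risk, n_event,
#'   n_censor, survival) and `median`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("empty group")
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  # median = smallest t with S(t) <= 0.5 (no flat-interval interpolation),
  # NA when S never reaches 0.5
  below <- tab$time[tab$survival <= 0.5 + 1e-12]
  med <- if (length(below) > 0) min(below) else NA_real_
  structure(list(table = tab, median = med,
                 n = length(time), events = sum(event)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: n=%d, events=%d, median=%s months\n",
              x$n, x$events,
              if (is.na(x$median)) "NA (not reached)" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Unweighted log-rank chi-square (1 df, hypergeometric variance) comparing
#' altered vs unaltered survival, with per-group Kaplan-Meier medians.
#'
#' @param time,event survival times (months) and event flags.
#' @param group factor/character with exactly two levels (e.g. "altered",
#'   "unaltered"); both groups must be non-empty.
#' @return a `logrank_result` list: chisq, p, and per-group n, events, median.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2)
    stop("log-rank test needs exactly 2 non-empty groups, got ",
         nlevels(group))
  if (sum(event) == 0) {
    chisq <- 0  # no events anywhere: no evidence either way
  } else {
    sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- sd_fit$chisq
    if (!is.finite(chisq)) chisq <- 0  # degenerate identical groups
  }
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  per_group <- lapply(levels(group), function(g) {
    sel <- group == g
    km <- km_estimate(time[sel], event[sel])
    list(n = sum(sel), events = sum(event[sel]), median = km$median)
  })
  names(per_group) <- levels(group)
  structure(list(chisq = unname(chisq), p = unname(p), groups = per_group),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq=%.4f (1 df), p=%.4g\n", x$chisq, x$p))
  for (g in names(x$groups)) {
    gi <- x$groups[[g]]
    cat(sprintf("  %s: n=%d, events=%d, median=%s\n", g, gi$n, gi$events,
                if (is.na(gi$median)) "NA" else format(gi$median)))
  }
  invisible(x)
}

#' Survival contrast of altered vs unaltered case sets
#'
#' Builds the two-group survival data from the clinical table for the chosen
#' endpoint (samples lacking endpoint data are dropped, with the retained
#' denominator reported) and runs the log-rank comparison.
#'
#' @param clin a `clinical_table`.
#' @param altered character vector of altered sample IDs.
#' @param endpoint `"OS"` or `"DFS"` (DFS is the single non-OS endpoint; the
#'   literature labels it DFS or PFS interchangeably).
#' @return a `logrank_result` with extra fields `endpoint`, `n_used`,
#'   `n_dropped`.
#' @export
compare_altered_vs_unaltered <- function(clin, altered, endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  tm <- if (endpoint == "OS") clin$os_months else clin$dfs_months
  ev <- if (endpoint == "OS") clin$os_event else clin$dfs_event
  keep <- !is.na(tm) & !is.na(ev)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(sprintf("%s: %d sample(s) without endpoint data dropped (n used = %d)",
                    endpoint, n_dropped, sum(keep)))
  tm <- tm[keep]; ev <- ev[keep]
  grp <- ifelse(clin$sample[keep] %in% altered, "altered", "unaltered")
  if (!any(grp == "altered")) stop("altered case set empty after filtering")
  if (!any(grp == "unaltered")) stop("unaltered case set empty after filtering")
  res <- logrank_test(tm, ev, grp)
  res$endpoint <- endpoint
  res$n_used <- sum(keep)
  res$n_dropped <- n_dropped
  res
}
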