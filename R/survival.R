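# Per-gene univariate survival screening: median split of expression,
# Kaplan-Meier curves, two-group log-rank test and Mantel-Haenszel
# hazard ratio. The product-limit and log-rank machinery goes through
# the survival package.

#' Median split of per-sample expression
#'
#' High iff strictly above the median; ties at the median go low (a fixed
#' rule keeps runs reproducible).
#'
#' @param expr Named numeric vector of per-sample expression (>= 4
#'   values).
#' @return Named character vector of \code{"high"} / \code{"low"}.
#' @export
median_split <- function(expr) {
  if (length(expr) < 4) stop("usage error: need at least 4 samples")
  if (length(unique(expr)) == 1)
    stop("degenerate-split error: all expression values identical")
  med <- stats::median(expr)
  stats::setNames(ifelse(expr > med, "high", "low"), names(expr))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive event/censoring times.
#' @param events 1 = event, 0 = censored.
#' @return List of class \code{km_curve}: \code{time} (distinct times,
#'   ascending), \code{n_risk}, \code{n_event}, \code{surv} (S(t),
#'   non-increasing, 1 before the first event).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("usage error: empty input")
  if (any(times <= 0)) stop("usage error: times must be > 0")
  if (!all(events %in% c(0, 1))) stop("usage error: events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed events in group A are
#' compared with their hypergeometric expectation; chi-square =
#' (sum O - sum E)^2 / sum V on 1 df, with the standard
#' d(n-d)/(n-1) * nA nB / n^2 tie-corrected variance.
#'
#' @param timesA,eventsA Group A times and event indicators.
#' @param timesB,eventsB Group B.
#' @return List: \code{chi2}, \code{p}, \code{obs} (length 2),
#'   \code{exp} (length 2), \code{flag} (\code{"no_events"} when the test
#'   is undefined, else \code{NA}).
#' @export
logrank_test <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) == 0 || length(timesB) == 0)
    stop("usage error: both groups must be non-empty")
  if (sum(eventsA) + sum(eventsB) == 0)
    return(list(chi2 = NA_real_, p = NA_real_, obs = c(0, 0),
                exp = c(NA_real_, NA_real_), flag = "no_events"))
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- factor(c(rep("A", length(timesA)), rep("B", length(timesB))),
                levels = c("A", "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       obs = unname(sd$obs), exp = unname(sd$exp), flag = NA_character_)
}

#' Mantel-Haenszel hazard ratio (group A vs group B)
#'
#' HR = (O_A / E_A) / (O_B / E_B) from the log-rank observed and expected
#' event counts. With all events in one group the ratio degenerates to
#' \code{Inf} (all in A) or \code{0} (all in B) and is flagged.
#'
#' @inheritParams logrank_test
#' @return List: \code{hr}, \code{flag} (\code{NA}, \code{"no_events"},
#'   or \code{"degenerate"}).
#' @export
hazard_ratio <- function(timesA, eventsA, timesB, eventsB) {
  lr <- logrank_test(timesA, eventsA, timesB, eventsB)
  if (!is.na(lr$flag) && lr$flag == "no_events")
    return(list(hr = NA_real_, flag = "no_events"))
  oa <- lr$obs[1]; ob <- lr$obs[2]
  ea <- lr$exp[1]; eb <- lr$exp[2]
  if (ob == 0) return(list(hr = Inf, flag = "degenerate"))
  if (oa == 0) return(list(hr = 0, flag = "degenerate"))
  list(hr = (oa / ea) / (ob / eb), flag = NA_character_)
}

#' Median-split survival screen across a gene panel
#'
#' For every gene: median split of expression over the tumour samples
#' with clinical records, KM curve per group, log-rank test and
#' Mantel-Haenszel HR (high vs low). Samples without clinical records
#' are dropped with a message; genes with a degenerate split or fewer
#' than 4 usable samples are skipped with a warning.
#'
#' @param expr logCPM \code{\link{expr_matrix}}.
#' @param clinical Clinical data.frame (sample_id, time, event).
#' @param genes Gene ids to screen (default: all rows of \code{expr}).
#' @param keep_curves Also return per-gene KM curves.
#' @return data.frame of class \code{km_screen}: gene, n_high, n_low,
#'   events_high, events_low, HR, hr_flag, logrank_chi2, logrank_p,
#'   ordered by gene id. With \code{keep_curves}, attribute
#'   \code{curves}: named list of \code{list(high =, low =)} km_curve
#'   pairs.
#' @export
gene_survival_screen <- function(expr, clinical, genes = NULL,
                                 keep_curves = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(genes)) genes <- rownames(expr$values)
  genes <- sort(genes)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing) > 0) stop("unknown gene id: ", missing[1L])

  samples <- intersect(colnames(expr$values), clinical$sample_id)
  n_dropped <- ncol(expr$values) - length(samples)
  if (!is.null(expr$groups)) {
    tum <- names(expr$groups)[expr$groups == "tumour"]
    samples <- intersect(samples, tum)
  }
  if (n_dropped > 0)
    message(sprintf("survival screen: %d sample(s) without clinical records dropped",
                    n_dropped))
  cl <- clinical[match(samples, clinical$sample_id), ]

  rows <- list(); curves <- list()
  for (g in genes) {
    v <- expr$values[g, samples]
    if (length(v) < 4 || length(unique(v)) == 1) {
      warning("gene ", g, " skipped: degenerate or too few usable samples")
      next
    }
    grp <- median_split(v)
    hi <- grp == "high"
    lr <- logrank_test(cl$time[hi], cl$event[hi], cl$time[!hi], cl$event[!hi])
    hr <- hazard_ratio(cl$time[hi], cl$event[hi], cl$time[!hi], cl$event[!hi])
    rows[[g]] <- data.frame(
      gene = g, n_high = sum(hi), n_low = sum(!hi),
      events_high = sum(cl$event[hi]), events_low = sum(cl$event[!hi]),
      HR = hr$hr, hr_flag = hr$flag,
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      stringsAsFactors = FALSE)
    if (keep_curves)
      curves[[g]] <- list(high = km_estimate(cl$time[hi], cl$event[hi]),
                          low = km_estimate(cl$time[!hi], cl$event[!hi]))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(0), n_high = integer(0), n_low = integer(0),
               events_high = integer(0), events_low = integer(0),
               HR = numeric(0), hr_flag = character(0),
               logrank_chi2 = numeric(0), logrank_p = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_curves) attr(out, "curves") <- curves
  class(out) <- c("km_screen", "data.frame")
  out
}
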