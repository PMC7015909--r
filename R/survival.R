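# Quartile-stratified survival screen: top vs bottom expression quartiles,
# Kaplan-Meier estimation and two-group logrank tests across many genes,
# with unadjusted p-values (significance at p < alpha, deliberately no
# multiple-testing correction, matching the screen it reproduces).

#' Top and bottom expression quartiles
#'
#' Ranks samples by expression and returns the top 25% as the high group
#' and the bottom 25% as the low group (`ceiling(n/4)` each); the middle
#' half is excluded. Ties are broken by sample identifier, so group
#' membership is deterministic and stable under permutation of the input.
#'
#' @param expression Numeric expression values.
#' @param sample_ids Sample identifiers, same length.
#' @return List with character vectors `high` and `low`.
#' @export
quartile_groups <- function(expression, sample_ids) {
  stopifnot(length(expression) == length(sample_ids))
  n <- length(expression)
  if (n < 8) stop("need at least 8 samples", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  if (length(unique(expression)) == 1) {
    stop("expression is constant; quartile groups are undefined",
         call. = FALSE)
  }
  k <- ceiling(n / 4)
  ord <- order(expression, sample_ids)
  list(high = sort(sample_ids[ord][(n - k + 1):n]),
       low = sort(sample_ids[ord][1:k]))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function: starts at S(0) = 1,
#' non-increasing, drops only at event times.
#'
#' @param time Positive follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return Data frame `time`, `surv` (step function, one row per distinct
#'   observed time).
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, surv = fit$surv)
}

#' Two-group logrank test
#'
#' Standard logrank: at each distinct event time the observed number of
#' events in the high group is compared with its hypergeometric
#' expectation; the statistic is `(sum(O - E))^2 / sum(V)`, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param time_high,event_high Follow-up times and event indicators of the
#'   high group.
#' @param time_low,event_low Same for the low group.
#' @return List with `statistic`, `p_value`, `observed_high`,
#'   `expected_high`, and `degenerate` (TRUE when the total variance is
#'   zero, in which case the statistic is 0 and p = 1).
#' @export
logrank_test <- function(time_high, event_high, time_low, event_low) {
  stopifnot(length(time_high) >= 1, length(time_low) >= 1)
  if (sum(event_high) + sum(event_low) == 0) {
    return(list(statistic = 0, p_value = 1, observed_high = 0,
                expected_high = 0, degenerate = TRUE))
  }
  time <- c(time_high, time_low)
  event <- c(event_high, event_low)
  group <- factor(c(rep("high", length(time_high)),
                    rep("low", length(time_low))), levels = c("high", "low"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  v <- if (is.matrix(sd_$var)) sd_$var[1, 1] else sd_$var[1]
  if (!is.finite(v) || v <= 0) {
    return(list(statistic = 0, p_value = 1,
                observed_high = unname(sd_$obs[1]),
                expected_high = unname(sd_$exp[1]), degenerate = TRUE))
  }
  stat <- (sd_$obs[1] - sd_$exp[1])^2 / v
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE),
       observed_high = unname(sd_$obs[1]),
       expected_high = unname(sd_$exp[1]),
       degenerate = FALSE)
}

#' Quartile-stratified logrank screen across genes
#'
#' For every gene: split samples into top/bottom expression quartiles and
#' compare their survival with the logrank test. P-values are not adjusted
#' for multiple testing; `significant` flags unadjusted p < `alpha`. Genes
#' whose quartile groups are undefined (constant expression) are reported
#' with `NA` p-values and excluded from the significant set. The
#' `direction` is +1 when the high-expression group has fewer deaths than
#' expected (better survival), -1 when more, 0 when equal.
#'
#' @param expression Genes x samples numeric matrix with dimnames.
#' @param survival_table Data frame `sample_id`, `time`, `event` covering
#'   the matrix columns.
#' @param alpha Significance level (default 0.05).
#' @return Data frame sorted by p-value: `gene`, `n_high`, `n_low`,
#'   `statistic`, `p_value`, `direction`, `significant`.
#' @export
screen_genes <- function(expression, survival_table, alpha = 0.05) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  missing_samples <- setdiff(colnames(expression),
                             survival_table$sample_id)
  if (length(missing_samples) > 0) {
    stop("survival table missing sample(s): ",
         paste(utils::head(missing_samples, 3), collapse = ", "),
         call. = FALSE)
  }
  surv <- survival_table[match(colnames(expression),
                               survival_table$sample_id), ]
  rows <- lapply(rownames(expression), function(g) {
    x <- expression[g, ]
    groups <- tryCatch(quartile_groups(x, colnames(expression)),
                       error = function(e) NULL)
    if (is.null(groups)) {
      return(data.frame(gene = g, n_high = NA_integer_, n_low = NA_integer_,
                        statistic = NA_real_, p_value = NA_real_,
                        direction = NA_real_, significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    hi <- surv[surv$sample_id %in% groups$high, ]
    lo <- surv[surv$sample_id %in% groups$low, ]
    lr <- logrank_test(hi$time, hi$event, lo$time, lo$event)
    data.frame(
      gene = g, n_high = nrow(hi), n_low = nrow(lo),
      statistic = lr$statistic, p_value = lr$p_value,
      direction = sign(lr$expected_high - lr$observed_high),
      significant = !lr$degenerate && lr$p_value < alpha,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$gene), , drop = FALSE]
}
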