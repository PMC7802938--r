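#' Coefficient of determination between automatic and manual measurements
#'
#' Agreement of automatically extracted trait values with paired manual
#' measurements about the manual mean:
#' `R^2 = 1 - sum((v_i - v'_i)^2) / sum((v_i - vbar)^2)`,
#' where `v` are the manual values, `v'` the automatic ones and `vbar` the
#' manual mean. Equals 1 for perfect agreement and 0 when the automatic
#' values carry no more information than the manual mean; can be negative
#' for predictors worse than the mean.
#'
#' @param manual,automatic numeric vectors of equal length >= 2.
#' @return scalar <= 1.
#' @export
r_squared <- function(manual, automatic) {
  stopifnot(length(manual) == length(automatic), length(manual) >= 2)
  ss_tot <- sum((manual - mean(manual))^2)
  if (ss_tot == 0) stop("manual values are all identical (zero variance)")
  1 - sum((manual - automatic)^2) / ss_tot
}

#' Normalized root-mean-squared error
#'
#' RMSE of the automatic values against the manual ones, divided by the
#' manual mean; conventionally reported as a percentage.
#'
#' @param manual,automatic numeric vectors of equal length.
#' @param as_percent return the value times 100 (default FALSE).
#' @return non-negative scalar (fraction of the manual mean, or percent).
#' @export
nrmse <- function(manual, automatic, as_percent = FALSE) {
  stopifnot(length(manual) == length(automatic), length(manual) >= 1)
  m <- mean(manual)
  if (m == 0) stop("manual mean is zero; NRMSE undefined")
  out <- sqrt(mean((manual - automatic)^2)) / m
  if (as_percent) 100 * out else out
}

#' Per-group trait summaries
#'
#' Arithmetic mean and sample standard deviation of each trait within each
#' group (cultivar, subpopulation, ...), the shape used to compare growth
#' potential and within-cultivar consistency across genotypes. Groups of
#' size 1 report NA (not 0) for the standard deviation.
#'
#' @param records data.frame of per-plant trait records (e.g. from
#'   [phenotype_image()]); non-numeric columns are ignored.
#' @param groups vector of group labels, one per record row.
#' @param traits character vector of trait columns to summarize; default
#'   all numeric columns except id/row/col.
#' @return long-format data.frame with columns group, trait, n, mean, sd --
#'   directly usable for summary tables or box plots.
#' @export
group_summary <- function(records, groups, traits = NULL) {
  stopifnot(nrow(records) == length(groups))
  if (anyNA(groups)) stop("every record must be labeled with a group")
  if (is.null(traits)) {
    num <- vapply(records, is.numeric, logical(1))
    traits <- setdiff(names(records)[num], c("id", "row", "col"))
  }
  out <- list()
  for (g in unique(groups)) {
    sub <- records[groups == g, , drop = FALSE]
    for (tr in traits) {
      v <- sub[[tr]]
      v <- v[!is.na(v)]
      out[[length(out) + 1]] <- data.frame(
        group = g, trait = tr, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) >= 2) sd(v) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Pivot a group summary to one row per group
#'
#' @param summary long-format output of [group_summary()].
#' @return data.frame with `<trait>_mean` / `<trait>_sd` columns.
#' @export
summary_wide <- function(summary) {
  groups <- unique(summary$group)
  traits <- unique(summary$trait)
  out <- data.frame(group = groups)
  for (tr in traits) {
    sub <- summary[summary$trait == tr, ]
    out[[paste0(tr, "_mean")]] <- sub$mean[match(groups, sub$group)]
    out[[paste0(tr, "_sd")]] <- sub$sd[match(groups, sub$group)]
  }
  out
}
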