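#' Per-group direction counts and proportions
#'
#' Tabulates flow-direction labels per subject group and overall, as in a
#' cohort table of antegrade/retrograde (or upward/downward) counts.
#' Proportions are computed in exact rational form (`count / total`) and
#' formatted separately by [format_percent()].
#'
#' @param records Data frame with one row per subject, containing at least
#'   `direction` and `site` columns; a `group` column is used when present,
#'   otherwise all subjects form one group.
#' @param site Site the records must all share (`"aqueduct"` or `"ccj"`).
#' @return Data frame with columns `group`, `direction`, `n`, `total`,
#'   `proportion` and `percent` (formatted to one decimal); includes an
#'   `"overall"` group. Rows ordered by group then direction.
#' @export
direction_counts <- function(records, site = c("aqueduct", "ccj")) {
  site <- match.arg(site)
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            "direction" %in% names(records))
  if ("site" %in% names(records) && !all(records$site == site))
    stop("records mix sites; expected all '", site, "'")
  if (!("group" %in% names(records))) records$group <- "all"
  tally <- function(df, gname) {
    counts <- table(df$direction)
    data.frame(group = gname, direction = names(counts),
               n = as.integer(counts), total = nrow(df),
               proportion = as.integer(counts) / nrow(df),
               percent = format_percent(as.integer(counts) / nrow(df)),
               stringsAsFactors = FALSE)
  }
  per_group <- lapply(sort(unique(records$group)), function(g)
    tally(records[records$group == g, , drop = FALSE], g))
  out <- rbind(do.call(rbind, per_group), tally(records, "overall"))
  out[order(out$group, out$direction), , drop = FALSE]
}

#' Format a proportion as a percentage, one decimal
#'
#' Rounds half away from zero (0.625 -> "62.5", 0.375 -> "37.5"), the usual
#' clinical-table convention, rather than IEEE round-half-even.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Character vector like `"62.5"`.
#' @export
format_percent <- function(p) {
  x <- p * 100
  rounded <- sign(x) * floor(abs(x) * 10 + 0.5) / 10
  sprintf("%.1f", rounded)
}

#' Per-group mean and SD (or median and range) of a metric
#'
#' @param records Data frame with one row per subject; a `group` column is
#'   used when present, otherwise all records form one group.
#' @param field Name of the numeric column to summarise (e.g.
#'   `"net_mL_per_min"` or a covariate).
#' @param stat `"mean_sd"` (sample SD, n-1 denominator) or
#'   `"median_range"`.
#' @return Data frame with one row per group: `group`, `n`, and either
#'   `mean`/`sd` or `median`/`min`/`max`.
#' @export
group_summary <- function(records, field, stat = c("mean_sd",
                                                   "median_range")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  if (!(field %in% names(records)))
    stop("no column '", field, "' in records")
  if (!is.numeric(records[[field]]))
    stop("column '", field, "' is not numeric")
  if (!("group" %in% names(records))) records$group <- "all"
  groups <- sort(unique(records$group))
  rows <- lapply(groups, function(g) {
    x <- records[[field]][records$group == g]
    if (length(x) == 0L) stop("group '", g, "' has no records")
    if (stat == "mean_sd") {
      data.frame(group = g, n = length(x), mean = mean(x),
                 sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group = g, n = length(x), median = stats::median(x),
                 min = min(x), max = max(x), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Pearson correlation between net flow and a covariate
#'
#' Product-moment correlation between the net flow column and a covariate
#' (e.g. ventricular volume), with listwise deletion of records missing
#' either value, as used for flow-versus-volume scatter plots.
#'
#' @param records Data frame with one row per subject.
#' @param covariate Name of the covariate column.
#' @param flow_field Net-flow column to correlate (default
#'   `"net_mL_per_min"`).
#' @return A list with `r` (Pearson correlation), `n` (pairs used after
#'   deletion), and the two column names.
#' @export
flow_volume_correlation <- function(records, covariate,
                                    flow_field = "net_mL_per_min") {
  stopifnot(is.data.frame(records))
  for (cn in c(covariate, flow_field))
    if (!(cn %in% names(records))) stop("no column '", cn, "' in records")
  x <- records[[flow_field]]
  y <- records[[covariate]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs, have ", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in '", if (stats::sd(x) == 0) flow_field
         else covariate, "'; correlation undefined")
  list(r = stats::cor(x, y, method = "pearson"), n = length(x),
       flow_field = flow_field, covariate = covariate)
}
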