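#' Validate a long-format metric table
#'
#' The batch container consumed by the statistics layer: one row per
#' (sample, timepoint, metric) with columns `sample_id`, `group`,
#' `timepoint`, `metric`, `value` (and optionally `unit`). Each input row
#' is treated as one experimental unit.
#'
#' @param table a data frame.
#' @return The table, invisibly, after validation.
#' @export
check_metric_table <- function(table) {
  need <- c("sample_id", "group", "metric", "value")
  if (!all(need %in% names(table)))
    stop_beatkit("bad_table", paste("metric table needs columns:",
                                    paste(need, collapse = ", ")))
  if (!"timepoint" %in% names(table)) table$timepoint <- ""
  key <- paste(table$sample_id, table$timepoint, table$metric, sep = "\r")
  if (anyDuplicated(key))
    stop_beatkit("duplicate_rows", "(sample_id, timepoint, metric) must be unique")
  if (!is.numeric(table$value))
    stop_beatkit("non_numeric", "metric values must be numeric")
  if ("unit" %in% names(table)) {
    by_metric <- tapply(table$unit, table$metric, function(u) length(unique(u)))
    if (any(by_metric > 1))
      stop_beatkit("mixed_units", "a metric name carries more than one unit")
  }
  invisible(table)
}

metric_values <- function(table, metric) {
  check_metric_table(table)
  sub <- table[table$metric == metric & is.finite(table$value), , drop = FALSE]
  if (nrow(sub) == 0)
    stop_beatkit("no_data", paste0("no finite values for metric ", metric))
  split(sub$value, factor(sub$group, levels = sort(unique(sub$group))))
}

#' Per-group mean and standard deviation
#'
#' Summaries as mean +/- SD with the sample (n-1 denominator) SD. A group
#' with a single value has no spread estimate: its SD is reported as 0 with
#' `n = 1` flagging the degeneracy.
#'
#' @param table a metric table (see [check_metric_table()]).
#' @param metric metric name to summarize.
#' @return Data frame with `group`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(table, metric) {
  vals <- metric_values(table, metric)
  out <- data.frame(
    group = names(vals),
    n = vapply(vals, length, integer(1)),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1) sd(v) else 0, numeric(1)),
    row.names = NULL
  )
  out
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance computed from sums
#' of squares: `F` is the between-group mean square over the within-group
#' mean square, with `(k-1, N-k)` degrees of freedom. The fully degenerate
#' case (zero between- and within-group variance) has no defined p-value
#' and is flagged.
#'
#' @inheritParams summarize_groups
#' @return List of class `anova_result`: `f`, `p`, `df1`, `df2`, `ss_between`,
#'   `ss_within`, `degenerate`.
#' @export
one_way_anova <- function(table, metric) {
  vals <- metric_values(table, metric)
  k <- length(vals)
  ns <- vapply(vals, length, integer(1))
  if (k < 2) stop_beatkit("too_few_groups", "ANOVA needs at least 2 groups")
  if (any(ns < 2)) stop_beatkit("too_few_samples", "every group needs n >= 2")
  N <- sum(ns)
  x <- unlist(vals, use.names = FALSE)
  grand <- mean(x)
  means <- vapply(vals, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  degenerate <- ssb == 0 && ssw == 0
  f <- if (degenerate) NA_real_ else (ssb / (k - 1)) / (ssw / (N - k))
  p <- if (degenerate) NA_real_ else pf(f, k - 1, N - k, lower.tail = FALSE)
  structure(list(f = f, p = p, df1 = k - 1, df2 = N - k,
                 ss_between = ssb, ss_within = ssw, degenerate = degenerate),
            class = "anova_result")
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' All unordered pairwise group contrasts with studentized-range adjusted
#' p-values. Balanced designs reduce to the standard Tukey procedure;
#' unbalanced groups use the Tukey-Kramer standard error
#' `sqrt(MSE/2 * (1/n_a + 1/n_b))`. Significance is flagged at two-tailed
#' 0.05 on the unrounded p-value.
#'
#' @inheritParams summarize_groups
#' @param alpha significance level for the flag. Default 0.05.
#' @return Data frame of class `tukey_result`: `group_a`, `group_b`,
#'   `diff` (mean of b minus mean of a), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(table, metric, alpha = 0.05) {
  vals <- metric_values(table, metric)
  k <- length(vals)
  ns <- vapply(vals, length, integer(1))
  if (k < 2) stop_beatkit("too_few_groups", "Tukey needs at least 2 groups")
  if (any(ns < 2)) stop_beatkit("too_few_samples", "every group needs n >= 2")
  N <- sum(ns)
  means <- vapply(vals, mean, numeric(1))
  mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1))) / (N - k)
  pairs <- utils::combn(names(vals), 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    diff = NA_real_, p_adj = NA_real_, significant = NA)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    d <- means[b] - means[a]
    se <- sqrt(mse / 2 * (1 / ns[a] + 1 / ns[b]))
    if (se == 0) {
      p <- if (d == 0) NA_real_ else 0
    } else {
      p <- ptukey(abs(d) / se, nmeans = k, df = N - k, lower.tail = FALSE)
    }
    out$diff[i] <- d
    out$p_adj[i] <- p
    out$significant[i] <- if (is.na(p)) NA else p < alpha
  }
  structure(out, class = c("tukey_result", "data.frame"))
}

#' Full group comparison for one metric
#'
#' Mean +/- SD summaries, one-way ANOVA, and Tukey post hoc contrasts in
#' one bundle, mirroring the statistical reporting used for grouped beating
#' and calcium read-outs.
#'
#' @inheritParams tukey_hsd
#' @return List of class `comparison_result`: `metric`, `summary`,
#'   `anova`, `tukey`.
#' @export
compare_groups <- function(table, metric, alpha = 0.05) {
  structure(list(metric = metric,
                 summary = summarize_groups(table, metric),
                 anova = one_way_anova(table, metric),
                 tukey = tukey_hsd(table, metric, alpha)),
            class = "comparison_result")
}

# Recursively sort named list keys so serialized reports are byte-stable.
sort_keys <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm, method = "radix")]
    return(lapply(x, sort_keys))
  }
  x
}

#' Write a metrics object as deterministic JSON
#'
#' Named lists are serialized with sorted keys and full numeric precision,
#' so the same inputs always produce byte-identical files.
#'
#' @param x a named list (metrics, report, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(sort_keys(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Build the pipeline report bundle
#'
#' Collects per-sample metrics, group summaries and comparison results into
#' one JSON document (sorted keys, deterministic bytes for fixed inputs)
#' plus a long-format CSV of the per-sample metrics.
#'
#' @param sample_metrics named list: per sample, a named list of metric
#'   values (for example a [beat_metrics()]).
#' @param comparisons list of [compare_groups()] results (may be empty).
#' @param config configuration echo to embed.
#' @param seeds seeds used, for provenance.
#' @param path_json,path_csv output file paths (`NULL` to skip writing).
#' @return The report list, invisibly.
#' @export
build_report <- function(sample_metrics, comparisons = list(), config = list(),
                         seeds = NULL, path_json = NULL, path_csv = NULL) {
  comp_out <- lapply(comparisons, function(cr) {
    list(metric = cr$metric,
         summary = cr$summary,
         anova = list(f = cr$anova$f, p = cr$anova$p, df1 = cr$anova$df1,
                      df2 = cr$anova$df2, degenerate = cr$anova$degenerate),
         tukey = as.data.frame(cr$tukey))
  })
  report <- list(
    schema_version = "1.0",
    software = list(package = "beatkit",
                    version = as.character(packageVersion("beatkit"))),
    config = config,
    seeds = seeds,
    samples = lapply(sample_metrics, function(m) m[order(names(m), method = "radix")]),
    comparisons = comp_out
  )
  if (!is.null(path_json)) write_metrics_json(report, path_json)
  if (!is.null(path_csv)) {
    rows <- do.call(rbind, lapply(names(sample_metrics), function(sid) {
      m <- sample_metrics[[sid]]
      num <- vapply(m, function(v) is.numeric(v) || is.logical(v), logical(1))
      data.frame(sample_id = sid, metric = names(m)[num],
                 value = as.numeric(unlist(m[num])), row.names = NULL)
    }))
    write.csv(rows[order(rows$sample_id, rows$metric, method = "radix"), ],
              path_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
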