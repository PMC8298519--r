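#' Features excluded by the fixed modelling-subset rule
#'
#' The 12 catalogue features dropped by the reference screening of the
#' original clinical force dataset (duration, minimum, coefficient of
#' variation, skewness and its 2SE significance, first-derivative SD,
#' peak count, cycle length, spikiness, the KPSS stationarity statistic,
#' the first autocorrelation zero and ACF E10), leaving a 25-feature
#' modelling subset.
#'
#' @export
FIXED_EXCLUDED_FEATURES <- c(
  "duration", "min", "cv", "skewness", "skewness_2se", "d1_sd",
  "peak_count", "cycle_length", "spikiness", "kpss_stat",
  "acf_first_zero_time", "acf_e10")

#' Per-feature two-way ANOVA screen (experience x task)
#'
#' For every catalogue feature, fits `value ~ experience * task` on
#' complete cases and reports Type II F statistics and p-values for both
#' main effects and the interaction. Type II sums of squares are used
#' because realistic segment tables are heavily unbalanced across cells.
#' Segments are treated as independent observations.
#'
#' @param features A [extract_features()] table with both factors at >= 2
#'   levels.
#' @param adjust_p If `TRUE`, Benjamini-Hochberg adjust each p-value
#'   column across features. Default `FALSE` (raw per-feature p-values).
#' @return An object of class `screening_report` whose `rows` element has
#'   one row per feature: `feature`, `f_experience`, `p_experience`,
#'   `f_task`, `p_task`, `f_interaction`, `p_interaction`, `n_used`.
#' @export
anova_screen <- function(features, adjust_p = FALSE) {
  stopifnot(inherits(features, "feature_table"))
  if (length(unique(features$experience)) < 2L)
    stop("configuration error: experience factor needs 2 levels")
  if (length(unique(features$task)) < 2L)
    stop("configuration error: task factor needs at least 2 levels")
  rows <- lapply(FEATURE_CATALOGUE, function(f) {
    df <- data.frame(value = features[[f]],
                     experience = factor(features$experience),
                     task = factor(features$task))
    df <- df[stats::complete.cases(df), , drop = FALSE]
    na_row <- data.frame(feature = f, f_experience = NA_real_,
                         p_experience = NA_real_, f_task = NA_real_,
                         p_task = NA_real_, f_interaction = NA_real_,
                         p_interaction = NA_real_, n_used = nrow(df))
    if (nrow(df) < 5L || var(df$value) == 0 ||
        nlevels(droplevels(df$experience)) < 2L ||
        nlevels(droplevels(df$task)) < 2L)
      return(na_row)
    df$experience <- droplevels(df$experience)
    df$task <- droplevels(df$task)
    tab <- tryCatch(
      suppressMessages(
        car::Anova(lm(value ~ experience * task, data = df), type = 2)),
      error = function(e) NULL)
    if (is.null(tab)) return(na_row)
    pick <- function(term, col) {
      i <- match(term, rownames(tab))
      if (is.na(i)) NA_real_ else tab[i, col]
    }
    data.frame(feature = f,
               f_experience = pick("experience", "F value"),
               p_experience = pick("experience", "Pr(>F)"),
               f_task = pick("task", "F value"),
               p_task = pick("task", "Pr(>F)"),
               f_interaction = pick("experience:task", "F value"),
               p_interaction = pick("experience:task", "Pr(>F)"),
               n_used = nrow(df))
  })
  rows <- do.call(rbind, rows)
  if (adjust_p)
    for (col in c("p_experience", "p_task", "p_interaction"))
      rows[[col]] <- stats::p.adjust(rows[[col]], method = "BH")
  structure(list(rows = rows, adjust_p = adjust_p),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d features screened\n", nrow(x$rows)))
  sig <- x$rows[!is.na(x$rows$p_experience) & x$rows$p_experience < 0.05,
                "feature"]
  cat("  experience effect p < 0.05:",
      if (length(sig)) paste(sig, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Pairwise task contrasts for one feature
#'
#' All pairwise task-mean differences with Tukey HSD adjusted p-values,
#' from a one-way analysis of the feature across tasks (complete cases).
#'
#' @param features A [extract_features()] table.
#' @param feature_name A catalogue feature name.
#' @return Data frame with `contrast`, `difference`, `p_adj`.
#' @export
posthoc_tasks <- function(features, feature_name) {
  stopifnot(inherits(features, "feature_table"))
  if (!feature_name %in% FEATURE_CATALOGUE)
    stop("unknown feature: ", feature_name)
  df <- data.frame(value = features[[feature_name]],
                   task = factor(features$task))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$task <- droplevels(df$task)
  if (nlevels(df$task) < 2L)
    stop("configuration error: task factor needs at least 2 levels")
  tk <- TukeyHSD(aov(value ~ task, data = df))$task
  data.frame(contrast = rownames(tk),
             difference = unname(tk[, "diff"]),
             p_adj = unname(tk[, "p adj"]),
             stringsAsFactors = FALSE)
}

#' Select the modelling feature subset
#'
#' @param report A [anova_screen()] result (used by `threshold` mode).
#' @param mode `"fixed"` drops the 12 features in
#'   [FIXED_EXCLUDED_FEATURES], returning the canonical 25-feature
#'   modelling subset; `"threshold"` retains features whose experience or
#'   task main-effect p-value is below `alpha`.
#' @param alpha Significance threshold for `threshold` mode. Default 0.05.
#' @return Ordered character vector of retained feature names (catalogue
#'   order).
#' @export
select_model_subset <- function(report = NULL,
                                mode = c("fixed", "threshold"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "fixed")
    return(setdiff(FEATURE_CATALOGUE, FIXED_EXCLUDED_FEATURES))
  stopifnot(inherits(report, "screening_report"))
  rows <- report$rows
  keep <- !is.na(rows$p_experience) & rows$p_experience < alpha |
    !is.na(rows$p_task) & rows$p_task < alpha
  FEATURE_CATALOGUE[FEATURE_CATALOGUE %in% rows$feature[keep]]
}

#' Write a screening report
#'
#' Writes the ANOVA rows as flat CSV and, when `json_path` is given, the
#' full report (rows plus selected subset) as JSON.
#'
#' @param report A [anova_screen()] result.
#' @param csv_path CSV output path.
#' @param json_path Optional JSON output path.
#' @param selected Optional character vector of selected features to embed.
#' @return `csv_path`, invisibly.
#' @export
write_screening_report <- function(report, csv_path, json_path = NULL,
                                   selected = NULL) {
  stopifnot(inherits(report, "screening_report"))
  write.csv(report$rows, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(list(rows = report$rows, selected = selected),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  invisible(csv_path)
}
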