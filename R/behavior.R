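# Behavioral statistics for fear-renewal and contextual experiments:
# stage aggregation, extinction-criterion filtering, planned pooled-variance
# t-tests at stimulation timepoints, control pooling, and timecourse
# comparisons.

#' Per-animal stage means over raw epochs
#'
#' Aggregates epoch-level freezing rows (e.g. `CS1`..`CS4`) into named
#' stages by per-animal arithmetic mean (e.g. `CS_1_4` = mean over the
#' first four CS presentations).  An animal missing any epoch of a stage is
#' excluded from that stage with a warning.
#'
#' @param table freezing table with epoch labels in the `stage` column.
#' @param stage_def named list mapping each output stage to its epoch
#'   labels, e.g. `list(CS_1_4 = c("CS1","CS2","CS3","CS4"))`.
#' @return freezing table with one row per animal and output stage.
#' @export
stage_means <- function(table, stage_def) {
  validate_freezing(table)
  stopifnot_param(is.list(stage_def) && length(stage_def) >= 1L &&
                    !is.null(names(stage_def)),
                  "stage_def must be a named list of epoch sets")
  vocab <- unique(table$stage)
  out <- list()
  for (s in names(stage_def)) {
    epochs <- stage_def[[s]]
    unk <- setdiff(epochs, vocab)
    if (length(unk)) {
      of_stop("invalid_parameter",
              "unknown epoch label(s) %s for stage '%s'; table has: %s",
              paste(unk, collapse = ", "), s, paste(vocab, collapse = ", "))
    }
    sub <- table[table$stage %in% epochs, , drop = FALSE]
    counts <- table(sub$animal_id)
    complete <- names(counts)[counts == length(epochs)]
    dropped <- setdiff(unique(sub$animal_id), complete)
    if (length(dropped)) {
      warning(sprintf("stage '%s': animal(s) %s missing epochs, excluded",
                      s, paste(dropped, collapse = ", ")))
    }
    sub <- sub[sub$animal_id %in% complete, , drop = FALSE]
    if (!nrow(sub)) next
    agg <- aggregate(percent_freezing ~ animal_id + group, data = sub,
                     FUN = mean)
    agg$stage <- s
    out[[s]] <- agg[, c("animal_id", "group", "stage", "percent_freezing")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the extinction criterion
#'
#' Extinction training continues until the mean freezing over the first
#' four CS presentations drops strictly below `threshold_pct`; animals not
#' reaching criterion by day `max_days` are excluded.
#'
#' @param records data.frame with columns `animal_id`, `day`,
#'   `mean_freezing` (per-day mean over the first four CS presentations,
#'   percent).
#' @param threshold_pct criterion threshold (default 60, strict `<`).
#' @param max_days last permissible day of extinction training (default 7).
#' @return data.frame with one row per animal: `animal_id`,
#'   `days_to_criterion` (`NA` if never reached within the recorded days),
#'   `included`.
#' @export
extinction_filter <- function(records, threshold_pct = 60, max_days = 7) {
  stopifnot_param(is.data.frame(records) && nrow(records) >= 1L,
                  "records must be a non-empty data.frame")
  need <- c("animal_id", "day", "mean_freezing")
  miss <- setdiff(need, names(records))
  stopifnot_param(length(miss) == 0L, "records missing column(s): %s",
                  paste(miss, collapse = ", "))
  by_animal <- split(records, records$animal_id)
  out <- lapply(names(by_animal), function(a) {
    r <- by_animal[[a]][order(by_animal[[a]]$day), , drop = FALSE]
    hit <- which(r$mean_freezing < threshold_pct)
    day <- if (length(hit)) r$day[hit[1]] else NA_integer_
    data.frame(animal_id = a, days_to_criterion = day,
               included = !is.na(day) && day <= max_days,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Planned unpaired (pooled-variance) t-test
#'
#' Student's two-sample t-test with pooled variance and
#' `df = n1 + n2 - 2`, the test matching the reported degrees of freedom
#' for groups of 7 and 7 (df = 12).  Degenerate zero-variance input: equal
#' means give `t = 0, p = 1`; unequal means are an error.
#'
#' @param values_a,values_b numeric group values (each `n >= 2`).
#' @param stage optional stage label carried into the result.
#' @return an object of class `stage_comparison`: `stage`, `n1`, `n2`,
#'   `mean1`, `mean2`, `sem1`, `sem2`, `t`, `df`, `p`.
#' @export
planned_ttest <- function(values_a, values_b, stage = NA_character_) {
  stopifnot_param(is.numeric(values_a) && is.numeric(values_b),
                  "group values must be numeric")
  stopifnot_param(length(values_a) >= 2L && length(values_b) >= 2L,
                  "each group needs at least 2 values")
  stopifnot_param(all(is.finite(values_a)) && all(is.finite(values_b)),
                  "group values must be finite")
  n1 <- length(values_a)
  n2 <- length(values_b)
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      tt <- list(statistic = 0, parameter = n1 + n2 - 2, p.value = 1)
    } else {
      of_stop("degenerate_data",
              "zero pooled variance with unequal group means")
    }
  } else {
    ht <- t.test(values_a, values_b, var.equal = TRUE)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(stage = stage, n1 = n1, n2 = n2,
                 mean1 = mean(values_a), mean2 = mean(values_b),
                 sem1 = sd(values_a) / sqrt(n1),
                 sem2 = sd(values_b) / sqrt(n2),
                 t = tt$statistic, df = tt$parameter, p = tt$p.value),
            class = "stage_comparison")
}

#' @export
print.stage_comparison <- function(x, ...) {
  cat(sprintf("<stage_comparison>%s t(%g) = %.3f, p = %.4g (n = %d vs %d)\n",
              if (is.na(x$stage)) "" else paste0(" ", x$stage, ":"),
              x$df, x$t, x$p, x$n1, x$n2))
  invisible(x)
}

#' Two-sided p-value from a t statistic
#'
#' `p = 2 P(T >= |t|)` under the central Student t distribution.
#'
#' @param t t statistic (vectorized).
#' @param df degrees of freedom, `>= 1`.
#' @return two-sided p-value(s).
#' @export
t_to_p <- function(t, df) {
  stopifnot_param(all(df >= 1), "df must be at least 1")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Check whether the two control groups can be pooled
#'
#' Runs [planned_ttest()] between `control_GFP` and `control_nolaser` at
#' every stage both share.  If no stage differs at `alpha`, the groups are
#' relabeled `pooled_control`; otherwise the table is returned unpooled
#' with the per-stage report.
#'
#' @param table freezing table containing both control groups.
#' @param alpha pooling threshold on the minimum per-stage p (default
#'   0.05).
#' @return list with `comparisons` (data.frame: stage, t, df, p), `pooled`
#'   (logical), and `table` (relabeled when pooled).  Row counts and animal
#'   identities are preserved either way.
#' @export
pool_controls_check <- function(table, alpha = 0.05) {
  validate_freezing(table)
  ctrl <- c("control_GFP", "control_nolaser")
  missing_grp <- setdiff(ctrl, unique(table$group))
  if (length(missing_grp)) {
    of_stop("invalid_parameter", "control group(s) absent: %s",
            paste(missing_grp, collapse = ", "))
  }
  g1 <- table[table$group == ctrl[1], , drop = FALSE]
  g2 <- table[table$group == ctrl[2], , drop = FALSE]
  stages <- intersect(unique(g1$stage), unique(g2$stage))
  stopifnot_param(length(stages) >= 1L, "control groups share no stage")
  comp <- do.call(rbind, lapply(stages, function(s) {
    ct <- planned_ttest(g1$percent_freezing[g1$stage == s],
                        g2$percent_freezing[g2$stage == s], stage = s)
    data.frame(stage = s, n1 = ct$n1, n2 = ct$n2, t = ct$t, df = ct$df,
               p = ct$p, stringsAsFactors = FALSE)
  }))
  pooled <- min(comp$p) > alpha
  out <- table
  if (pooled) out$group[out$group %in% ctrl] <- "pooled_control"
  list(comparisons = comp, pooled = pooled, table = out)
}

#' Stage-by-stage group comparison along the protocol timecourse
#'
#' Planned pooled-variance t-tests of `ChR2` against `pooled_control` at
#' each requested stage.  No multiple-comparison correction is applied by
#' default (the planned-comparison design maximizes sensitivity at the
#' stimulation timepoints); corrected p-values are reported alongside the
#' raw ones when requested.
#'
#' @param table freezing table with groups `ChR2` and `pooled_control`
#'   (run [pool_controls_check()] first if needed).
#' @param stages stage labels to compare; default all shared stages, in
#'   table order.
#' @param correction `"none"`, `"bonferroni"` or `"holm"`.
#' @return data.frame with one row per stage: group sizes, means, SEMs,
#'   `t`, `df`, `p`, and `p_adj`.
#' @export
timecourse_compare <- function(table, stages = NULL,
                               correction = c("none", "bonferroni", "holm")) {
  correction <- match.arg(correction)
  validate_freezing(table)
  groups <- unique(table$group)
  if (!all(c("ChR2", "pooled_control") %in% groups)) {
    of_stop("invalid_parameter",
            "table must contain groups ChR2 and pooled_control (found: %s); run pool_controls_check() first",
            paste(groups, collapse = ", "))
  }
  a <- table[table$group == "ChR2", , drop = FALSE]
  b <- table[table$group == "pooled_control", , drop = FALSE]
  shared <- intersect(unique(a$stage), unique(b$stage))
  if (is.null(stages)) stages <- shared
  unk <- setdiff(stages, shared)
  if (length(unk)) {
    of_stop("invalid_parameter", "stage(s) %s not present in both groups (shared: %s)",
            paste(unk, collapse = ", "), paste(shared, collapse = ", "))
  }
  rows <- lapply(stages, function(s) {
    ct <- planned_ttest(a$percent_freezing[a$stage == s],
                        b$percent_freezing[b$stage == s], stage = s)
    data.frame(stage = s, n1 = ct$n1, n2 = ct$n2, mean1 = ct$mean1,
               mean2 = ct$mean2, sem1 = ct$sem1, sem2 = ct$sem2,
               t = ct$t, df = ct$df, p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "none") out$p else p.adjust(out$p, correction)
  out
}
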