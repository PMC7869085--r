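#' Mismatch (difference-wave) peak features for one subject
#'
#' The difference wave is deviant minus standard. Within the analysis
#' window the peak is the extremum of largest absolute amplitude; its
#' latency is the time of that sample, taking the earliest sample among
#' equal-magnitude extrema. Features are returned per node plus for the
#' node-averaged timecourse.
#'
#' @param data An [evoked_dataset()].
#' @param window Analysis window in ms. The conventional mismatch window is
#'   80-200 ms; 80-300 ms is used when averaging over sources.
#' @return Data frame with columns node, amplitude, latency_ms; the last
#'   row (`node = "mean"`) is the node-averaged waveform.
#' @export
difference_wave_peaks <- function(data, window = c(80, 200)) {
  stopifnot(inherits(data, "evoked_dataset"))
  if (window[1] < min(data$time) || window[2] > max(data$time))
    stop("analysis window lies outside the epoch")
  diffw <- data$data$deviant - data$data$standard
  sel <- data$time >= window[1] & data$time <= window[2]
  tw <- data$time[sel]
  peak1 <- function(w) {
    i <- which.max(abs(w)) # earliest among ties
    c(amplitude = w[i], latency_ms = tw[i])
  }
  per_node <- t(apply(diffw[, sel, drop = FALSE], 1, peak1))
  avg <- peak1(colMeans(diffw[, sel, drop = FALSE]))
  out <- rbind(per_node, mean = avg)
  data.frame(node = rownames(out), amplitude = out[, "amplitude"],
             latency_ms = out[, "latency_ms"], row.names = NULL)
}

#' Per-condition peak features of the node-averaged response
#'
#' Peak amplitude (largest absolute extremum) and latency of each
#' condition's node-averaged waveform, used for the group-by-condition
#' analysis of variance.
#'
#' @inheritParams difference_wave_peaks
#' @return Data frame with columns condition, amplitude, latency_ms.
#' @export
condition_peaks <- function(data, window = c(80, 300)) {
  stopifnot(inherits(data, "evoked_dataset"))
  sel <- data$time >= window[1] & data$time <= window[2]
  tw <- data$time[sel]
  rows <- lapply(names(data$data), function(cond) {
    w <- colMeans(data$data[[cond]][, sel, drop = FALSE])
    i <- which.max(abs(w))
    data.frame(condition = cond, amplitude = w[i], latency_ms = tw[i])
  })
  do.call(rbind, rows)
}

#' Cohort-level mismatch feature table
#'
#' @param datasets List of [evoked_dataset()] objects.
#' @param window Analysis window (ms).
#' @return Data frame: subject, group, condition, amplitude, latency_ms
#'   (per-condition node-averaged peaks, two rows per subject).
#' @export
cohort_condition_features <- function(datasets, window = c(80, 300)) {
  do.call(rbind, lapply(datasets, function(d) {
    cbind(subject = d$subject, group = d$group,
          condition_peaks(d, window))
  }))
}

#' Group-by-condition (2 x 2) mixed ANOVA on evoked features
#'
#' Mixed-design analysis of variance with group as the between-subject
#' factor and condition (standard vs deviant) as the within-subject factor,
#' applied separately to peak amplitude and latency. Reports the
#' interaction F and p, plus post-hoc paired t-tests of the
#' deviant-vs-standard difference within each group.
#'
#' @param features Long data frame with columns subject, group, condition
#'   and the measures (amplitude, latency_ms).
#' @param measures Columns to analyse.
#' @return Named list per measure: `F` (interaction), `p`, `df`, and
#'   `posthoc` (per-group paired t-tests).
#' @export
group_condition_anova <- function(features,
                                  measures = c("amplitude", "latency_ms")) {
  features$group <- factor(features$group)
  features$condition <- factor(features$condition)
  features$subject <- factor(features$subject)
  if (nlevels(features$group) != 2 || nlevels(features$condition) != 2)
    stop("need exactly two groups and two conditions")
  counts <- table(features$group, features$condition)
  if (any(counts < 2)) stop("every group x condition cell needs >= 2 subjects")

  out <- list()
  for (m in measures) {
    d <- features[, c("subject", "group", "condition", m)]
    names(d)[4] <- "value"
    fit <- aov(value ~ group * condition + Error(subject/condition), data = d)
    within <- summary(fit)[["Error: subject:condition"]][[1]]
    row <- grep("group:condition", rownames(within))
    Fv <- within[row, "F value"]
    pv <- within[row, "Pr(>F)"]
    posthoc <- lapply(levels(d$group), function(g) {
      dg <- d[d$group == g, ]
      wide <- merge(dg[dg$condition == levels(d$condition)[1], c("subject", "value")],
                    dg[dg$condition == levels(d$condition)[2], c("subject", "value")],
                    by = "subject")
      tt <- tryCatch(t.test(wide$value.y, wide$value.x, paired = TRUE),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      data.frame(group = g, t = unname(tt$statistic), p = tt$p.value)
    })
    out[[m]] <- list(F = unname(Fv), p = unname(pv),
                     df = unname(within[row, "Df"]),
                     posthoc = do.call(rbind, posthoc))
  }
  out
}

#' Group tests on posterior model parameters
#'
#' Given per-subject posterior parameter tables, runs a group-by-parameter
#' analysis of variance followed by per-parameter independent two-sample
#' t-tests (uncorrected, as is conventional for these laminar hypotheses;
#' an optional FDR-adjusted column can be requested). Parameters constant
#' across all subjects are skipped with a notice.
#'
#' @param tables Data frame with columns subject, group, parameter, mean
#'   (stacked [posterior_summary()] tables, e.g. via
#'   [stack_posterior_tables()]).
#' @param fdr Add an FDR-adjusted p-value column.
#' @return List with `anova` (group x parameter interaction) and `tests`
#'   (per-parameter t, p, direction: positive means higher in patients).
#' @export
parameter_group_tests <- function(tables, fdr = FALSE) {
  tables$group <- factor(tables$group)
  if (nlevels(tables$group) != 2) stop("need exactly two groups")
  g2 <- levels(tables$group)[2]

  fit <- aov(mean ~ group * parameter, data = tables)
  sm <- summary(fit)[[1]]
  row <- grep("group:parameter", rownames(sm))
  anova_res <- list(F = unname(sm[row, "F value"]),
                    p = unname(sm[row, "Pr(>F)"]))

  skipped <- character(0)
  rows <- lapply(split(tables, tables$parameter), function(d) {
    if (sd(d$mean) == 0) {
      skipped <<- c(skipped, d$parameter[1])
      return(NULL)
    }
    a <- d$mean[d$group == g2]       # patients (second level)
    b <- d$mean[d$group != g2]
    tt <- t.test(a, b)
    data.frame(parameter = d$parameter[1], t = unname(tt$statistic),
               p = tt$p.value, direction = sign(mean(a) - mean(b)))
  })
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  if (length(skipped))
    message("skipped constant parameters: ", paste(skipped, collapse = ", "))
  if (fdr) tests$p_fdr <- p.adjust(tests$p, "fdr")
  list(anova = anova_res, tests = tests, skipped = skipped)
}

#' Stack per-subject posterior summaries into a long table
#'
#' @param results List of [invert()] results (one per subject).
#' @param subjects,groups Subject ids and group labels.
#' @param which Parameter selector passed to [posterior_summary()].
#' @return Long data frame: subject, group, parameter, block, mean, sd.
#' @export
stack_posterior_tables <- function(results, subjects, groups,
                                   which = "J") {
  do.call(rbind, lapply(seq_along(results), function(i) {
    cbind(subject = subjects[i], group = groups[i],
          posterior_summary(results[[i]], which))
  }))
}
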