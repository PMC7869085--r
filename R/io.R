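#' Write / read evoked datasets as long-format CSV
#'
#' One row per subject, condition, node and sample; metadata (sampling
#' rate, node labels) is recoverable from the table itself.
#'
#' @param datasets List of [evoked_dataset()] objects.
#' @param path CSV path.
#' @return `path` invisibly; `read_evoked_csv()` returns the list of
#'   datasets.
#' @export
write_evoked_csv <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    do.call(rbind, lapply(names(d$data), function(cond) {
      m <- d$data[[cond]]
      data.frame(subject = d$subject, group = d$group, condition = cond,
                 node = rep(rownames(m), times = ncol(m)),
                 time_ms = rep(d$time, each = nrow(m)),
                 value = as.numeric(m))
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evoked_csv
#' @export
read_evoked_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$subject), function(ds) {
    time <- sort(unique(ds$time_ms))
    nodes <- unique(ds$node)
    fs <- round(1000 / stats::median(diff(time)))
    mats <- lapply(split(ds, ds$condition), function(dc) {
      m <- matrix(dc$value[order(dc$time_ms, match(dc$node, nodes))],
                  length(nodes), length(time),
                  dimnames = list(nodes, NULL))
      m
    })
    evoked_dataset(mats$standard, mats$deviant, time, fs, nodes,
                   subject = ds$subject[1], group = ds$group[1])
  })
  out[unique(df$subject)]
}

#' Write / read an evidence matrix as CSV (subjects x models)
#' @param ev An [evidence_matrix()].
#' @param path CSV path.
#' @export
write_evidence_csv <- function(ev, path) {
  df <- data.frame(subject = rownames(ev), unclass(ev), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_csv
#' @export
read_evidence_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject
  evidence_matrix(m)
}

#' Serialize a BMS result to JSON
#' @param result A `bms_result` or `greedy_search`.
#' @param path JSON path.
#' @export
write_bms_json <- function(result, path) {
  strip <- function(x) {
    if (inherits(x, "bms_result")) x <- unclass(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  jsonlite::write_json(strip(unclass(result)), path, digits = NA,
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write / read a parameter table as full-precision CSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' doubles round-trip bit-exactly.
#'
#' @param df Data frame (e.g. a [posterior_summary()] table).
#' @param path CSV path.
#' @export
write_parameter_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_parameter_csv
#' @param template Data frame whose column types the read should restore.
#' @export
read_parameter_csv <- function(path, template = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(template))
    for (j in names(df))
      if (is.double(template[[j]])) df[[j]] <- as.double(df[[j]])
  df
}

#' Write a prior specification (or any spec object) to YAML
#' @param x A spec-like list object.
#' @param path YAML path.
#' @export
write_spec_yaml <- function(x, path) {
  yaml::write_yaml(lapply(unclass(x), function(el)
    if (is.matrix(el)) apply(el, 1, identity, simplify = FALSE) else el),
    path)
  invisible(path)
}
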