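#' Labeled univariate time-series dataset
#'
#' An ordered collection of fixed-length scalar signals with integer class
#' labels. Labels follow the internal convention of contiguous integers
#' from 0; the original label strings are kept in `class_names` (so
#' `class_names[label + 1]` recovers the file's label). Signals are used as
#' distributed — no normalization is applied anywhere in the pipeline, and
#' one sample value corresponds to one simulation time-step (1 ms).
#'
#' @param signals numeric `n x T` matrix, one signal per row.
#' @param labels integer vector of 0-based labels, length n.
#' @param class_names character vector naming each label.
#' @param split `"train"` or `"test"` tag.
#' @return object of class `ts_dataset`.
#' @export
ts_dataset <- function(signals, labels, class_names = NULL, split = "train") {
  signals <- as.matrix(signals)
  labels <- as.integer(labels)
  stopifnot(nrow(signals) == length(labels))
  if (is.null(class_names)) {
    class_names <- as.character(sort(unique(labels)))
  }
  if (any(labels < 0 | labels >= length(class_names))) {
    stop_invalid("labels must lie in [0, n_classes)")
  }
  dimnames(signals) <- NULL
  structure(
    list(signals = signals, labels = labels,
         class_names = as.character(class_names), split = split),
    class = "ts_dataset")
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("<ts_dataset %s> %d samples x %d steps, %d classes (%s)\n",
              x$split, nrow(x$signals), ncol(x$signals),
              length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset a `ts_dataset`.
#' @return integer.
#' @export
n_samples <- function(dataset) nrow(dataset$signals)

relabel_contiguous <- function(raw_labels, split) {
  nm <- sort(unique(raw_labels))
  list(labels = match(raw_labels, nm) - 1L, class_names = as.character(nm))
}

load_ucr_tsv <- function(path, split) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  rows <- strsplit(trimws(lines), sep)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop_invalid("ragged row in ", path, " at line ", bad,
                 " (", lens[bad], " fields, expected ", lens[1], ")")
  }
  raw_labels <- vapply(rows, `[`, character(1), 1)
  vals <- vapply(rows, function(r) as.numeric(r[-1]), numeric(lens[1] - 1))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
  if (anyNA(m)) {
    stop_invalid("non-numeric signal value in ", path)
  }
  lab <- relabel_contiguous(raw_labels, split)
  ts_dataset(m, lab$labels, lab$class_names, split)
}

load_ucr_ts <- function(path, split) {
  lines <- readLines(path)
  data_at <- grep("^\\s*@data\\s*$", lines, ignore.case = TRUE)
  if (length(data_at) != 1) {
    stop_invalid("no single @data marker found in ", path)
  }
  body <- lines[(data_at + 1):length(lines)]
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "#")]
  parts <- strsplit(trimws(body), ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    bad <- which(lengths(parts) != 2)[1]
    stop_invalid("line ", data_at + bad, " of ", path,
                 " does not have a single ':' label separator")
  }
  vals <- lapply(parts, function(p) as.numeric(strsplit(p[1], ",")[[1]]))
  lens <- lengths(vals)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop_invalid("ragged series in ", path, " at data line ", bad)
  }
  raw_labels <- vapply(parts, function(p) trimws(p[2]), character(1))
  lab <- relabel_contiguous(raw_labels, split)
  ts_dataset(do.call(rbind, vals), lab$labels, lab$class_names, split)
}

load_ucr_arff <- function(path, split) {
  df <- foreign::read.arff(path)
  # by UCR convention the class attribute is the last column
  raw_labels <- as.character(df[[ncol(df)]])
  m <- as.matrix(df[, -ncol(df), drop = FALSE])
  lab <- relabel_contiguous(raw_labels, split)
  ts_dataset(m, lab$labels, lab$class_names, split)
}

#' Read a UCR-archive time-series file
#'
#' Supports three dialects: `"ts"` (the sktime `.ts` text format — header
#' lines, an `@data` marker, then `v1,v2,...,vT:label` lines), `"tsv"`
#' (label in the first column, values after, tab- or comma-separated), and
#' `"arff"`. Sample order follows file order; original labels are preserved
#' in `class_names` and recoded to contiguous 0-based integers.
#'
#' @param path file path.
#' @param dialect one of `"ts"`, `"tsv"`, `"arff"`.
#' @param split `"train"` or `"test"` tag for the returned dataset.
#' @return a [ts_dataset()].
#' @export
load_ucr <- function(path, dialect = c("tsv", "ts", "arff"), split = "train") {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  dialect <- match.arg(dialect)
  switch(dialect,
         tsv = load_ucr_tsv(path, split),
         ts = load_ucr_ts(path, split),
         arff = load_ucr_arff(path, split))
}

#' Write a dataset in the UCR TSV dialect
#'
#' Label first (the original class name), tab-separated values after; the
#' format [load_ucr()] reads back losslessly.
#'
#' @param dataset a `ts_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ucr_tsv <- function(dataset, path) {
  lab <- dataset$class_names[dataset$labels + 1L]
  lines <- vapply(seq_len(n_samples(dataset)), function(i) {
    paste(c(lab[i], format(dataset$signals[i, ], digits = 17,
                           scientific = FALSE, trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge the four abnormal ECG5000 classes into one
#'
#' The five-class ECG5000 labels (normal heartbeat plus four arrhythmia
#' types) are mapped to a binary task: the normal class (label `1` in the
#' archive files) becomes 0 and all four abnormal classes become 1. A
#' dataset that is already binary with class names `0`/`1` passes through
#' unchanged; any other label set is an error.
#'
#' @param dataset a `ts_dataset` with the five original classes.
#' @return binary `ts_dataset` with `class_names = c("0", "1")`.
#' @export
binarize_ecg5000 <- function(dataset) {
  stopifnot(inherits(dataset, "ts_dataset"))
  if (setequal(dataset$class_names, c("0", "1"))) {
    return(dataset)
  }
  if (length(dataset$class_names) != 5 || !("1" %in% dataset$class_names)) {
    stop_invalid("expected the 5 ECG5000 classes (labels 1..5); got: ",
                 paste(dataset$class_names, collapse = ", "))
  }
  normal <- dataset$class_names[dataset$labels + 1L] == "1"
  ts_dataset(dataset$signals, ifelse(normal, 0L, 1L),
             class_names = c("0", "1"), split = dataset$split)
}

#' Trim trailing samples to a batch-size multiple
#'
#' Drops the minimal number of trailing samples — `count %% batch_size` —
#' so the sample count divides evenly into batches, preserving order.
#' Applied once at load time, before any shuffling.
#'
#' @param dataset a `ts_dataset`.
#' @param batch_size batch size (>= 1).
#' @return trimmed `ts_dataset`.
#' @examples
#' # Ford-A train: 3601 samples, batch 40 -> 3600
#' @export
trim_to_batch <- function(dataset, batch_size) {
  stopifnot(inherits(dataset, "ts_dataset"), batch_size >= 1)
  n <- n_samples(dataset)
  keep <- n - (n %% batch_size)
  if (keep == n) return(dataset)
  ts_dataset(dataset$signals[seq_len(keep), , drop = FALSE],
             dataset$labels[seq_len(keep)],
             dataset$class_names, dataset$split)
}
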