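#' Read a delimited dataset into a feature matrix and response
#'
#' Reads a CSV/TSV with a header row, samples as rows (use
#' `transpose = TRUE` for gene-expression-style files with features as
#' rows), and one label column.  A label column with exactly two distinct
#' values is mapped to -1/+1 (the lexicographically, or numerically,
#' smaller value becomes -1; the mapping is reported via `message`); any
#' other numeric label column is passed through as a regression target.
#'
#' @param path file path.
#' @param label_col name of the label column (after transposition, if
#'   any).
#' @param delimiter field separator; `NULL` (default) infers `\t` vs `,`
#'   from the header line.
#' @param transpose read features-as-rows files.
#' @return list with `x` (numeric matrix, named columns), `y` (numeric
#'   response) and `label_map` (named -1/+1 vector, or `NULL` for
#'   pass-through labels).
#' @export
read_dataset <- function(path, label_col, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    hdr <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = delimiter,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (transpose) {
    rn <- df[[1L]]
    mat <- t(as.matrix(df[, -1L, drop = FALSE]))
    colnames(mat) <- rn
    df <- as.data.frame(mat, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!label_col %in% names(df)) stop("label column '", label_col, "' not found")
  lab <- df[[label_col]]
  feats <- df[, setdiff(names(df), label_col), drop = FALSE]
  for (j in seq_along(feats)) {
    v <- suppressWarnings(as.numeric(feats[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric feature cell at row %d, column '%s'",
                   i, names(feats)[j]))
    }
    feats[[j]] <- v
  }
  x <- as.matrix(feats)
  if (nrow(x) < 4L) stop("at least 4 samples are required, got ", nrow(x))
  label_map <- NULL
  uv <- sort(unique(lab))
  if (length(uv) == 2L) {
    label_map <- stats::setNames(c(-1, 1), as.character(uv))
    y <- unname(label_map[as.character(lab)])
    message("label mapping: ", uv[1L], " -> -1, ", uv[2L], " -> +1")
  } else if (is.numeric(lab)) {
    y <- as.numeric(lab)
  } else {
    stop("non-numeric label column must have exactly two distinct values")
  }
  v <- validate_xy(x, y)
  list(x = v$x, y = v$y, label_map = label_map)
}

#' Write and read score tables
#'
#' `write_scores()` serializes a fitted `"fealect"` object as a TSV of
#' `(feature, score)` sorted by decreasing score, plus a sidecar
#' `<path>.meta.json` holding the full run configuration (gamma, m,
#' max_features, seed, path-length histogram), making every artifact
#' reproducible from its own metadata.  `read_scores()` restores the
#' score vector.
#'
#' @param fit a `"fealect"` object.
#' @param path output TSV path.
#' @return `write_scores()`: `path`, invisibly.  `read_scores()`: a named
#'   numeric score vector with attribute `"meta"` if the sidecar exists.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "fealect"))
  ord <- order(fit$scores, decreasing = TRUE)
  df <- data.frame(feature = names(fit$scores)[ord],
                   score = sprintf("%.12g", fit$scores[ord]))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(gamma = fit$gamma, m = fit$m, max_features = fit$max_features,
               seed = fit$seed, n = fit$n, d = fit$d,
               path_length_histogram = as.list(table(fit$sizes)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- stats::setNames(as.numeric(df$score), df$feature)
  metafile <- paste0(path, ".meta.json")
  if (file.exists(metafile)) attr(out, "meta") <- jsonlite::read_json(metafile)
  out
}

#' Export a fitted curve and segmentation as plain text
#'
#' Writes the selection report (knots, segment coefficients, threshold,
#' selected features) as JSON and, optionally, the curve as a TSV of
#' `(rank, feature, score, log_score, segment)` for external plotting.
#'
#' @param selection a `"fealect_selection"` object.
#' @param report_path JSON output path.
#' @param curve_path optional TSV output path.
#' @return `report_path`, invisibly.
#' @export
write_selection_report <- function(selection, report_path, curve_path = NULL) {
  stopifnot(inherits(selection, "fealect_selection"))
  fit <- selection$fit
  rep <- list(
    knots = c(fit$k1, fit$k2),
    coefficients = lapply(fit$coefficients, as.list),
    sse = fit$sse,
    threshold_score = selection$threshold_score,
    segment_counts = as.list(selection$segment_counts),
    n_zero_score = selection$n_zero,
    selected = as.list(selection$selected_name))
  jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(curve_path)) {
    cv <- fit$curve
    seg <- cut(cv$rank, c(0, fit$k1, fit$k2, fit$L),
               labels = c("g1", "g2", "g3"))
    write.table(data.frame(rank = cv$rank, feature = cv$feature_name,
                           score = cv$score, log_score = cv$log_score,
                           segment = seg),
                curve_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report_path)
}
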