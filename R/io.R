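#' Read an expression matrix with optional class labels
#'
#' Reads delimited expression data and normalizes the orientation to samples
#' x features. CSV/TSV files are expected one sample per row with a leading
#' sample-id column; GCT 1.2 files (genes x samples, as distributed by the
#' Broad Institute) are transposed on load. Constant-variance features are
#' detected and recorded in the \code{constant_features} attribute of the
#' returned matrix — some classifiers (naive Bayes in particular) fail on
#' such columns when no dimension reduction is applied.
#'
#' @param path File to read.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"gct"}; defaults to the
#'   file extension.
#' @param label_column Name of the column holding class labels (CSV/TSV),
#'   or \code{NULL} when the file is unlabeled.
#' @param labels_file Optional separate file with one label per sample
#'   (single column, header optional), used for any format.
#' @return A list of class \code{"expr_data"} with \code{x}, \code{labels}
#'   (factor or \code{NULL}) and \code{provenance}.
#' @export
read_expression <- function(path, format = NULL, label_column = "label",
                            labels_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", gct = "gct",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  format <- match.arg(format, c("csv", "tsv", "gct"))

  if (format == "gct") {
    dat <- read_gct(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("malformed table (need a sample-id column plus data): ", path,
           call. = FALSE)
    ids <- as.character(tab[[1L]])
    tab <- tab[, -1L, drop = FALSE]
    labels <- NULL
    if (!is.null(label_column) && label_column %in% names(tab)) {
      labels <- factor(tab[[label_column]])
      tab <- tab[, setdiff(names(tab), label_column), drop = FALSE]
      if (all(is.na(labels)) || all(labels == ""))
        stop("label column '", label_column, "' is empty: ",
             "dataset is unlabeled", call. = FALSE)
    }
    bad <- which(!vapply(tab, is.numeric, TRUE))
    if (length(bad))
      stop(sprintf("non-numeric expression column '%s' in %s",
                   names(tab)[bad[1L]], path), call. = FALSE)
    x <- as.matrix(tab)
    rownames(x) <- ids
    dat <- list(x = x, labels = labels)
  }

  if (!is.null(labels_file)) {
    lab <- utils::read.table(labels_file, header = FALSE,
                             stringsAsFactors = FALSE)
    lab <- lab[[ncol(lab)]]
    if (length(lab) != nrow(dat$x))
      stop(sprintf("labels file has %d entries for %d samples",
                   length(lab), nrow(dat$x)), call. = FALSE)
    dat$labels <- factor(lab)
  }

  const <- which(apply(dat$x, 2, function(v) stats::var(v) == 0))
  if (length(const)) {
    attr(dat$x, "constant_features") <- unname(const)
    message(sprintf("%d constant-variance feature(s) detected (e.g. '%s')",
                    length(const), colnames(dat$x)[const[1L]]))
  }
  structure(list(x = dat$x, labels = dat$labels, provenance = path),
            class = "expr_data")
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !startsWith(lines[1L], "#1.2"))
    stop("not a GCT 1.2 file (missing #1.2 header): ", path, call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("malformed GCT dimension line (line 2): ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != dims[2L] + 2L || nrow(tab) != dims[1L])
    stop(sprintf(
      "GCT dimensions %d x %d do not match table (%d rows, %d samples)",
      dims[1L], dims[2L], nrow(tab), ncol(tab) - 2L), call. = FALSE)
  genes <- as.character(tab[[1L]])
  x <- t(as.matrix(tab[, -(1:2), drop = FALSE]))  # to samples x genes
  colnames(x) <- genes
  storage.mode(x) <- "double"
  list(x = x, labels = NULL)
}

#' Write an expression dataset as CSV
#'
#' Writes one sample per row with a \code{sample_id} column, a \code{label}
#' column when labels are present, and one column per feature, at full
#' double precision so the file round-trips through
#' \code{\link{read_expression}}.
#'
#' @param data An \code{"expr_data"} list (e.g. from
#'   \code{\link{simulate_expression}}) or a numeric matrix.
#' @param path Output file.
#' @param labels Labels to attach when \code{data} is a bare matrix.
#' @return The path, invisibly.
#' @export
write_expression <- function(data, path, labels = NULL) {
  if (inherits(data, "expr_data")) {
    x <- data$x; labels <- data$labels
  } else x <- as_data_matrix(data)
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(x)))
  df <- data.frame(sample_id = ids, check.names = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("labels length does not match sample count", call. = FALSE)
    df$label <- as.character(labels)
  }
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e)
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  invisible(path)
}
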