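#' Read / write a binary observation matrix
#'
#' The file is CSV or TSV with a header row of unique variable names and
#' 0/1 cells; the delimiter is inferred from the extension (`.tsv` /
#' `.txt` = tab, anything else = comma). Missing or non-binary cells are
#' rejected with an error naming the offending row and column.
#'
#' @param path file path.
#' @return `read_binary_dataset()` returns a [binary_dataset()];
#'   `write_binary_dataset()` invisibly returns `path`.
#' @export
read_binary_dataset <- function(path) {
  sep <- dataset_sep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "numeric")
  if (is.null(names(df)) || any(!nzchar(names(df)))) {
    stop("dataset file must have a header row of variable names",
         call. = FALSE)
  }
  if (anyDuplicated(names(df))) {
    stop("duplicate variable names: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(df)
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-binary or missing cell at data row %d, column '%s'",
      bad[1, 1], colnames(m)[bad[1, 2]]
    ), call. = FALSE)
  }
  binary_dataset(m, provenance = paste0("file: ", path))
}

#' @param data a [binary_dataset()] or 0/1 matrix with column names.
#' @rdname read_binary_dataset
#' @export
write_binary_dataset <- function(data, path) {
  if (!inherits(data, "bgm_dataset")) data <- binary_dataset(as.matrix(data))
  sep <- dataset_sep(path)
  write.table(unclass(data), path, sep = sep, row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

dataset_sep <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext %in% c("tsv", "txt")) "\t" else ","
}
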