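#' Read a GCT v1.2 expression file as an omic layer
#'
#' GCT v1.2 stores genes in rows and samples in columns behind a `#1.2`
#' version line and a `nrows ncols` dimension line; the first two data
#' columns are `Name` (feature id) and `Description` (free text, may be
#' empty). The returned layer is transposed to the package's samples x
#' features orientation, with feature ids taken from `Name`.
#'
#' @param path Path to a GCT file.
#' @param name Layer name (defaults to the file name without extension).
#' @return A continuous [omic_layer()].
#' @export
read_gct <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  version <- readLines(con, n = 1)
  if (!identical(trimws(version), "#1.2"))
    stop("malformed GCT header (expected '#1.2'): ", path)
  dims <- strsplit(trimws(readLines(con, n = 1)), "\t")[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop("malformed GCT dimension line: ", path)
  nr <- as.integer(dims[1]); nc <- as.integer(dims[2])
  body <- read.delim(con, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (nrow(body) != nr)
    stop("GCT dimension mismatch: header declares ", nr,
         " rows, body has ", nrow(body))
  if (ncol(body) != nc + 2)
    stop("GCT dimension mismatch: header declares ", nc,
         " samples, body has ", ncol(body) - 2)
  m <- t(as.matrix(body[, -(1:2), drop = FALSE]))
  storage.mode(m) <- "numeric"
  colnames(m) <- as.character(body[[1]])
  if (is.null(name)) name <- sub("\\.gct$", "", basename(path))
  omic_layer(name, m, modality = "continuous")
}

#' Write an omic layer as GCT v1.2
#'
#' @param layer A continuous [omic_layer()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(layer, path) {
  v <- t(layer$values)  # genes x samples
  df <- data.frame(Name = rownames(v), Description = "",
                   v, check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a boolean alteration table (CSV) as an omic layer
#'
#' Expects a CSV with sample ids in the first column and one 0/1 (or
#' TRUE/FALSE) column per genomic feature. Any other cell value is
#' rejected with the offending row and column named.
#'
#' @param path Path to a CSV file.
#' @param name Layer name (defaults to the file name).
#' @return A boolean [omic_layer()].
#' @export
read_boolean_table <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (is.character(m)) {
    up <- toupper(trimws(m))
    conv <- ifelse(up %in% c("TRUE", "T", "1"), 1,
                   ifelse(up %in% c("FALSE", "F", "0"), 0, NA_real_))
    bad <- which(is.na(conv) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-binary value '", m[bad[1, 1], bad[1, 2]], "' at row ",
           ids[bad[1, 1]], ", column ", colnames(m)[bad[1, 2]])
    }
    storage.mode(conv) <- "numeric"
    dim(conv) <- dim(m); dimnames(conv) <- dimnames(m)
    m <- conv
  } else {
    storage.mode(m) <- "numeric"
    bad <- which(!(m %in% c(0, 1)) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-binary value '", m[bad[1, 1], bad[1, 2]], "' at row ",
           ids[bad[1, 1]], ", column ", colnames(m)[bad[1, 2]])
  }
  rownames(m) <- ids
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  omic_layer(name, m, modality = "boolean")
}

#' Read a continuous CSV matrix (samples in rows) as an omic layer
#'
#' @param path Path to a CSV with sample ids in the first column.
#' @param name Layer name (defaults to the file name).
#' @return A continuous [omic_layer()].
#' @export
read_csv_layer <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (is.null(name)) name <- sub("\\.csv$", "", basename(path))
  omic_layer(name, m, modality = "continuous")
}
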