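# On-disk formats. TSV is canonical (labels may contain commas); CSV is
# accepted on read. Numbers are serialized with 17 significant digits so a
# write/read round trip reproduces doubles exactly.

fmtNum <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
}

sepForPath <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

readDelim <- function(path) {
    if (!file.exists(path)) dataError(paste("file not found:", path))
    if (file.size(path) == 0L) dataError(paste("empty input file:", path))
    tab <- utils::read.table(path, sep = sepForPath(path), header = TRUE,
                             colClasses = "character", check.names = FALSE,
                             comment.char = "", quote = "\"",
                             stringsAsFactors = FALSE)
    if (!nrow(tab)) dataError(paste("no data rows in:", path))
    tab
}

numericColumn <- function(tab, col, path) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & !raw %in% c("NA", "NaN", ""))
    if (length(bad))
        dataError(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                          raw[bad[1]], col, bad[1], path))
    val
}

#' Read and write flow event tables
#'
#' `writeEventTable()` serializes a [FlowEventTable-class] as headed TSV
#' (CSV if the path ends in `.csv`) with decimal-preserving number
#' formatting; `readEventTable()` reads it back losslessly and validates the
#' schema, naming any missing columns or the first non-numeric channel cell.
#'
#' @param x a [FlowEventTable-class].
#' @param path file path.
#' @return `readEventTable()` returns a [FlowEventTable-class];
#'   `writeEventTable()` returns `path` invisibly.
#' @export
writeEventTable <- function(x, path) {
    if (!methods::is(x, "FlowEventTable")) dataError("x must be a FlowEventTable")
    ev <- x@events
    for (ch in CHANNELS) ev[[ch]] <- fmtNum(ev[[ch]])
    utils::write.table(ev, path, sep = sepForPath(path), quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
    tab <- readDelim(path)
    missing <- setdiff(FLOW_COLUMNS, names(tab))
    if (length(missing))
        dataError(paste0("event table ", path, " is missing required column(s): ",
                         paste(missing, collapse = ", ")))
    for (ch in CHANNELS) tab[[ch]] <- numericColumn(tab, ch, path)
    if (!is.null(tab$dead)) tab$dead <- as.logical(tab$dead)
    FlowEventTable(tab)
}

#' Read and write expression matrices
#'
#' Format: an optional `# kind: <kind>` header line, then a headed table
#' whose first column holds gene ids and remaining columns samples or
#' datasets.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path file path.
#' @param kind overrides the kind recorded in the file (or supplies it when
#'   the header line is absent; default `"log2fc"`).
#' @return `readExpressionMatrix()` returns an [ExpressionMatrix-class];
#'   `writeExpressionMatrix()` returns `path` invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    if (!methods::is(x, "ExpressionMatrix"))
        dataError("x must be an ExpressionMatrix")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# kind: ", x@kind), con)
    sep <- sepForPath(path)
    v <- x@values
    header <- paste(c("gene", colnames(v)), collapse = sep)
    writeLines(header, con)
    body <- cbind(rownames(v), apply(v, 2, fmtNum))
    writeLines(apply(body, 1, paste, collapse = sep), con)
    invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path, kind = NULL) {
    if (!file.exists(path)) dataError(paste("file not found:", path))
    if (file.size(path) == 0L) dataError(paste("empty input file:", path))
    first <- readLines(path, n = 1L)
    skip <- 0L
    if (grepl("^#\\s*kind:", first)) {
        if (is.null(kind)) kind <- trimws(sub("^#\\s*kind:", "", first))
        skip <- 1L
    }
    tab <- utils::read.table(path, sep = sepForPath(path), header = TRUE,
                             skip = skip, colClasses = "character",
                             check.names = FALSE, comment.char = "",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        dataError(paste("expression matrix needs a gene column plus >= 1",
                        "sample column:", path))
    if (!nrow(tab)) dataError(paste("no data rows in:", path))
    genes <- tab[[1]]
    if (anyDuplicated(genes))
        dataError(paste("duplicate gene ids in:", path))
    v <- vapply(names(tab)[-1], function(col) numericColumn(tab, col, path),
                numeric(nrow(tab)))
    v <- matrix(v, nrow = nrow(tab),
                dimnames = list(genes, names(tab)[-1]))
    ExpressionMatrix(v, kind = kind %||% "log2fc")
}

#' Write a report table or correlation matrix as TSV
#'
#' @param x a data.frame (e.g. the hit table from [scoreScreen()]) or a
#'   [CorrelationMatrix-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(x, path) {
    sep <- sepForPath(path)
    if (methods::is(x, "CorrelationMatrix")) {
        r <- x@r
        df <- data.frame(dataset = rownames(r), r, check.names = FALSE,
                         stringsAsFactors = FALSE)
        for (col in colnames(r)) df[[col]] <- fmtNum(df[[col]])
        utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
        return(invisible(path))
    }
    if (!is.data.frame(x)) dataError("x must be a data.frame or CorrelationMatrix")
    df <- x
    for (col in names(df)) if (is.numeric(df[[col]])) df[[col]] <- fmtNum(df[[col]])
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}
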