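# Table schemas: column name -> type. Headers are matched
# case-insensitively and order-free; keys must be unique.
.schemas <- list(
  blot = list(cols = c(strain = "character", membrane_id = "character",
                       replicate = "integer", raw_intensity = "numeric"),
              key = c("strain", "membrane_id", "replicate")),
  growth = list(cols = c(strain = "character", trial = "integer",
                         time_h = "numeric", od600 = "numeric"),
                key = c("strain", "trial", "time_h")),
  annotation = list(cols = c(category_id = "character",
                             category_name = "character",
                             gene = "character"),
                    key = c("category_id", "gene")),
  fcop = list(cols = c(strain = "character", replicate = "integer",
                       fm464 = "numeric", cfu = "numeric"),
              key = c("strain", "replicate"))
)

#' Read and validate a screen input table
#'
#' Reads one of the pipeline's tabular inputs (comma-separated by default,
#' tab-separated for `.tsv`/`.txt` files), matching headers
#' case-insensitively and in any order, coercing columns to their declared
#' types, and reporting schema violations with the file, column and line.
#' Duplicate key rows (e.g. the same strain/membrane/replicate twice) are
#' an error. Values are validated for type only; semantic checks (such as
#' non-positive intensities) happen downstream in the stage that owns them.
#'
#' @param path Path to the file.
#' @param schema One of `"blot"`, `"growth"`, `"annotation"`, `"fcop"`.
#' @return A typed data.frame with canonical lower-case column names.
#' @seealso [readBlotTable()], [readGrowthTable()], [readAnnotationTable()],
#'   [readFcopTable()]
#' @export
readScreenTable <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  spec <- .schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  required <- names(spec$cols)
  optional <- if (schema == "annotation") "category_name" else character()
  missing <- setdiff(setdiff(required, optional), names(raw))
  if (length(missing) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in required) {
    if (!col %in% names(raw)) { # optional column
      out[[col]] <- raw[["category_id"]]
      next
    }
    v <- raw[[col]]
    type <- spec$cols[[col]]
    if (type == "character") {
      out[[col]] <- v
    } else {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & nzchar(v))
      if (length(bad) > 0L) {
        stop(path, ": column '", col, "', line ", bad[1] + 1L,
             ": cannot parse '", v[bad[1]], "' as a number", call. = FALSE)
      }
      out[[col]] <- if (type == "integer") as.integer(round(conv)) else conv
    }
  }
  key <- do.call(paste, c(out[spec$key], sep = "\r"))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(path, ": duplicate key (", paste(spec$key, collapse = ", "),
         ") at line ", i + 1L, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @rdname readScreenTable
#' @export
readBlotTable <- function(path) readScreenTable(path, "blot")

#' @rdname readScreenTable
#' @export
readGrowthTable <- function(path) readScreenTable(path, "growth")

#' Read a flat annotation table into an [AnnotationSet-class]
#'
#' @param path TSV/CSV with columns `category_id`, `gene` and optionally
#'   `category_name` (one row per membership).
#' @param universe Character vector of background genes.
#' @return An [AnnotationSet-class].
#' @export
readAnnotationTable <- function(path, universe) {
  tab <- readScreenTable(path, "annotation")
  AnnotationSet(data.frame(category = tab$category_id,
                           name = tab$category_name,
                           gene = tab$gene, stringsAsFactors = FALSE),
                universe = universe)
}

#' @rdname readScreenTable
#' @export
readFcopTable <- function(path) readScreenTable(path, "fcop")

#' Write a result table as TSV at full precision
#'
#' Output tables are tab-separated with a header row; numbers keep 15
#' significant digits so that a write-then-read round trip is lossless at
#' documented (12 significant digit) precision.
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeResultTable <- function(df, path) {
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1)) &
    !vapply(fmt, is.integer, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) {
    formatC(x, digits = 15, format = "g")
  })
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
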