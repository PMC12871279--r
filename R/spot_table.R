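## core data model: per-transcript spot tables

#' Default pattern identifying blank codewords
#'
#' Blank barcodes are valid codewords that map to no gene; their
#' detection rate estimates the false-positive rate of decoding.
#' Vendor tables name them "Blank-1", "Blank-2", ...
#' @export
blank_pattern_default <- "^blank"

#' Construct a spot table
#'
#' A spot table is the pipeline's atomic input: one row per detected
#' transcript with its gene, 3D position in micrometres (section-local
#' frame), section id, blank flag and (after segmentation) an optional
#' cell assignment.
#'
#' @param gene character vector of gene (or blank codeword) names.
#' @param x,y,z numeric coordinates in micrometres.
#' @param section_id section identifier (recycled if length 1).
#' @param transcript_id integer ids, unique within a section; defaults
#'   to the row number.
#' @param cell_id optional character cell assignment (`NA` = unassigned).
#' @param blank_pattern case-insensitive regex marking blank codewords.
#' @return a `data.frame` of class `spot_table` with columns
#'   `transcript_id`, `gene`, `x`, `y`, `z`, `section_id`, `is_blank`,
#'   `cell_id`.
#' @export
spot_table <- function(gene, x, y, z = 0, section_id = "S1",
                       transcript_id = NULL, cell_id = NA_character_,
                       blank_pattern = blank_pattern_default) {
  n <- length(gene)
  x <- as.numeric(x); y <- as.numeric(y)
  z <- rep_len(as.numeric(z), n)
  if (length(x) != n || length(y) != n)
    stop_merscape("gene/x/y lengths differ", class = "merscape_format_error")
  if (n && any(!is.finite(x) | !is.finite(y) | !is.finite(z)))
    stop_merscape("non-finite coordinates in spot table",
                  class = "merscape_parse_error")
  if (is.null(transcript_id)) transcript_id <- seq_len(n)
  st <- data.frame(
    transcript_id = as.integer(transcript_id),
    gene = as.character(gene),
    x = x, y = y, z = z,
    section_id = rep_len(as.character(section_id), n),
    is_blank = grepl(blank_pattern, as.character(gene), ignore.case = TRUE),
    cell_id = rep_len(as.character(cell_id), n),
    stringsAsFactors = FALSE
  )
  for (s in unique(st$section_id)) {
    tid <- st$transcript_id[st$section_id == s]
    if (anyDuplicated(tid))
      stop_merscape("duplicate transcript_id within section ", s,
                    class = "merscape_format_error")
  }
  class(st) <- c("spot_table", "data.frame")
  st
}

#' Read a detected-transcripts table
#'
#' Reads a MERSCOPE-style detected-transcripts CSV (columns `gene`,
#' `global_x`, `global_y`, `global_z`, optional `fov`/`section`) or a
#' generic CSV with columns `gene`, `x`, `y`, `z`.
#'
#' @param path path to a CSV file.
#' @param dialect `"merscope_csv"` or `"generic_csv"`.
#' @param blank_pattern regex marking blank codewords.
#' @return a [spot_table].
#' @export
read_spot_table <- function(path, dialect = c("merscope_csv", "generic_csv"),
                            blank_pattern = blank_pattern_default) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_merscape("file not found: ", path, class = "merscape_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- if (dialect == "merscope_csv")
    c(x = "global_x", y = "global_y", z = "global_z") else
    c(x = "x", y = "y", z = "z")
  need <- c("gene", unname(cols[c("x", "y")]))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_merscape("missing required column(s): ", paste(miss, collapse = ", "),
                  class = "merscape_format_error")
  getnum <- function(col, default = NULL) {
    if (!col %in% names(df)) return(default)
    v <- df[[col]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v) & nzchar(as.character(v)))
    if (length(bad))
      stop_merscape("non-numeric coordinate in column '", col,
                    "' at row ", bad[1L], class = "merscape_parse_error")
    vn
  }
  n <- nrow(df)
  zcol <- getnum(cols[["z"]], default = rep(0, n))
  sec <- if ("section" %in% names(df)) as.character(df$section)
         else if ("fov" %in% names(df)) as.character(df$fov) else "S1"
  tid <- if ("transcript_id" %in% names(df)) df$transcript_id else NULL
  spot_table(gene = df$gene, x = getnum(cols[["x"]]), y = getnum(cols[["y"]]),
             z = zcol, section_id = if (n) sec else character(0),
             transcript_id = tid, blank_pattern = blank_pattern)
}

#' Write a spot table as a generic CSV
#' @param spots a [spot_table].
#' @param path output path.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(as.data.frame(spots), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("<spot_table> %d transcripts, %d genes, %d blank (%.2f%%), %d section(s)\n",
              nrow(x), length(unique(x$gene[!x$is_blank])), sum(x$is_blank),
              if (nrow(x)) 100 * mean(x$is_blank) else 0,
              length(unique(x$section_id))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
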