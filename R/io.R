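# Versioned TSV serialization shared by all pipeline stages. The first
# line is a comment header "#cysredox <schema> v1" so a reader can verify
# what it is loading; numeric ratio-like columns are written at 6
# significant digits.

.TSV_VERSION <- "v1"
.SIGNIF_COLS <- c("ratio_LH", "mean_ratio", "cv", "light_area",
                  "heavy_area", "pct", "mean_pct", "sd_pct", "delta_pct",
                  "intensity", "slope", "top_dose_ratio")

#' Write a stage table as versioned TSV
#'
#' @param x data.frame (list columns are dropped with a message).
#' @param path Output path.
#' @param schema Short schema name recorded in the header line (e.g.
#'   `"ratio_observation"`).
#' @export
write_stage_tsv <- function(x, path, schema) {
  drop <- vapply(x, is.list, logical(1))
  if (any(drop)) x <- x[, !drop, drop = FALSE]
  for (col in intersect(names(x), .SIGNIF_COLS)) {
    x[[col]] <- signif(x[[col]], 6)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#cysredox\t%s\t%s", schema, .TSV_VERSION), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a versioned stage TSV, checking its schema
#'
#' @param path TSV path written by [write_stage_tsv()].
#' @param schema Expected schema name; mismatch is an error.
#' @return data.frame.
#' @export
read_stage_tsv <- function(path, schema) {
  header <- readLines(path, n = 1L)
  parts <- strsplit(header, "\t")[[1]]
  if (length(parts) != 3L || parts[1] != "#cysredox" ||
      parts[2] != schema) {
    stop(sprintf("'%s' is not a cysredox %s table (header: %s)",
                 path, schema, header), call. = FALSE)
  }
  utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
}
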