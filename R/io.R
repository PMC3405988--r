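#' Read a mutation table (TSV)
#'
#' Reads a tab-separated mutation table with header columns `isolate`,
#' `position`, `kind`, `wt`, `mut`, `indel_seq`, `rank`; lines starting
#' with `#` are comments. Positions are 1-based target coordinates.
#' Malformed rows abort with their (1-based) data row numbers.
#'
#' @param path Path to a TSV file.
#' @param target Optional [mutation_target()] for position / wild-type
#'   base validation.
#' @return A validated mutation record data frame.
#' @export
read_mutation_table <- function(path, target = NULL) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_mutation_records(df, target)
}

#' Write a mutation table (TSV)
#'
#' @param records Mutation record data frame.
#' @param path Output path.
#' @export
write_mutation_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a burst table (TSV) into a burst dataset
#'
#' Accepts either form of burst table and auto-detects which: a class
#' histogram with columns `revertants` and `cultures`, or a per-culture
#' listing with columns `culture` and `revertants`. Both forms of the
#' same data produce identical datasets.
#'
#' @param path Path to a TSV file (`#` comments allowed).
#' @inheritParams burst_dataset
#' @return A [burst_dataset()].
#' @export
read_burst_table <- function(path, N, B_mean, B_sd = NA_real_,
                             exclude_ge = NULL, plating_efficiency = 1) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (all(c("revertants", "cultures") %in% names(df))) {
    burst_dataset(histogram = df[, c("revertants", "cultures")],
                  N = N, B_mean = B_mean, B_sd = B_sd,
                  exclude_ge = exclude_ge,
                  plating_efficiency = plating_efficiency)
  } else if (all(c("culture", "revertants") %in% names(df))) {
    burst_dataset(counts = df$revertants, N = N, B_mean = B_mean,
                  B_sd = B_sd, exclude_ge = exclude_ge,
                  plating_efficiency = plating_efficiency)
  } else {
    stop("burst table needs columns (revertants, cultures) or ",
         "(culture, revertants)")
  }
}

#' Write an analysis report
#'
#' Serialises a (possibly nested) list of results deterministically:
#' JSON with unboxed scalars and full numeric precision, or an indented
#' plain-text rendering. The package version is embedded.
#'
#' @param results Named list of results (numbers, vectors, data frames,
#'   nested lists).
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "text")) {
  format <- match.arg(format)
  payload <- list(software = "qmutate",
                  version = as.character(utils::packageVersion("qmutate")),
                  results = results)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    render <- function(x, name, indent) {
      pad <- strrep("  ", indent)
      if (is.list(x) && !is.data.frame(x)) {
        cat(sprintf("%s%s:\n", pad, name), file = con)
        for (nm in names(x)) render(x[[nm]], nm, indent + 1)
      } else if (is.data.frame(x)) {
        cat(sprintf("%s%s: <%d rows>\n", pad, name, nrow(x)), file = con)
        lines <- utils::capture.output(print(x, row.names = FALSE))
        writeLines(paste0(pad, "  ", lines), con = con)
      } else {
        cat(sprintf("%s%s: %s\n", pad, name,
                    paste(format(x, digits = 15), collapse = ", ")),
            file = con)
      }
    }
    render(payload, "report", 0)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return The deserialised payload list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
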