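#' Read a long-format phenotype table
#'
#' Expects one row per genotype x cutting x replication with columns
#' \code{Cut}, \code{Gen}, \code{Rep}, optionally \code{Block} and
#' \code{Cut.Rep}, and one column per trait (e.g. Height, GB, DB, DM,
#' ADF, NDF, DIG, LIG).  Empty fields and "NA" are missing.
#'
#' @param path CSV/TSV file path.
#' @param sep field separator; guessed from the header when NULL.
#' @return Data frame of records.
#' @export
read_phenotypes <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  need <- c("Cut", "Gen", "Rep")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$Gen <- as.character(df$Gen)
  df
}

#' Write a phenotype table in the dialect \code{read_phenotypes} reads
#'
#' @param phenotypes data frame of records.
#' @param path output CSV path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Write an SSR genotype table in the raw dialect
#'
#' One column per locus holding "/"-separated allele sizes; empty field
#' marks a missing call.
#'
#' @param table an \code{\link{ssr_table}}.
#' @param path output CSV path.
#' @export
write_ssr_table <- function(table, path) {
  stopifnot(inherits(table, "ssr_table"))
  cols <- lapply(table$calls, function(locus)
    vapply(locus, function(x)
      if (is.null(x)) "" else paste(x, collapse = "/"), character(1)))
  df <- data.frame(Code = table$genotypes, cols, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expanded binary marker matrix as CSV
#'
#' @param markers a \code{\link{marker_matrix}}.
#' @param path output CSV path.
#' @export
write_marker_matrix <- function(markers, path) {
  stopifnot(inherits(markers, "marker_matrix"))
  df <- data.frame(Code = markers$genotypes, markers$Z,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
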