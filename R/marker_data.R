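#' Construct a multiallelic SSR genotype table
#'
#' Holds raw simple sequence repeat (SSR) calls: for every genotype and
#' locus, the set of allele lengths (base pairs) observed, or a missing
#' state.  Because the species may be polyploid, a genotype can carry
#' several alleles at one locus.
#'
#' @param genotypes character vector of unique genotype identifiers.
#' @param calls named list, one element per locus.  Each element is a list
#'   of length \code{length(genotypes)} whose components are integer
#'   vectors of allele sizes; \code{NULL} (or a vector of \code{NA}) marks
#'   a missing call at that locus.
#' @return An object of class \code{ssr_table}.
#' @export
ssr_table <- function(genotypes, calls) {
  genotypes <- as.character(genotypes)
  if (anyDuplicated(genotypes))
    stop("duplicate genotype_id: ",
         paste(unique(genotypes[duplicated(genotypes)]), collapse = ", "))
  if (is.null(names(calls)) || anyDuplicated(names(calls)))
    stop("locus names must be present and unique")
  calls <- lapply(calls, function(locus) {
    if (length(locus) != length(genotypes))
      stop("each locus must have one call per genotype")
    lapply(locus, function(x) {
      if (is.null(x) || all(is.na(x))) NULL else sort(unique(as.integer(x)))
    })
  })
  structure(list(genotypes = genotypes, calls = calls), class = "ssr_table")
}

#' @export
print.ssr_table <- function(x, ...) {
  cat("SSR genotype table:", length(x$genotypes), "genotypes x",
      length(x$calls), "loci\n")
  miss <- vapply(x$calls, function(l) mean(vapply(l, is.null, logical(1))),
                 numeric(1))
  cat("  mean missing-call rate:", format(mean(miss), digits = 3), "\n")
  invisible(x)
}

#' Read an SSR marker table from delimited text
#'
#' Auto-detects two layouts by header/content: \emph{raw} (one column per
#' locus holding "/"-separated allele sizes, empty field = missing) and
#' \emph{expanded} (one 0/1/NA column per locus_allele combination, names
#' like \code{M28_161}).  The first column is the genotype identifier.
#'
#' @param path file path to a CSV/TSV file.
#' @param sep field separator; guessed from the header line when `NULL`.
#' @return An \code{ssr_table} (raw layout) or \code{marker_matrix}
#'   (expanded layout).
#' @export
read_marker_table <- function(path, sep = NULL) {
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  expanded <- all(grepl("^.+_[0-9]+$", names(body))) &&
    all(vapply(body, function(col) all(is.na(col) | col %in% c(0, 1)),
               logical(1)))
  if (expanded) {
    Z <- as.matrix(body)
    storage.mode(Z) <- "double"
    rownames(Z) <- ids
    return(marker_matrix(Z))
  }
  calls <- lapply(body, function(col) {
    lapply(as.character(col), function(x) {
      if (is.na(x) || !nzchar(x)) NULL
      else as.integer(strsplit(x, "/", fixed = TRUE)[[1L]])
    })
  })
  ssr_table(ids, calls)
}

#' Construct a binary presence/absence marker matrix
#'
#' @param Z numeric matrix, genotypes in rows and allele-markers in
#'   columns, entries 0/1/NA; column names \code{locus_allele}.
#' @param p optional per-marker presence frequencies.
#' @return An object of class \code{marker_matrix} with fields \code{Z},
#'   \code{markers}, \code{genotypes}, \code{locus}, \code{allele} and
#'   (once computed) \code{p}.
#' @export
marker_matrix <- function(Z, p = NULL) {
  stopifnot(is.matrix(Z))
  if (is.null(colnames(Z))) stop("marker columns must be named locus_allele")
  if (is.null(rownames(Z))) rownames(Z) <- paste0("G", seq_len(nrow(Z)))
  if (anyDuplicated(rownames(Z))) stop("duplicate genotype_id in marker matrix")
  bad <- !(is.na(Z) | Z == 0 | Z == 1)
  if (any(bad)) stop("marker entries must be 0, 1 or NA")
  loc <- sub("_[0-9]+$", "", colnames(Z))
  al <- suppressWarnings(as.integer(sub("^.*_", "", colnames(Z))))
  structure(list(Z = Z, markers = colnames(Z), genotypes = rownames(Z),
                 locus = loc, allele = al, p = p),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Binary marker matrix:", nrow(x$Z), "genotypes x", ncol(x$Z),
      "allele-markers (", length(unique(x$locus)), "loci )\n")
  cat("  missing entries:", sum(is.na(x$Z)),
      if (!is.null(x$p)) " | frequencies attached" else "", "\n", sep = "")
  invisible(x)
}

#' Expand multiallelic SSR calls into binary allele-markers
#'
#' Every distinct (locus, allele) pair observed anywhere in the table
#' becomes one binary marker: 1 if the allele is in the genotype's call
#' set, 0 if the locus was called without it, NA for all of a locus's
#' markers when that locus call is missing.  Columns are ordered by locus
#' order as read, then ascending allele size, so marker indices are stable.
#'
#' @param table an \code{\link{ssr_table}}.
#' @return A \code{\link{marker_matrix}}.
#' @export
expand_alleles <- function(table) {
  stopifnot(inherits(table, "ssr_table"))
  n <- length(table$genotypes)
  if (n == 0L) stop("empty SSR table")
  cols <- list()
  for (locus in names(table$calls)) {
    locus_calls <- table$calls[[locus]]
    alleles <- sort(unique(unlist(locus_calls)))
    for (a in alleles) {
      v <- vapply(locus_calls, function(s) {
        if (is.null(s)) NA_real_ else as.numeric(a %in% s)
      }, numeric(1))
      cols[[paste0(locus, "_", a)]] <- v
    }
  }
  if (!length(cols)) stop("no alleles observed in the table")
  Z <- do.call(cbind, cols)
  rownames(Z) <- table$genotypes
  marker_matrix(Z)
}

#' Per-marker presence frequencies
#'
#' \code{p_i} is the mean of the observed (non-missing) 0/1 entries of
#' column \code{i}.
#'
#' @param x a \code{marker_matrix}.
#' @return Named numeric vector of frequencies in [0, 1].
#' @export
allele_frequencies <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  nobs <- colSums(!is.na(x$Z))
  if (any(nobs == 0L))
    stop("all entries missing for marker(s): ",
         paste(x$markers[nobs == 0L], collapse = ", "))
  colMeans(x$Z, na.rm = TRUE)
}

#' Quality-control filter for binary allele-markers
#'
#' Drops markers whose call rate (fraction of non-missing genotypes) falls
#' below \code{call_rate_min} and markers whose minor-allele frequency
#' \code{min(p, 1 - p)} falls below \code{maf_min}.  The defaults keep
#' markers with at most 15\% missing calls and MAF of at least 1\%.
#'
#' @param x a \code{marker_matrix}.
#' @param call_rate_min minimum call rate in [0, 1].
#' @param maf_min minimum minor-allele frequency in [0, 1].
#' @return List with \code{markers} (the filtered \code{marker_matrix})
#'   and \code{report} (data frame: marker, call_rate, freq, status,
#'   reason).
#' @export
qc_filter <- function(x, call_rate_min = 0.85, maf_min = 0.01) {
  stopifnot(inherits(x, "marker_matrix"),
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  call_rate <- colMeans(!is.na(x$Z))
  freq <- ifelse(call_rate > 0, colMeans(x$Z, na.rm = TRUE), NA_real_)
  maf <- pmin(freq, 1 - freq)
  reason <- character(ncol(x$Z))
  reason[call_rate < call_rate_min] <- "low_call_rate"
  low_maf <- call_rate >= call_rate_min & (is.na(maf) | maf < maf_min)
  reason[low_maf] <- "low_maf"
  keep <- reason == ""
  report <- data.frame(marker = x$markers,
                       call_rate = unname(call_rate),
                       freq = unname(freq),
                       status = ifelse(keep, "pass", "fail"),
                       reason = ifelse(keep, "", reason),
                       stringsAsFactors = FALSE)
  attr(report, "n_before") <- ncol(x$Z)
  attr(report, "n_pass") <- sum(keep)
  attr(report, "n_fail") <- sum(!keep)
  list(markers = marker_matrix(x$Z[, keep, drop = FALSE]), report = report)
}

#' Impute missing marker calls by the frequency-threshold rule
#'
#' Each missing entry in column \code{i} is replaced by 0 when the
#' presence frequency over the observed entries satisfies
#' \code{p_i <= 0.5}, and by 1 when \code{p_i > 0.5}.  Observed entries
#' are untouched; the operation is idempotent.  The frequencies stored on
#' the result are recomputed from the completed matrix (so that the
#' centered matrix has zero column sums).
#'
#' @param x a \code{marker_matrix} (normally after \code{\link{qc_filter}}).
#' @return A complete \code{marker_matrix} with frequencies attached.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  p_obs <- allele_frequencies(x)
  Z <- x$Z
  fill <- as.numeric(p_obs > 0.5)
  idx <- which(is.na(Z), arr.ind = TRUE)
  if (nrow(idx)) Z[idx] <- fill[idx[, 2L]]
  out <- marker_matrix(Z)
  out$p <- colMeans(Z)
  out
}

#' Centered marker matrix Z* = Z - P
#'
#' @param x a complete (post-imputation) \code{marker_matrix}.
#' @param p frequencies to center on; defaults to the frequencies of
#'   \code{x} (stored, or recomputed from the complete matrix).
#' @return Numeric matrix with the per-marker frequency subtracted from
#'   every column.
#' @export
centered_markers <- function(x, p = NULL) {
  stopifnot(inherits(x, "marker_matrix"))
  if (anyNA(x$Z)) stop("centering requires a complete matrix; impute first")
  if (is.null(p)) p <- if (!is.null(x$p)) x$p else colMeans(x$Z)
  sweep(x$Z, 2L, p, "-")
}

#' Write a marker QC report as CSV
#'
#' @param report the report component returned by \code{\link{qc_filter}}.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
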