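#' Build or read a run configuration
#'
#' A run is driven by one configuration holding either input file paths
#' or a simulation block (exactly one of the two), the trait list, and
#' every analysis constant: QC thresholds (0.85 call rate, 0.01 MAF),
#' blending weight (0.95), FDR settings (q = 0.02, alpha = 0.05) and the
#' LRT level (0.05).
#'
#' @param phenotypes,markers input file paths (CSV), or NULL when
#'   simulating.
#' @param simulation named list of \code{\link{sim_config}} arguments
#'   (seed supplied by the run), or NULL when reading files.
#' @param traits trait columns to analyse.
#' @param call_rate_min,maf_min QC thresholds.
#' @param blend_weight relationship blending weight.
#' @param gi interaction covariance kind (\code{"relationship"} or
#'   \code{"identity"}).
#' @param fdr_q,fdr_alpha association FDR rate and screening level.
#' @param lrt_alpha likelihood-ratio test level.
#' @param cuttings cuttings to scan (NULL = all present).
#' @param out_dir output directory.
#' @param seed master seed for all randomness.
#' @param reml list of \code{\link{reml_opts}} arguments for the fits.
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(phenotypes = NULL, markers = NULL,
                       simulation = NULL, traits = NULL,
                       call_rate_min = 0.85, maf_min = 0.01,
                       blend_weight = 0.95,
                       gi = c("relationship", "identity"),
                       fdr_q = 0.02, fdr_alpha = 0.05, lrt_alpha = 0.05,
                       cuttings = NULL, out_dir = ".", seed = 1L,
                       reml = list(method = "ai", tol = 1e-6)) {
  gi <- match.arg(gi)
  has_files <- !is.null(phenotypes) || !is.null(markers)
  if (has_files == !is.null(simulation))
    stop("provide exactly one of {phenotypes+markers paths, simulation}")
  if (has_files && (is.null(phenotypes) || is.null(markers)))
    stop("both phenotype and marker paths are required")
  structure(list(phenotypes = phenotypes, markers = markers,
                 simulation = simulation, traits = traits,
                 call_rate_min = call_rate_min, maf_min = maf_min,
                 blend_weight = blend_weight, gi = gi,
                 fdr_q = fdr_q, fdr_alpha = fdr_alpha,
                 lrt_alpha = lrt_alpha, cuttings = cuttings,
                 out_dir = out_dir, seed = as.integer(seed),
                 reml = reml),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose keys match the arguments of
#'   \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

## Load files or simulate; returns phenotypes, raw genotype input,
## post-QC imputed markers, QC report and relationship sets.
.prepare_inputs <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    study <- simulate_study(do.call(sim_config, sim_args))
    ph <- study$phenotypes
    raw <- study$genotype_table
    if (is.null(cfg$traits)) cfg$traits <- study$config$traits
  } else {
    ph <- read_phenotypes(cfg$phenotypes)
    raw <- read_marker_table(cfg$markers)
    study <- NULL
    if (is.null(cfg$traits))
      cfg$traits <- setdiff(names(ph),
                            c("Cut", "Gen", "Rep", "Block", "Cut.Rep",
                              "Int"))
  }
  expanded <- if (inherits(raw, "marker_matrix")) raw
              else expand_alleles(raw)
  qc <- qc_filter(expanded, cfg$call_rate_min, cfg$maf_min)
  imputed <- impute_missing(qc$markers)
  ids <- sort(unique(c(ph$Gen, imputed$genotypes)))
  rel <- relationship_set(imputed, individuals = ids,
                          weight = cfg$blend_weight)
  rel_genotyped <- relationship_set(imputed, weight = cfg$blend_weight)
  list(cfg = cfg, phenotypes = ph, raw = raw, expanded = expanded,
       qc_report = qc$report, markers = imputed, relationships = rel,
       relationships_genotyped = rel_genotyped, study = study)
}

#' Run the full multi-harvest evaluation
#'
#' Marker QC and imputation, relationship construction, then for every
#' trait: the full single-step GBLUP fit with a likelihood-ratio test of
#' each random term, and the repeatability + interaction fit, with
#' PEV-based accuracies of both compared side by side.  All tables are
#' written under the configured output directory.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return Invisible list of artifacts: tables, fits and output paths.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- .prepare_inputs(cfg)
  cfg <- inp$cfg
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add_file <- function(path) files <<- c(files, path)

  write_qc_report(inp$qc_report, file.path(cfg$out_dir, "qc_report.csv"))
  add_file("qc_report.csv")
  opts <- do.call(reml_opts, cfg$reml)
  has_block <- "Block" %in% names(inp$phenotypes)

  lrt_rows <- list(); acc_rows <- list(); vc_rows <- list()
  fits <- list()
  for (tr in cfg$traits) {
    spec_full <- spec_full_ssgblup(tr, gi = cfg$gi, block = has_block)
    des <- build_design(inp$phenotypes, spec_full, inp$relationships)
    full <- fit_reml(des, inp$relationships, opts)
    fits[[tr]] <- full
    for (tm in names(full$u)) {
      red_des <- build_design(inp$phenotypes, drop_term(spec_full, tm),
                              inp$relationships)
      red <- fit_reml(red_des, inp$relationships, opts)
      lt <- lrt(full, red, alpha = cfg$lrt_alpha)
      lrt_rows[[paste(tr, tm)]] <-
        data.frame(trait = tr, term = tm, statistic = lt$statistic,
                   p = lt$p.value, significant = lt$significant)
    }
    acc_full <- accuracy(full, "a")$summary
    spec_rep <- spec_repeatability(tr, block = has_block)
    rep_des <- build_design(inp$phenotypes, spec_rep, inp$relationships)
    rep_fit <- fit_reml(rep_des, inp$relationships, opts)
    acc_rep <- accuracy(rep_fit, "g")$summary
    acc_rows[[tr]] <- data.frame(
      trait = tr, model = c("ssGBLUP", "repeatability"),
      accuracy = c(acc_full, acc_rep))
    vc_rows[[tr]] <- data.frame(trait = tr,
                                term = names(full$sigma2),
                                estimate = unname(full$sigma2))
    utils::write.csv(extract_blups(full, "a"),
                     file.path(cfg$out_dir,
                               paste0("blup_a_", tr, ".csv")),
                     row.names = FALSE, quote = FALSE)
    add_file(paste0("blup_a_", tr, ".csv"))
  }
  lrt_table <- do.call(rbind, lrt_rows)
  acc_table <- do.call(rbind, acc_rows)
  vc_table <- do.call(rbind, vc_rows)
  rownames(lrt_table) <- rownames(acc_table) <- rownames(vc_table) <- NULL
  for (nm in c("lrt_table", "accuracy_comparison", "variance_components")) {
    obj <- switch(nm, lrt_table = lrt_table,
                  accuracy_comparison = acc_table,
                  variance_components = vc_table)
    utils::write.csv(obj, file.path(cfg$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
    add_file(paste0(nm, ".csv"))
  }
  invisible(list(dir = cfg$out_dir, files = files, cfg = cfg,
                 inputs = inp, fits = fits, lrt_table = lrt_table,
                 accuracy_comparison = acc_table,
                 variance_components = vc_table))
}

#' Run per-cutting association scans
#'
#' For every cutting x trait: the marker scan of
#' \code{\link{gwas_scan}} (genotyped individuals only), Manhattan and
#' QQ plot data, the significant-marker list, and a linkage-
#' disequilibrium profile for each significant marker.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param inputs optional prepared inputs (reused from
#'   \code{\link{run_full_analysis}} output \code{$inputs}) to avoid
#'   recomputation.
#' @return Invisible list of artifacts.
#' @export
run_gwas_per_cutting <- function(cfg, inputs = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(inputs)) inputs <- .prepare_inputs(cfg)
  cfg <- inputs$cfg
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ph <- inputs$phenotypes
  ph <- ph[ph$Gen %in% inputs$markers$genotypes, , drop = FALSE]
  cuts <- if (is.null(cfg$cuttings)) sort(unique(ph$Cut)) else cfg$cuttings
  opts <- do.call(reml_opts, cfg$reml)
  files <- character(0)
  scans <- list(); sig_rows <- list()
  for (cc in cuts) {
    sub <- ph[ph$Cut == cc, , drop = FALSE]
    if (!nrow(sub)) stop("cutting ", cc, " absent from the data")
    for (tr in cfg$traits) {
      res <- gwas_scan(sub, inputs$markers,
                       inputs$relationships_genotyped, tr,
                       q = cfg$fdr_q, alpha = cfg$fdr_alpha, opts = opts)
      tag <- paste0("cut", cc, "_", tr)
      utils::write.csv(
        cbind(cutting = cc, trait = tr, res$table),
        file.path(cfg$out_dir, paste0("gwas_", tag, ".csv")),
        row.names = FALSE, quote = FALSE)
      files <- c(files, paste0("gwas_", tag, ".csv"))
      pd <- qq_manhattan_data(res)
      utils::write.csv(pd$manhattan,
                       file.path(cfg$out_dir,
                                 paste0("manhattan_", tag, ".csv")),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(pd$qq,
                       file.path(cfg$out_dir, paste0("qq_", tag, ".csv")),
                       row.names = FALSE, quote = FALSE)
      files <- c(files, paste0("manhattan_", tag, ".csv"),
                 paste0("qq_", tag, ".csv"))
      sig <- res$table$marker[res$table$significant]
      if (length(sig)) {
        sig_rows[[tag]] <- data.frame(cutting = cc, trait = tr,
                                      marker = sig)
        for (mk in sig) {
          prof <- ld_profile(inputs$markers, mk)
          utils::write.csv(prof$pairs,
                           file.path(cfg$out_dir,
                                     paste0("ld_", mk, ".csv")),
                           row.names = FALSE, quote = FALSE)
          files <- c(files, paste0("ld_", mk, ".csv"))
        }
      } else {
        message("no significant markers for ", tag,
                "; LD profile skipped")
      }
      scans[[tag]] <- res
    }
  }
  sig_table <- if (length(sig_rows)) do.call(rbind, sig_rows)
               else data.frame(cutting = integer(0), trait = character(0),
                               marker = character(0))
  rownames(sig_table) <- NULL
  utils::write.csv(sig_table,
                   file.path(cfg$out_dir, "significant_markers.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, "significant_markers.csv")
  invisible(list(dir = cfg$out_dir, files = files, cfg = cfg,
                 scans = scans, significant = sig_table))
}

#' Write a run summary and machine-readable manifest
#'
#' @param artifacts list(s) returned by \code{\link{run_full_analysis}}
#'   and/or \code{\link{run_gwas_per_cutting}} (concatenate their
#'   \code{files} under one \code{dir}).
#' @return Invisible paths of report.txt and manifest.json.
#' @export
write_report <- function(artifacts) {
  dir <- artifacts$dir
  files <- sort(unique(artifacts$files))
  lines <- c("Run summary", "===========", "")
  if (!is.null(artifacts$accuracy_comparison)) {
    lines <- c(lines, "Accuracy by trait and model:",
               utils::capture.output(print(artifacts$accuracy_comparison)),
               "")
  }
  if (!is.null(artifacts$significant)) {
    lines <- c(lines,
               if (nrow(artifacts$significant))
                 c("Significant trait-marker associations:",
                   utils::capture.output(print(artifacts$significant)))
               else "Zero significant trait-marker associations.",
               "")
  }
  lines <- c(lines, "Artifacts:", paste0("  ", files))
  report_path <- file.path(dir, "report.txt")
  writeLines(lines, report_path)
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "ssrgblup",
    version = as.character(utils::packageVersion("ssrgblup")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = artifacts$cfg$seed,
    files = stats::setNames(as.list(unname(hashes)), files),
    manifest_hash = unname(tools::md5sum(
      tempfile_with(paste(unname(hashes), collapse = "")))))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(report = report_path, manifest = manifest_path))
}

## write a string to a temp file and return its path (for hashing)
tempfile_with <- function(text) {
  f <- tempfile()
  writeLines(text, f)
  f
}
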