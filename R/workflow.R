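# provenance sidecar shared by every run_* driver
write_provenance <- function(outdir, step, params, seed) {
  prov <- list(
    step = step,
    package = "mrmlfq",
    version = as.character(utils::packageVersion("mrmlfq")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = params)
  jsonlite::write_json(prov, file.path(outdir, paste0(step, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

check_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  outdir
}

#' Simulate study data to disk
#'
#' Writes an abundance matrix, sample metadata, ground truth, and a
#' calibration chromatogram series (as integrated ratio tables) plus a
#' provenance sidecar. A missing seed is generated and logged.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; generated and logged when `NULL`.
#' @param ... Passed to [simulate_abundance_matrix()].
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(outdir, seed = NULL, ...) {
  check_outdir(outdir)
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; using generated seed ", seed)
  }
  sim <- simulate_abundance_matrix(seed = seed, ...)
  paths <- list(
    matrix = file.path(outdir, "abundance.csv"),
    metadata = file.path(outdir, "metadata.csv"),
    truth = file.path(outdir, "truth.csv"))
  write_abundance_matrix(sim$matrix, paths$matrix)
  write_sample_metadata(sim$metadata, paths$metadata)
  utils::write.csv(sim$truth, paths$truth, row.names = FALSE, quote = FALSE)
  write_provenance(outdir, "simulate", c(list(...), list()), seed)
  invisible(paths)
}

#' Run calibration validation and sample quantitation
#'
#' Simulates (or accepts) a calibration series, fits per-analysis
#' weighted curves, validates precision/accuracy, quantifies the
#' supplied sample chromatogram sets, and writes the quantitation
#' report, validation report, and provenance.
#'
#' @param outdir Output directory.
#' @param series Calibration series ([simulate_calibration_series()]
#'   output); simulated with defaults when `NULL`.
#' @param samples Named list of `chromatogram_set` objects to quantify.
#' @param sample_groups Optional factor over `samples` (e.g. genotype);
#'   when present a two-sided Wilcoxon rank-sum comparison of
#'   concentrations is reported.
#' @param seed Seed for the default simulated series.
#' @param reconstitution_volume uL per 100 ug digest.
#' @param ... Passed to [simulate_calibration_series()].
#' @return Invisible list: `validation`, `quant` (data frame),
#'   `group_test`.
#' @export
run_quant <- function(outdir, series = NULL, samples = list(),
                      sample_groups = NULL, seed = NULL,
                      reconstitution_volume = 30, ...) {
  check_outdir(outdir)
  if (is.null(series)) {
    if (is.null(seed)) {
      seed <- sample.int(.Machine$integer.max, 1)
      message("no seed supplied; using generated seed ", seed)
    }
    series <- simulate_calibration_series(n_analyses = 5, seed = seed, ...)
  }
  cal <- process_calibration(series)
  val <- cal$validation
  utils::write.csv(val$levels, file.path(outdir, "validation_report.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!any(val$levels$pass)) {
    stop("calibration failed validation at every level; see ",
         file.path(outdir, "validation_report.csv"))
  }
  curve <- cal$curves[[1]]
  quant <- NULL
  if (length(samples)) {
    quant <- do.call(rbind, lapply(names(samples), function(id) {
      qr <- tryCatch(
        quantify_sample(samples[[id]], curve, lod = val$lod,
                        reconstitution_volume = reconstitution_volume),
        error = function(e) stop("sample ", id, ": ", conditionMessage(e),
                                 call. = FALSE))
      data.frame(sample = id, ratio = qr$ratio, rdotp = qr$rdotp,
                 fmol_per_ul = qr$concentration,
                 fmol_per_100ug = qr$amount_per_100ug,
                 verdict = qr$verdict, stringsAsFactors = FALSE)
    }))
    utils::write.csv(quant, file.path(outdir, "quant_report.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  group_test <- NULL
  if (!is.null(quant) && !is.null(sample_groups)) {
    gs <- split(quant$fmol_per_ul, sample_groups)
    if (length(gs) == 2) {
      group_test <- wilcoxon_rank_sum(gs[[1]], gs[[2]])
    }
  }
  write_provenance(outdir, "quant",
                   list(reconstitution_volume = reconstitution_volume,
                        lod = val$lod), seed)
  invisible(list(validation = val, quant = quant, group_test = group_test,
                 curves = cal$curves))
}

#' Run the differential-expression pipeline from files or objects
#'
#' @param outdir Output directory.
#' @param mat Matrix or path to an abundance table.
#' @param metadata Data frame or path to a metadata table.
#' @param ... Passed to [run_de_pipeline()].
#' @return Invisible pipeline result.
#' @export
run_de <- function(outdir, mat, metadata, ...) {
  check_outdir(outdir)
  if (is.character(mat)) mat <- read_abundance_matrix(mat)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  tissues <- unique(metadata$tissue)
  if (is.null(tissues)) tissues <- "all"
  out <- list()
  for (tn in tissues) {
    idx <- if ("tissue" %in% names(metadata)) metadata$tissue == tn
           else rep(TRUE, nrow(metadata))
    md <- metadata[idx, ]
    res <- run_de_pipeline(mat[, md$sample, drop = FALSE], md, ...)
    tag <- if (length(tissues) > 1) paste0("_", tn) else ""
    utils::write.csv(res$results,
                     file.path(outdir, paste0("de_results", tag, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(sample = rownames(res$pca$scores),
                                res$pca$scores),
                     file.path(outdir, paste0("pca_scores", tag, ".csv")),
                     row.names = FALSE, quote = FALSE)
    out[[tn]] <- res
  }
  write_provenance(outdir, "de", list(tissues = tissues), seed = NULL)
  invisible(if (length(tissues) == 1) out[[1]] else out)
}

#' Run over-representation and cross-tissue overlap analysis
#'
#' @param outdir Output directory.
#' @param de_sets Named list of per-tissue differential identifier
#'   sets.
#' @param gmt Path to a GMT gene-set file, or `NULL` for overlap-only
#'   mode.
#' @param universe Background identifiers (required with `gmt`).
#' @return Invisible list: `enrichment` (per tissue, or `NULL`),
#'   `overlap`.
#' @export
run_enrich <- function(outdir, de_sets, gmt = NULL, universe = NULL) {
  check_outdir(outdir)
  enrichment <- NULL
  if (!is.null(gmt)) {
    sets <- read_gmt(gmt)
    enrichment <- lapply(names(de_sets), function(tn) {
      q <- intersect(de_sets[[tn]], universe)
      if (!length(q)) {
        warning("tissue ", tn, ": empty query after harmonisation")
        return(NULL)
      }
      rows <- ora_hypergeometric(q, sets, universe)
      utils::write.csv(rows,
                       file.path(outdir, paste0("enrichment_", tn, ".csv")),
                       row.names = FALSE, quote = FALSE)
      rows
    })
    names(enrichment) <- names(de_sets)
  }
  overlap <- NULL
  if (length(de_sets) >= 2) {
    overlap <- cross_tissue_overlap(de_sets)
    utils::write.csv(overlap$counts,
                     file.path(outdir, "overlap_membership.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(threshold = names(overlap$summary),
                                count = as.integer(overlap$summary)),
                     file.path(outdir, "overlap_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_provenance(outdir, "enrich",
                   list(gmt = gmt, n_sets = length(de_sets)), seed = NULL)
  invisible(list(enrichment = enrichment, overlap = overlap))
}
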