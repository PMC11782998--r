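# run code under a seed without clobbering the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a set of co-eluting MRM transition chromatograms
#'
#' Each transition trace is a Gaussian peak centred at the peptide's
#' retention time, with area proportional to the true analyte amount
#' times the fragment's relative intensity, on a uniform time grid.
#' Light and heavy channels co-elute. Noise is multiplicative
#' log-normal on the peak amplitude (parameterised by a coefficient of
#' variation) plus an additive Gaussian baseline; intensities are
#' clipped at zero.
#'
#' @param amount_light,amount_heavy True analyte amounts (fmol or
#'   fmol/uL; the response factor sets the area per unit).
#' @param rel_intensities Named numeric vector of relative fragment
#'   intensities (e.g. `c(y4 = 0.5, y5 = 0.3, y6 = 0.2)`), shared by
#'   light and heavy channels.
#' @param rt Retention time (min) of the shared apex.
#' @param peak_sigma Gaussian peak width sigma (min); must be positive.
#' @param response_factor Area (intensity.min) per unit amount.
#' @param noise_cv CV of multiplicative log-normal amplitude noise.
#' @param baseline_mean,baseline_sd Additive baseline level and noise.
#' @param time_range,dt Time grid (min).
#' @param seed Optional integer; identical seeds give identical traces.
#' @return A long-format data frame (`fragment`, `label`, `time`,
#'   `intensity`) of class `"chromatogram_set"`.
#' @export
simulate_chromatogram <- function(amount_light, amount_heavy = 0,
                                  rel_intensities = c(y4 = 0.5, y5 = 0.3, y6 = 0.2),
                                  rt = 1.6, peak_sigma = 0.02,
                                  response_factor = 1000,
                                  noise_cv = 0,
                                  baseline_mean = 0, baseline_sd = 0,
                                  time_range = c(rt - 0.4, rt + 0.4),
                                  dt = 0.004, seed = NULL) {
  if (peak_sigma <= 0) stop("peak width sigma must be positive")
  stopifnot(amount_light >= 0, amount_heavy >= 0)
  with_local_seed(seed, {
    times <- seq(time_range[1], time_range[2], by = dt)
    shape <- exp(-((times - rt)^2) / (2 * peak_sigma^2))
    out <- list()
    sdlog <- sqrt(log(1 + noise_cv^2))
    for (label in c("light", "heavy")) {
      amount <- if (label == "light") amount_light else amount_heavy
      for (fr in names(rel_intensities)) {
        area <- amount * response_factor * rel_intensities[[fr]]
        if (noise_cv > 0) {
          area <- area * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        }
        amp <- area / (peak_sigma * sqrt(2 * pi))
        y <- amp * shape + baseline_mean
        if (baseline_sd > 0) y <- y + stats::rnorm(length(y), 0, baseline_sd)
        out[[paste(fr, label)]] <- data.frame(
          fragment = fr, label = label, time = times,
          intensity = pmax(y, 0))
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    class(res) <- c("chromatogram_set", "data.frame")
    res
  })
}

#' Simulate a serial-dilution calibration series
#'
#' Emits a 1:2 serial-dilution ladder of light-peptide concentrations
#' with a constant heavy (SILS) spike, in replicate, across one or more
#' analyses, plus a zero calibrator (heavy spike only) and a blank
#' (solvent, no peptide). The top concentration and point count are
#' explicit parameters; defaults give an 11-point ladder from
#' 1000 fmol/uL with a 50 fmol/uL heavy spike.
#'
#' @param top_conc Highest calibrator concentration (fmol/uL).
#' @param n_points Number of 1:2 dilution points (>= 2).
#' @param heavy_conc Constant SILS spike (fmol/uL), default 50.
#' @param n_replicates Replicates per level per analysis (>= 1).
#' @param n_analyses Independent analyses (curves).
#' @param noise_cv Multiplicative CV on peak areas.
#' @param seed Integer seed; the whole series is deterministic given it.
#' @param ... Passed to [simulate_chromatogram()] (peak shape, grid).
#' @return Data frame with one row per simulated injection: `analysis`,
#'   `level` (`"cal"`, `"zero"`, `"blank"`), `nominal` (fmol/uL),
#'   `replicate`, and a list-column `chromatogram`.
#' @export
simulate_calibration_series <- function(top_conc = 1000, n_points = 11,
                                        heavy_conc = 50, n_replicates = 3,
                                        n_analyses = 1, noise_cv = 0.05,
                                        seed = NULL, ...) {
  if (n_points < 2 || top_conc <= 0) {
    stop("need >= 2 dilution points and a positive top concentration")
  }
  if (n_replicates < 1) stop("need at least one replicate per level")
  nominal <- top_conc / 2^(seq_len(n_points) - 1)
  with_local_seed(seed, {
    rows <- list()
    for (a in seq_len(n_analyses)) {
      for (conc in c(nominal, 0, NA)) {   # NA marks the blank
        level <- if (is.na(conc)) "blank" else if (conc == 0) "zero" else "cal"
        nrep <- if (level == "cal") n_replicates else 1L
        for (r in seq_len(nrep)) {
          ch <- simulate_chromatogram(
            amount_light = if (level == "cal") conc else 0,
            amount_heavy = if (level == "blank") 0 else heavy_conc,
            noise_cv = noise_cv, ...)
          rows[[length(rows) + 1L]] <- data.frame(
            analysis = a, level = level,
            nominal = if (level == "cal") conc else 0,
            replicate = r)
          rows[[length(rows)]]$chromatogram <- list(ch)
        }
      }
    }
    res <- do.call(rbind, rows)
    attr(res, "heavy_conc") <- heavy_conc
    res
  })
}

#' Simulate a knockout-vs-wild-type protein abundance matrix
#'
#' Log-normal protein intensities for a two-genotype design with
#' run-order batch structure, age and sex covariates, and
#' intensity-dependent zeros. A configured fraction of proteins carries
#' a genotype log2 fold change; batch effects are additive on the log2
#' scale and piecewise-constant over consecutive run-order blocks.
#' Intensities below `zero_threshold` are recorded as 0 (left
#' censoring), emulating values missing because abundance is low.
#' Ground truth (which proteins are differential and their true log2FC)
#' is returned alongside.
#'
#' Defaults mirror an 8 knockout vs 10 wild-type plasma design with
#' 2000 proteins, 10% differential at |log2FC| = 1.5, residual noise
#' sigma = 0.3 (log2), and three run-order blocks.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param n_ko,n_wt Group sizes (>= 2).
#' @param de_fraction Fraction of proteins with a genotype effect.
#' @param logfc_effect Effect size; true log2FC is `+/- logfc_effect`
#'   with random sign (or a function(n) returning effects).
#' @param noise_sd Residual log2-scale standard deviation.
#' @param n_batches Number of consecutive run-order blocks.
#' @param batch_offsets Log2-scale offset per block (recycled);
#'   default alternating +/-0.5.
#' @param age_effect Log2 units per week of age (applied to all
#'   proteins); ages drawn uniformly on `age_range`.
#' @param sex_effect Log2 offset of males vs females.
#' @param age_range Age range in weeks.
#' @param mean_log2,sd_log2 Distribution of baseline protein log2 means.
#' @param zero_threshold Intensities below this are recorded as 0.
#' @param tissue Tissue label stored in the metadata.
#' @param seed Integer seed.
#' @return List with `matrix` (protein x sample), `metadata` (data
#'   frame: `sample`, `genotype`, `age`, `sex`, `run_order`, `tissue`),
#'   and `truth` (`protein`, `is_de`, `true_logfc`).
#' @export
simulate_abundance_matrix <- function(n_proteins = 2000, n_ko = 8, n_wt = 10,
                                      de_fraction = 0.10, logfc_effect = 1.5,
                                      noise_sd = 0.3,
                                      n_batches = 3,
                                      batch_offsets = c(0, 0.5, -0.5),
                                      age_effect = 0, sex_effect = 0,
                                      age_range = c(8, 20),
                                      mean_log2 = 20, sd_log2 = 2,
                                      zero_threshold = 2^15,
                                      tissue = "plasma", seed = NULL) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (n_ko < 2 || n_wt < 2) stop("each genotype group needs >= 2 samples")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  with_local_seed(seed, {
    n <- n_ko + n_wt
    genotype <- c(rep("KO", n_ko), rep("WT", n_wt))
    # interleave run order so batches are not confounded with genotype
    run_order <- order(order(c(seq(1, n, length.out = n_ko) + 0.25,
                               seq(1, n, length.out = n_wt))))
    batch <- cut(run_order, breaks = n_batches, labels = FALSE)
    age <- round(stats::runif(n, age_range[1], age_range[2]), 1)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    offsets <- rep_len(batch_offsets, n_batches)

    base <- stats::rnorm(n_proteins, mean_log2, sd_log2)
    n_de <- round(de_fraction * n_proteins)
    is_de <- rep(FALSE, n_proteins)
    if (n_de > 0) is_de[sample.int(n_proteins, n_de)] <- TRUE
    true_logfc <- numeric(n_proteins)
    if (is.function(logfc_effect)) {
      true_logfc[is_de] <- logfc_effect(sum(is_de))
    } else {
      true_logfc[is_de] <- logfc_effect *
        sample(c(-1, 1), sum(is_de), replace = TRUE)
    }

    log2mat <- matrix(base, n_proteins, n, byrow = FALSE) +
      outer(true_logfc, as.numeric(genotype == "KO")) +
      matrix(offsets[batch], n_proteins, n, byrow = TRUE) +
      matrix(age_effect * (age - mean(age)), n_proteins, n, byrow = TRUE) +
      matrix(sex_effect * (sex == "M"), n_proteins, n, byrow = TRUE) +
      matrix(stats::rnorm(n_proteins * n, 0, noise_sd), n_proteins, n)

    mat <- 2^log2mat
    mat[mat < zero_threshold] <- 0
    proteins <- sprintf("P%05d", seq_len(n_proteins))
    samples <- sprintf("S%02d", seq_len(n))
    dimnames(mat) <- list(proteins, samples)
    list(
      matrix = mat,
      metadata = data.frame(
        sample = samples, genotype = genotype, age = age, sex = sex,
        run_order = run_order, tissue = tissue,
        stringsAsFactors = FALSE),
      truth = data.frame(protein = proteins, is_de = is_de,
                         true_logfc = true_logfc,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a multi-tissue abundance panel with shared differential proteins
#'
#' Generates one abundance matrix per tissue in which a configured
#' fraction of each tissue's differential proteins is drawn from a
#' common shared set, so cross-tissue overlap counting can be validated
#' against a planted ground truth.
#'
#' @param n_tissues Number of tissues (>= 2).
#' @param shared_fraction Fraction of each tissue's differential set
#'   drawn from the common core, in [0, 1].
#' @param tissues Optional tissue names.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_abundance_matrix()].
#' @return List with `tissues` (named list of per-tissue simulations)
#'   and `shared` (the planted common differential protein ids).
#' @export
simulate_tissue_panel <- function(n_tissues = 4, shared_fraction = 0.25,
                                  tissues = NULL, seed = NULL,
                                  n_proteins = 2000, de_fraction = 0.10,
                                  ...) {
  if (n_tissues < 2) stop("need at least two tissues")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0,1]")
  }
  if (is.null(tissues)) tissues <- paste0("tissue", seq_len(n_tissues))
  with_local_seed(seed, {
    proteins <- sprintf("P%05d", seq_len(n_proteins))
    n_de <- round(de_fraction * n_proteins)
    n_shared <- round(shared_fraction * n_de)
    if (n_shared + n_tissues * (n_de - n_shared) > n_proteins) {
      stop("not enough proteins for disjoint tissue-specific ",
           "differential sets; raise n_proteins or shared_fraction")
    }
    shared <- sample(proteins, n_shared)
    pool <- setdiff(proteins, shared)
    sims <- list()
    for (tn in tissues) {
      own <- if (n_de > n_shared) sample(pool, n_de - n_shared) else character()
      pool <- setdiff(pool, own)   # tissue-specific sets stay disjoint
      de_set <- c(shared, own)
      sim <- simulate_abundance_matrix(
        n_proteins = n_proteins, de_fraction = 0, tissue = tn,
        seed = sample.int(.Machine$integer.max, 1), ...)
      # plant the tissue's differential set deterministically
      idx <- match(de_set, proteins)
      sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
      eff <- 1.5 * sgn
      ko <- sim$metadata$genotype == "KO"
      sim$matrix[idx, ko] <- sim$matrix[idx, ko] * 2^eff
      sim$truth$is_de[idx] <- TRUE
      sim$truth$true_logfc[idx] <- eff
      sims[[tn]] <- sim
    }
    list(tissues = sims, shared = sort(shared))
  })
}
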