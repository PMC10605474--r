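# Molecule-level simulator: generates distance sets, alignment fixtures and
# cohort tables with the statistical structure the sizing algorithm assumes.

#' Describe a simulated allele
#'
#' @param repeats True allele size in repeat units (0 for a reference
#'   allele; may be any real).
#' @param sd_repeats Per-molecule standard deviation in repeat units.
#'   Defaults to 5% of the allele size with a floor of 10 repeats — the
#'   dispersion level observed across samples of this locus, dominated by
#'   optical measurement error.
#' @param fraction Fraction of molecules drawn from this allele; fractions
#'   over a sample must sum to 1.
#' @return A list of class `allele_spec`.
#' @export
allele_spec <- function(repeats, sd_repeats = max(0.05 * abs(repeats), 10),
                        fraction = 1) {
  stopifnot(is.numeric(repeats), length(repeats) == 1L)
  if (!(sd_repeats > 0)) {
    stop_ogmstr("validation", "sd_repeats must be positive")
  }
  if (!(fraction > 0 && fraction <= 1)) {
    stop_ogmstr("validation", "fraction must lie in (0, 1]")
  }
  structure(list(repeats = repeats, sd_repeats = sd_repeats,
                 fraction = fraction),
            class = "allele_spec")
}

#' Simulation settings
#'
#' @param n_molecules Number of molecules to draw (typical coverage at a
#'   single locus yields 30-200 spanning molecules).
#' @param outlier_rate Fraction of molecules replaced by uniform
#'   contamination (default 0.02), emulating chimeric or misaligned
#'   molecules.
#' @param outlier_range_bp Range of the uniform contamination (default
#'   500-60000 bp).
#' @param locus A [locus_spec()] (default [rfc1_locus()]).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_molecules, outlier_rate = 0.02,
                       outlier_range_bp = c(500, 60000),
                       locus = rfc1_locus(), seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop_ogmstr("validation", "seed is mandatory for reproducibility")
  }
  stopifnot(is_count(n_molecules), inherits(locus, "locus_spec"))
  if (!(outlier_rate >= 0 && outlier_rate < 1)) {
    stop_ogmstr("validation", "outlier_rate must lie in [0, 1)")
  }
  if (length(outlier_range_bp) != 2L ||
      outlier_range_bp[1] <= 0 || diff(outlier_range_bp) <= 0) {
    stop_ogmstr("validation", "outlier_range_bp must be a valid interval")
  }
  if (outlier_rate > 0.2) {
    warn_ogmstr("config", "outlier_rate %.2f is unusually high", outlier_rate)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 outlier_rate = outlier_rate,
                 outlier_range_bp = as.numeric(outlier_range_bp),
                 locus = locus,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-molecule intermarker distances for one sample
#'
#' Each molecule is assigned to an allele with probability equal to the
#' allele fraction and its distance drawn from
#' `Normal(reference + repeats * motif, (sd_repeats * motif)^2)`; a
#' `Bernoulli(outlier_rate)` subset is then replaced by
#' `Uniform(outlier_range_bp)` contamination.  Deterministic under
#' `config$seed`.  The generating truth is attached as
#' `attr(, "truth")` (alleles, per-molecule allele index, outlier flags).
#'
#' @param alleles List of one or two [allele_spec()]s (a single
#'   `allele_spec` is accepted); fractions must sum to 1.
#' @param config A [sim_config()].
#' @param sample_id Sample identifier (default `"sim"`).
#' @return A [distance_set()].
#' @export
simulate_molecule_distances <- function(alleles, config, sample_id = "sim") {
  if (inherits(alleles, "allele_spec")) alleles <- list(alleles)
  stopifnot(inherits(config, "sim_config"))
  if (length(alleles) < 1L || length(alleles) > 2L) {
    stop_ogmstr("validation", "1 or 2 alleles expected, got %d",
                length(alleles))
  }
  fr <- vapply(alleles, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_ogmstr("validation", "allele fractions must sum to 1 (got %.4f)",
                sum(fr))
  }
  locus <- config$locus
  n <- config$n_molecules
  out <- with_seed(config$seed, {
    which_allele <- sample.int(length(alleles), n, replace = TRUE, prob = fr)
    mu <- repeats_to_bp(vapply(alleles, `[[`, 0, "repeats"), locus)
    sdv <- vapply(alleles, `[[`, 0, "sd_repeats") * locus$motif_length_bp
    d <- stats::rnorm(n, mu[which_allele], sdv[which_allele])
    is_outlier <- stats::runif(n) < config$outlier_rate
    d[is_outlier] <- stats::runif(sum(is_outlier),
                                  config$outlier_range_bp[1],
                                  config$outlier_range_bp[2])
    d <- pmax(d, 1)  # physical distances are positive
    list(d = d, which_allele = which_allele, is_outlier = is_outlier)
  })
  dset <- distance_set(sample_id, out$d)
  attr(dset, "truth") <- list(alleles = alleles,
                              allele_index = out$which_allele,
                              is_outlier = out$is_outlier)
  dset
}

#' Simulate a cohort for cross-platform concordance analysis
#'
#' Draws true allele sizes from `allele_size_sampler`, then derives the
#' three platform measurements: optical mapping as truth plus 5% Gaussian
#' noise, Southern blot via the inverse of an affine bias
#' (`sb = (truth - b)/a + noise`, so that regressing OGM on SB recovers a
#' slope of about `a`), and long-read counts as truth plus Gaussian read
#' noise.  Writes the cohort CSV, the long-read reads CSV and a truth table
#' under `dir`.
#'
#' @param n_patients Number of patients.
#' @param allele_size_sampler Function `n -> n` true sizes (repeat units).
#'   Default samples uniformly over 250-2500 repeats.
#' @param sb_bias Numeric `c(a, b, noise_sd)`: affine bias slope `a > 0`,
#'   intercept `b`, and SB measurement noise (repeat units).
#' @param lr_reads_per_patient Long reads simulated per patient (default 2).
#' @param seed Integer seed.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param ogm_cv Coefficient of variation of the OGM measurement
#'   (default 0.05).
#' @param lr_noise_sd Per-read long-read noise in repeat units (default 30).
#' @return Invisibly, a list with `cohort`, `lr_reads` and `truth`
#'   data.frames and the file `paths` (when written).
#' @export
simulate_cohort <- function(n_patients,
                            allele_size_sampler = function(n) {
                              stats::runif(n, 250, 2500)
                            },
                            sb_bias = c(0.62, 232, 40),
                            lr_reads_per_patient = 2L,
                            seed,
                            dir = NULL,
                            ogm_cv = 0.05,
                            lr_noise_sd = 30) {
  if (missing(seed)) stop_ogmstr("validation", "seed is mandatory")
  a <- sb_bias[1]; b <- sb_bias[2]; noise_sd <- sb_bias[3]
  if (!(a > 0)) stop_ogmstr("validation", "sb_bias slope a must be > 0")
  stopifnot(is_count(n_patients))

  res <- with_seed(seed, {
    truth <- matrix(allele_size_sampler(2L * n_patients), ncol = 2L)
    truth <- t(apply(truth, 1, sort))
    ogm <- truth + stats::rnorm(length(truth), 0, ogm_cv * abs(truth))
    sb <- (truth - b) / a + stats::rnorm(length(truth), 0, noise_sd)
    reads <- lapply(seq_len(n_patients), function(i) {
      # long reads sample the larger allele (the one enrichment recovers)
      truth[i, 2] + stats::rnorm(lr_reads_per_patient, 0, lr_noise_sd)
    })
    list(truth = truth, ogm = ogm, sb = sb, reads = reads)
  })

  ids <- sprintf("SIM%02d", seq_len(n_patients))
  cohort <- data.frame(
    patient_id = ids,
    sb_allele1 = res$sb[, 1], sb_allele2 = res$sb[, 2],
    sb_homozygous = FALSE,
    ogm_mean1 = res$ogm[, 1], ogm_sd1 = ogm_cv * res$truth[, 1],
    ogm_mean2 = res$ogm[, 2], ogm_sd2 = ogm_cv * res$truth[, 2],
    ogm_homozygous = FALSE,
    stringsAsFactors = FALSE
  )
  lr_reads <- do.call(rbind, lapply(seq_len(n_patients), function(i) {
    data.frame(patient_id = ids[i],
               read_id = seq_len(lr_reads_per_patient),
               repeats = res$reads[[i]])
  }))
  truth <- data.frame(patient_id = ids,
                      allele1 = res$truth[, 1],
                      allele2 = res$truth[, 2])

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(cohort = file.path(dir, "cohort.csv"),
                  lr_reads = file.path(dir, "lr_reads.csv"),
                  truth = file.path(dir, "truth.csv"))
    utils::write.csv(cohort, paths$cohort, row.names = FALSE)
    utils::write.csv(lr_reads, paths$lr_reads, row.names = FALSE)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
  }
  invisible(list(cohort = cohort, lr_reads = lr_reads, truth = truth,
                 paths = paths))
}

#' Write a minimal XMAP/CMAP alignment fixture reproducing a distance set
#'
#' Emits a spec-conformant trio of files — `<prefix>.xmap`,
#' `<prefix>_r.cmap` (reference) and `<prefix>_q.cmap` (one query map per
#' molecule) — in which every molecule carries the two flanking labels plus
#' two decoy labels, such that [extract_intermarker_distances()] recovers
#' `dset` exactly (to the serialised 1e-4 bp precision).  Molecules alternate
#' between `+` and `-` orientation; `-` molecules have their label maps
#' mirrored, exercising the orientation invariance of the extraction.
#'
#' @param dset A [distance_set()].
#' @param locus A [locus_spec()].
#' @param path_prefix Path prefix for the three files.
#' @return Invisibly, a named list of the three paths.
#' @export
write_alignment_fixture <- function(dset, locus, path_prefix) {
  stopifnot(inherits(dset, "distance_set"), inherits(locus, "locus_spec"))
  left_id <- locus$marker_left_id %||% 2L
  right_id <- locus$marker_right_id %||% 3L
  ref_id <- "1"
  pad <- 5000

  ref_positions <- data.frame(
    site_id = c(left_id - 1L, left_id, right_id, right_id + 1L),
    position_bp = c(locus$marker_left_pos - pad, locus$marker_left_pos,
                    locus$marker_right_pos, locus$marker_right_pos + pad)
  )
  ref_len <- locus$marker_right_pos + 2 * pad

  paths <- list(xmap = paste0(path_prefix, ".xmap"),
                ref_cmap = paste0(path_prefix, "_r.cmap"),
                qry_cmap = paste0(path_prefix, "_q.cmap"))
  write_cmap_file(list(list(map_id = ref_id, positions = ref_positions,
                            length_bp = ref_len)),
                  paths$ref_cmap)

  n <- length(dset$distances_bp)
  qmaps <- vector("list", n)
  xrows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dset$distances_bp[i]
    fwd <- c(100, 100 + pad, 100 + pad + d, 100 + 2 * pad + d)
    qlen <- 200 + 2 * pad + d
    neg <- i %% 2L == 0L
    qpos <- if (neg) sort(qlen - fwd) else fwd
    # site index (ascending) matched to each of the 4 reference sites
    qsites <- if (neg) 4:1 else 1:4
    qmaps[[i]] <- list(map_id = as.character(dset$molecule_ids[i]),
                       positions = data.frame(site_id = 1:4,
                                              position_bp = qpos),
                       length_bp = qlen)
    xrows[[i]] <- data.frame(
      XmapEntryID = i,
      QryContigID = as.character(dset$molecule_ids[i]),
      RefContigID = ref_id,
      Orientation = if (neg) "-" else "+",
      Confidence = 20.0,
      Alignment = paste0(sprintf("(%d,%d)", ref_positions$site_id, qsites),
                         collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  write_cmap_file(qmaps, paths$qry_cmap)
  write_xmap_file(do.call(rbind, xrows), paths$xmap)
  invisible(paths)
}

write_cmap_file <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# CMAP File Version:\t0.1",
               "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition"),
             con)
  for (m in maps) {
    np <- nrow(m$positions)
    if (np > 0L) {
      writeLines(sprintf("%s\t%.4f\t%d\t%d\t1\t%.4f",
                         m$map_id, m$length_bp, np,
                         m$positions$site_id, m$positions$position_bp),
                 con)
    }
    # end-of-map sentinel row (LabelChannel 0)
    writeLines(sprintf("%s\t%.4f\t%d\t%d\t0\t%.4f",
                       m$map_id, m$length_bp, np,
                       max(m$positions$site_id, 0L) + 1L, m$length_bp),
               con)
  }
  invisible(path)
}

write_xmap_file <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# XMAP File Version:\t0.2",
               "#h XmapEntryID\tQryContigID\tRefContigID\tOrientation\tConfidence\tAlignment"),
             con)
  if (!is.null(df) && nrow(df) > 0L) {
    writeLines(sprintf("%d\t%s\t%s\t%s\t%.1f\t%s",
                       df$XmapEntryID, df$QryContigID, df$RefContigID,
                       df$Orientation, df$Confidence, df$Alignment),
               con)
  }
  invisible(path)
}
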