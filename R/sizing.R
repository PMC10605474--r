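#' Convert an intermarker distance to repeat units (and back)
#'
#' The expansion size in repeat units is the excess of the measured
#' intermarker distance over the reference distance, divided by the motif
#' length:
#' `repeats = (distance_bp - reference_distance_bp) / motif_length_bp`.
#' A molecule carrying the reference allele therefore maps to 0 repeats,
#' and values may be negative (a slightly contracted or mismeasured
#' reference allele).  Negative estimates are reported as-is, never
#' clamped.  Rounding to whole repeats (round-half-to-even) is applied at
#' presentation only, never inside the pipeline.
#'
#' @param distance_bp Numeric vector of intermarker distances (bp).
#' @param repeats Numeric vector of repeat counts.
#' @param locus A [locus_spec()].
#' @return `bp_to_repeats()` returns repeat units; `repeats_to_bp()` is its
#'   inverse.
#' @examples
#' bp_to_repeats(11443, rfc1_locus())  # a 4585 bp expansion -> 917 repeats
#' @export
bp_to_repeats <- function(distance_bp, locus) {
  stopifnot(inherits(locus, "locus_spec"))
  (distance_bp - locus$reference_distance_bp) / locus$motif_length_bp
}

#' @rdname bp_to_repeats
#' @export
repeats_to_bp <- function(repeats, locus) {
  stopifnot(inherits(locus, "locus_spec"))
  locus$reference_distance_bp + repeats * locus$motif_length_bp
}

#' Size the alleles of one sample from its molecule distances
#'
#' The full two-step sizing algorithm:
#' 1. *Outlier removal.*  A DBSCAN radius is chosen automatically as the
#'    knee of the `min_samples`-nearest-neighbour distance curve
#'    ([knee_epsilon()]); all molecules not belonging to any DBSCAN
#'    cluster are discarded as outliers ([dbscan_filter()]).
#' 2. *Allele decomposition.*  One- and two-component Gaussian mixtures
#'    are fitted to the kept distances ([fit_gmm()]); the two-component
#'    model is selected only if its BIC improves and both weights exceed
#'    the threshold ([select_model()]).
#'
#' Component means estimate allele sizes; standard deviations absorb the
#' optical measurement error and any somatic instability.  Fitted moments
#' are converted to repeat units via [bp_to_repeats()] and alleles sorted
#' ascending.  A single selected component is labelled
#' `"single-component (reported homozygous)"` — one component may also hide
#' two alleles of very similar size — otherwise `"two alleles"`.
#'
#' @param dset A [distance_set()] with at least `config$min_molecules`
#'   molecules.
#' @param locus A [locus_spec()].
#' @param config A [sizing_config()].
#' @return An object of class `sizing_result`: list with `sample_id`,
#'   `selected` (`mixture_fit`), `fit1`, `fit2`, `alleles` (data.frame with
#'   `mean_bp`, `sd_bp`, `weight`, `mean_repeats`, `sd_repeats`,
#'   `classification`, `instability_ratio`), `zygosity_label`, `n_total`,
#'   `n_kept`, `n_outliers`, `epsilon_used`.
#' @export
size_sample <- function(dset, locus, config = sizing_config()) {
  stopifnot(inherits(dset, "distance_set"), inherits(locus, "locus_spec"))
  d <- dset$distances_bp
  n <- length(d)
  if (n < config$min_molecules) {
    stop_ogmstr("insufficient_data",
                "sample '%s': %d molecules, need at least %d",
                dset$sample_id, n, config$min_molecules)
  }

  eps <- knee_epsilon(d, min_samples = config$min_samples,
                      S = config$knee_sensitivity)
  eps <- max(eps, .Machine$double.eps)
  flt <- dbscan_filter(d, eps, min_samples = config$min_samples)
  kept <- flt$kept
  if (length(kept) < 4L) {
    stop_ogmstr("insufficient_data",
                "sample '%s': only %d molecules left after outlier removal",
                dset$sample_id, length(kept))
  }

  fit1 <- fit_gmm(kept, 1L, config)
  fit2 <- fit_gmm(kept, 2L, config)
  sel <- select_model(fit1, fit2, config$weight_threshold)

  alleles <- sel$components
  alleles$mean_repeats <- bp_to_repeats(alleles$mean_bp, locus)
  alleles$sd_repeats <- alleles$sd_bp / locus$motif_length_bp
  alleles <- alleles[order(alleles$mean_repeats), , drop = FALSE]
  rownames(alleles) <- NULL
  alleles$classification <- classify_allele(alleles$mean_repeats, config)
  alleles$instability_ratio <- ifelse(alleles$mean_repeats > 0,
                                      alleles$sd_repeats / alleles$mean_repeats,
                                      NA_real_)

  structure(
    list(sample_id = dset$sample_id,
         selected = sel,
         fit1 = fit1,
         fit2 = fit2,
         alleles = alleles,
         zygosity_label = if (sel$k == 1L) {
           "single-component (reported homozygous)"
         } else {
           "two alleles"
         },
         n_total = n,
         n_kept = length(kept),
         n_outliers = n - length(kept),
         epsilon_used = eps),
    class = "sizing_result"
  )
}

classify_allele <- function(mean_repeats, config) {
  ifelse(mean_repeats < config$normal_threshold_repeats, "normal",
         ifelse(mean_repeats >= config$expanded_threshold_repeats,
                "expanded", "intermediate"))
}

#' @export
print.sizing_result <- function(x, ...) {
  cat(sprintf("<sizing_result> sample %s: %s\n", x$sample_id,
              x$zygosity_label))
  cat(sprintf("  molecules: %d total, %d kept, %d outliers (epsilon %.1f bp)\n",
              x$n_total, x$n_kept, x$n_outliers, x$epsilon_used))
  cat(sprintf("  BIC: k=1 %.1f, k=2 %.1f -> k = %d selected\n",
              x$fit1$bic, x$fit2$bic, x$selected$k))
  a <- x$alleles
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  allele %d: %.0f +/- %.0f repeats (weight %.2f, %s)\n",
                i, a$mean_repeats[i], a$sd_repeats[i], a$weight[i],
                a$classification[i]))
  }
  invisible(x)
}

#' Flatten one or more sizing results into a per-allele table
#'
#' @param results A `sizing_result` or list of them.
#' @return A data.frame with one row per allele: sample_id, k, allele index,
#'   mean and sd in repeats and bp, weight, classification, instability
#'   ratio, molecule counts, epsilon and both BICs.
#' @export
sizing_table <- function(results) {
  if (inherits(results, "sizing_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    a <- r$alleles
    data.frame(sample_id = r$sample_id,
               k = r$selected$k,
               allele = seq_len(nrow(a)),
               mean_repeats = a$mean_repeats,
               sd_repeats = a$sd_repeats,
               mean_bp = a$mean_bp,
               sd_bp = a$sd_bp,
               weight = a$weight,
               classification = a$classification,
               instability_ratio = a$instability_ratio,
               zygosity = r$zygosity_label,
               n_total = r$n_total,
               n_kept = r$n_kept,
               n_outliers = r$n_outliers,
               epsilon_used = r$epsilon_used,
               bic_k1 = r$fit1$bic,
               bic_k2 = r$fit2$bic,
               stringsAsFactors = FALSE)
  }))
}
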