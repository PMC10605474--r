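#' Define a repeat locus by its flanking optical-map labels
#'
#' A repeat expansion is invisible to optical mapping except as a change in
#' the distance between the two labelled sites that flank it.  A
#' `locus_spec` records those two flanking label positions on the reference,
#' the reference intermarker distance they imply, and the length of the
#' repeated motif, so that molecule distances can be converted into repeat
#' units.
#'
#' For the RFC1 locus on hg38 the flanking labels sit at
#' chr4:39,343,732 and chr4:39,350,590 (reference label-site ids 7723 and
#' 7724 on the chromosome 4 label map), giving a reference intermarker
#' distance of 6858 bp around the pentanucleotide (5 bp) repeat.
#' [rfc1_locus()] returns exactly that definition.
#'
#' @param chrom Chromosome name, e.g. `"chr4"`.
#' @param marker_left_pos,marker_right_pos Reference coordinates (bp) of the
#'   left and right flanking labels; `marker_right_pos` must be strictly
#'   greater than `marker_left_pos`.
#' @param motif_length_bp Length of the repeated motif in bp (5 for a
#'   pentanucleotide repeat).
#' @param marker_left_id,marker_right_id Optional reference label-site ids
#'   (integers) identifying the two flanking labels on the reference CMAP;
#'   when absent, markers are resolved by position (see
#'   [extract_intermarker_distances()]).
#' @return An object of class `locus_spec`: a list with fields `chrom`,
#'   `marker_left_pos`, `marker_right_pos`, `reference_distance_bp`,
#'   `motif_length_bp`, `marker_left_id`, `marker_right_id`.
#' @examples
#' locus_spec("chr4", 39343732, 39350590, motif_length_bp = 5)
#' rfc1_locus()
#' @export
locus_spec <- function(chrom, marker_left_pos, marker_right_pos,
                       motif_length_bp,
                       marker_left_id = NULL, marker_right_id = NULL) {
  if (!is.character(chrom) || length(chrom) != 1L) {
    stop_ogmstr("validation", "chrom must be a single string")
  }
  if (!is.numeric(marker_left_pos) || !is.numeric(marker_right_pos) ||
      marker_right_pos <= marker_left_pos) {
    stop_ogmstr("validation",
                "marker_right_pos (%s) must exceed marker_left_pos (%s)",
                format(marker_right_pos), format(marker_left_pos))
  }
  if (!is_count(motif_length_bp)) {
    stop_ogmstr("validation", "motif_length_bp must be a positive integer")
  }
  structure(
    list(
      chrom = chrom,
      marker_left_pos = as.numeric(marker_left_pos),
      marker_right_pos = as.numeric(marker_right_pos),
      reference_distance_bp = as.numeric(marker_right_pos - marker_left_pos),
      motif_length_bp = as.integer(motif_length_bp),
      marker_left_id = if (is.null(marker_left_id)) NULL else as.integer(marker_left_id),
      marker_right_id = if (is.null(marker_right_id)) NULL else as.integer(marker_right_id)
    ),
    class = "locus_spec"
  )
}

#' @rdname locus_spec
#' @export
rfc1_locus <- function() {
  locus_spec("chr4", 39343732, 39350590, motif_length_bp = 5,
             marker_left_id = 7723L, marker_right_id = 7724L)
}

#' Parse a "chr:start-end" region string into a locus definition
#'
#' @param region Region string, e.g. `"chr4:39343732-39350590"`.
#' @inheritParams locus_spec
#' @return A [locus_spec()].
#' @export
parse_locus <- function(region, motif_length_bp,
                        marker_left_id = NULL, marker_right_id = NULL) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) {
    stop_ogmstr("validation",
                "cannot parse locus '%s' (expected chr:start-end)", region)
  }
  locus_spec(m[2], as.numeric(m[3]), as.numeric(m[4]), motif_length_bp,
             marker_left_id = marker_left_id, marker_right_id = marker_right_id)
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("<locus_spec> %s:%s-%s  reference distance %s bp, motif %d bp\n",
              x$chrom, format(x$marker_left_pos, scientific = FALSE),
              format(x$marker_right_pos, scientific = FALSE),
              format(x$reference_distance_bp, scientific = FALSE),
              x$motif_length_bp))
  if (!is.null(x$marker_left_id)) {
    cat(sprintf("  flanking label ids: %d / %d\n",
                x$marker_left_id, x$marker_right_id))
  }
  invisible(x)
}

#' Per-sample set of molecule intermarker distances
#'
#' The algorithm's native input: one positive distance (bp) per molecule
#' spanning both flanking labels of the locus.
#'
#' @param sample_id Sample identifier.
#' @param distances_bp Numeric vector of positive distances in bp.
#' @param molecule_ids Parallel vector of molecule identifiers (defaults to
#'   `seq_along(distances_bp)`).
#' @return An object of class `distance_set`.
#' @export
distance_set <- function(sample_id, distances_bp,
                         molecule_ids = seq_along(distances_bp)) {
  distances_bp <- as.numeric(distances_bp)
  if (length(distances_bp) != length(molecule_ids)) {
    stop_ogmstr("validation",
                "distances_bp and molecule_ids differ in length (%d vs %d)",
                length(distances_bp), length(molecule_ids))
  }
  if (any(!is.finite(distances_bp)) || any(distances_bp <= 0)) {
    stop_ogmstr("validation",
                "all distances must be finite and > 0 (sample '%s')", sample_id)
  }
  structure(
    list(sample_id = as.character(sample_id),
         distances_bp = distances_bp,
         molecule_ids = molecule_ids),
    class = "distance_set"
  )
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("<distance_set> sample %s: %d molecules, median %.0f bp\n",
              x$sample_id, length(x$distances_bp),
              stats::median(x$distances_bp)))
  invisible(x)
}

#' @export
length.distance_set <- function(x) length(x$distances_bp)
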