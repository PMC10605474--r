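#' Extract per-molecule intermarker distances at a locus
#'
#' Collects, over all molecules whose alignment matches both flanking
#' labels of the locus, the distance between the two matched label positions
#' on the molecule's own label map.  The absolute value is taken, so the
#' result does not depend on alignment orientation.  Molecules matching only
#' one (or neither) flanking label are skipped.
#'
#' If an alignment matches one reference marker with several query sites
#' (split matches), the mean of the matched query positions is used for that
#' marker and the molecule id is recorded in the `split_matches` attribute
#' of the result.
#'
#' @param alignments List of `molecule_alignment` objects from [read_xmap()].
#' @param ref_map `label_map` of the reference contig carrying the locus.
#' @param qry_maps List of molecule `label_map`s from [read_cmap()]; must
#'   contain every molecule referenced by `alignments`.
#' @param locus A [locus_spec()].  Markers are resolved to reference label
#'   sites by id when `marker_left_id`/`marker_right_id` are set, otherwise
#'   by position (nearest reference label within 500 bp, else an error:
#'   labels, not genomic coordinates, are the alignment currency).
#' @param sample_id Sample identifier for the returned set.
#' @param min_confidence Optional minimum alignment confidence; `NULL`
#'   (default) applies no filter.
#' @return A [distance_set()] (possibly empty, with a warning, when no
#'   molecule spans both markers).
#' @export
extract_intermarker_distances <- function(alignments, ref_map, qry_maps,
                                          locus, sample_id,
                                          min_confidence = NULL) {
  stopifnot(inherits(locus, "locus_spec"))
  left_id <- resolve_marker(ref_map, locus$marker_left_id,
                            locus$marker_left_pos)
  right_id <- resolve_marker(ref_map, locus$marker_right_id,
                             locus$marker_right_pos)

  qry_index <- stats::setNames(qry_maps,
                               vapply(qry_maps, `[[`, "", "map_id"))
  distances <- numeric(0)
  mol_ids <- character(0)
  split_ids <- character(0)

  for (aln in alignments) {
    if (aln$ref_contig_id != ref_map$map_id) next
    if (!is.null(min_confidence) &&
        is.finite(aln$confidence) && aln$confidence < min_confidence) next
    qsites_l <- aln$pairs[aln$pairs[, "ref_site"] == left_id, "qry_site"]
    qsites_r <- aln$pairs[aln$pairs[, "ref_site"] == right_id, "qry_site"]
    if (length(qsites_l) == 0L || length(qsites_r) == 0L) next

    qmap <- qry_index[[aln$molecule_id]]
    if (is.null(qmap)) {
      stop_ogmstr("consistency",
                  "alignment references molecule '%s' absent from query maps",
                  aln$molecule_id)
    }
    pos_l <- site_positions(qmap, qsites_l, aln$molecule_id)
    pos_r <- site_positions(qmap, qsites_r, aln$molecule_id)
    if (length(qsites_l) > 1L || length(qsites_r) > 1L) {
      split_ids <- c(split_ids, aln$molecule_id)
    }
    distances <- c(distances, abs(mean(pos_r) - mean(pos_l)))
    mol_ids <- c(mol_ids, aln$molecule_id)
  }

  if (length(distances) == 0L) {
    warn_ogmstr("no_spanning_molecules",
                "sample '%s': no molecule spans both markers", sample_id)
    out <- structure(list(sample_id = as.character(sample_id),
                          distances_bp = numeric(0),
                          molecule_ids = character(0)),
                     class = "distance_set")
  } else {
    out <- distance_set(sample_id, distances, mol_ids)
  }
  attr(out, "split_matches") <- unique(split_ids)
  out
}

resolve_marker <- function(ref_map, site_id, position, max_offset = 500) {
  if (!is.null(site_id)) {
    if (!site_id %in% ref_map$positions$site_id) {
      stop_ogmstr("consistency",
                  "marker site id %d not present in reference map '%s'",
                  site_id, ref_map$map_id)
    }
    return(site_id)
  }
  off <- abs(ref_map$positions$position_bp - position)
  i <- which.min(off)
  if (off[i] > max_offset) {
    stop_ogmstr("consistency",
                "no reference label within %d bp of position %s on map '%s'",
                max_offset, format(position, scientific = FALSE),
                ref_map$map_id)
  }
  ref_map$positions$site_id[i]
}

site_positions <- function(qmap, site_ids, molecule_id) {
  idx <- match(site_ids, qmap$positions$site_id)
  if (anyNA(idx)) {
    stop_ogmstr("consistency",
                "molecule '%s': aligned query site(s) %s missing from its label map",
                molecule_id,
                paste(site_ids[is.na(idx)], collapse = ", "))
  }
  qmap$positions$position_bp[idx]
}
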