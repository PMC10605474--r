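# Readers for the Bionano tab-separated optical-map formats.  Columns are
# located by header name (the '#h' line), never by position, so the parsers
# tolerate extra columns added by different tool versions.

read_bionano_table <- function(path, required) {
  if (!file.exists(path)) {
    stop_ogmstr("io", "file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  is_header <- startsWith(lines, "#")
  header_lines <- lines[is_header]
  body <- lines[!is_header & nzchar(trimws(lines))]

  hline <- header_lines[startsWith(header_lines, "#h")]
  if (length(hline) == 0L) {
    stop_ogmstr("format", "no '#h' column-header line in %s", path)
  }
  cols <- strsplit(trimws(sub("^#h[[:space:]]*", "", hline[1])),
                   "[[:space:]]+")[[1]]
  missing_cols <- setdiff(required, cols)
  if (length(missing_cols) > 0L) {
    stop_ogmstr("format", "%s: missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  if (length(body) == 0L) {
    stop_ogmstr("empty_input", "%s contains header lines only (no records)",
                path)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < length(cols))) {
    # fall back to whitespace splitting for hand-written fixtures
    fields <- strsplit(trimws(body), "[[:space:]]+")
  }
  mat <- do.call(rbind, lapply(fields, function(f) f[seq_along(cols)]))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

#' Read a Bionano CMAP label-map file
#'
#' A CMAP lists, for each map (reference contig or single molecule), the
#' positions of its fluorescent labels.  Rows with `LabelChannel == 0` are
#' end-of-map sentinels and are excluded from the label positions.
#'
#' @param path Path to a CMAP file ('#'-prefixed header lines, tab-separated
#'   body with at least CMapId, ContigLength, SiteID, Position).
#' @return A list of `label_map` objects, one per CMapId, each a list with
#'   `map_id`, `positions` (data.frame `site_id`, `position_bp`, ordered by
#'   site id) and `length_bp`.
#' @seealso [read_xmap()], [extract_intermarker_distances()]
#' @export
read_cmap <- function(path) {
  df <- read_bionano_table(path,
                           required = c("CMapId", "ContigLength", "SiteID",
                                        "Position"))
  df$CMapId <- as.character(df$CMapId)
  df$SiteID <- as.integer(df$SiteID)
  df$Position <- as.numeric(df$Position)
  df$ContigLength <- as.numeric(df$ContigLength)
  if (anyNA(df$SiteID) || anyNA(df$Position)) {
    stop_ogmstr("format", "%s: non-numeric SiteID or Position", path)
  }
  if ("LabelChannel" %in% names(df)) {
    df <- df[as.integer(df$LabelChannel) != 0L, , drop = FALSE]
  }
  maps <- lapply(split(df, factor(df$CMapId, levels = unique(df$CMapId))),
                 function(d) {
    d <- d[order(d$SiteID), , drop = FALSE]
    structure(
      list(map_id = d$CMapId[1],
           positions = data.frame(site_id = d$SiteID,
                                  position_bp = d$Position),
           length_bp = d$ContigLength[1]),
      class = "label_map"
    )
  })
  unname(maps)
}

#' Read a Bionano XMAP alignment file
#'
#' An XMAP records molecule-to-reference alignments; its `Alignment` column
#' is a concatenation of `"(refSiteID,qrySiteID)"` matched label pairs.
#'
#' @param path Path to an XMAP file with at least XmapEntryID, QryContigID,
#'   RefContigID, Orientation, Confidence and Alignment columns.
#' @return A list of `molecule_alignment` objects: lists with
#'   `molecule_id`, `ref_contig_id`, `orientation` (`"+"` or `"-"`),
#'   `confidence`, and `pairs` (two-column integer matrix
#'   `ref_site`/`qry_site`).
#' @export
read_xmap <- function(path) {
  df <- read_bionano_table(path,
                           required = c("XmapEntryID", "QryContigID",
                                        "RefContigID", "Orientation",
                                        "Confidence", "Alignment"))
  lapply(seq_len(nrow(df)), function(i) {
    pairs <- parse_alignment_string(df$Alignment[i], df$XmapEntryID[i])
    structure(
      list(molecule_id = as.character(df$QryContigID[i]),
           ref_contig_id = as.character(df$RefContigID[i]),
           orientation = df$Orientation[i],
           confidence = suppressWarnings(as.numeric(df$Confidence[i])),
           pairs = pairs),
      class = "molecule_alignment"
    )
  })
}

parse_alignment_string <- function(s, entry_id) {
  s <- trimws(s)
  # the whole string must be a sequence of "(int,int)" groups
  if (!grepl("^(\\([0-9]+,[0-9]+\\))+$", s)) {
    stop_ogmstr("parse",
                "XMAP entry %s: malformed Alignment string '%s'", entry_id, s)
  }
  toks <- regmatches(s, gregexpr("\\(([0-9]+),([0-9]+)\\)", s))[[1]]
  nums <- regmatches(toks, regexec("\\(([0-9]+),([0-9]+)\\)", toks))
  m <- t(vapply(nums, function(x) as.integer(x[2:3]), integer(2)))
  colnames(m) <- c("ref_site", "qry_site")
  m
}

# --- canonical distance table -------------------------------------------

#' Read or write the canonical per-molecule distance table
#'
#' The canonical exchange format of the package: a TSV with columns
#' `sample_id`, `molecule_id`, `distance_bp`, one row per molecule.
#' `write_distance_table()` serialises distances with three decimals, so a
#' write/read round trip reproduces values to 1e-3 bp.
#'
#' @param path Path of the TSV file.
#' @param sets A single [distance_set()] or a list of them.
#' @return `read_distance_table()` returns a list of [distance_set()]
#'   objects grouped by `sample_id` (in order of first appearance);
#'   `write_distance_table()` returns `path` invisibly.
#' @export
read_distance_table <- function(path) {
  if (!file.exists(path)) {
    stop_ogmstr("io", "file not found: %s", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "molecule_id", "distance_bp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_ogmstr("format", "%s: missing required column(s): %s",
                path, paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    stop_ogmstr("empty_input", "%s has a header but no rows", path)
  }
  d <- suppressWarnings(as.numeric(df$distance_bp))
  bad <- which(is.na(d) | d <= 0)
  if (length(bad) > 0L) {
    stop_ogmstr("validation",
                "%s line %d: invalid distance_bp '%s' (must be a positive number)",
                path, bad[1] + 1L, df$distance_bp[bad[1]])
  }
  ids <- factor(df$sample_id, levels = unique(df$sample_id))
  lapply(split(seq_len(nrow(df)), ids), function(idx) {
    distance_set(df$sample_id[idx[1]], d[idx], df$molecule_id[idx])
  })
}

#' @rdname read_distance_table
#' @export
write_distance_table <- function(sets, path) {
  if (inherits(sets, "distance_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    data.frame(sample_id = s$sample_id,
               molecule_id = as.character(s$molecule_ids),
               distance_bp = sprintf("%.3f", s$distances_bp),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
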