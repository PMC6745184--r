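# NPA motif location and composition of the full feature profile (NPA x2,
# ar/R filter, Froger's positions, SDP1-9) by anchored alignment.

#' Locate the two NPA motifs of an aquaporin
#'
#' Scans for N-P-X trimers (the canonical Asn-Pro-Ala motif and its
#' NPS/NPT/NPC/NPL/NPG variants). With a six-segment transmembrane layout
#' the loop-B candidate is the first N-P-X strictly between TM2 and TM3 and
#' the loop-E candidate the first N-P-X strictly between TM5 and TM6. When
#' the segmentation does not yield six segments, the positions projected
#' from an anchor reference are used instead.
#'
#' @param seq a [protein_sequence()].
#' @param tm_segments matrix from [predict_tm_segments()], or `NULL`.
#' @param anchor_positions optional named vector with projected `NPA_LB`
#'   and `NPA_LE` query positions (fallback).
#' @return A list with elements `lb` and `le`, each `list(motif, start)`,
#'   and `source` (`"scan"` or `"anchor"`).
#' @export
find_npa_motifs <- function(seq, tm_segments = NULL,
                            anchor_positions = NULL) {
  stopifnot(inherits(seq, "protein_sequence"))
  hits <- gregexpr("NP[A-Z]", seq$residues)[[1]]
  starts <- if (hits[1] == -1L) integer(0) else as.integer(hits)
  from_scan <- NULL
  if (!is.null(tm_segments) && nrow(tm_segments) == 6L) {
    in_loop <- function(lo, hi) {
      cand <- starts[starts > lo & (starts + 2L) < hi]
      if (length(cand)) cand[1] else NA_integer_
    }
    lb <- in_loop(tm_segments[2, "end"], tm_segments[3, "start"])
    le <- in_loop(tm_segments[5, "end"], tm_segments[6, "start"])
    if (!is.na(lb) && !is.na(le)) {
      from_scan <- list(
        lb = list(motif = substr(seq$residues, lb, lb + 2L), start = lb),
        le = list(motif = substr(seq$residues, le, le + 2L), start = le),
        source = "scan"
      )
    }
  }
  if (!is.null(from_scan)) return(from_scan)
  if (!is.null(anchor_positions) &&
      all(c("NPA_LB", "NPA_LE") %in% names(anchor_positions)) &&
      !anyNA(anchor_positions[c("NPA_LB", "NPA_LE")])) {
    lb <- as.integer(anchor_positions[["NPA_LB"]])
    le <- as.integer(anchor_positions[["NPA_LE"]])
    return(list(
      lb = list(motif = substr(seq$residues, lb, lb + 2L), start = lb),
      le = list(motif = substr(seq$residues, le, le + 2L), start = le),
      source = "anchor"
    ))
  }
  stop("find_npa_motifs: no N-P-X motif locatable in '", seq$id,
       "' and no anchor fallback available")
}

#' Extract the full feature profile of a query aquaporin
#'
#' Selects the best-scoring reference anchor, projects all 20 annotated
#' feature positions onto the query through the global alignment, and reads
#' the query residues at the projected positions. NPA motif strings are the
#' three residues starting at the projected NPA positions; when the
#' hydropathy segmentation yields exactly six transmembrane segments the
#' motifs are cross-checked against the de-novo N-P-X scan and a
#' discrepancy is reported as a warning (the projection wins). Features
#' projected into query gaps are reported as unresolved (`"-"`).
#'
#' @param query a [protein_sequence()].
#' @param refs non-empty list of [reference_anchor()] objects.
#' @param config [aqp_config()].
#' @return An object of class `feature_profile` with `query_id`,
#'   `anchor_ref_id`, `npa_lb`/`npa_le` (`list(motif, start)`), `arr`
#'   (named H2/H5/LE1/LE2), `froger` (P1..P5), `sdp` (SDP1..SDP9),
#'   `positions` (all 20 projected positions), `unresolved` (feature names
#'   that mapped to gaps) and `tm_count`.
#' @export
extract_feature_profile <- function(query, refs, config = aqp_config()) {
  sel <- select_best_reference(query, refs, config)
  proj <- project_positions(sel$alignment, sel$anchor$feature_positions)
  n <- seq_length(query)

  read_res <- function(pos) {
    if (is.na(pos) || pos < 1L || pos > n) "-" else residue_at(query, pos)
  }
  read_motif <- function(pos) {
    if (is.na(pos) || pos + 2L > n) return("-")
    substr(query$residues, pos, pos + 2L)
  }

  unresolved <- names(proj)[is.na(proj)]
  npa_lb <- list(motif = read_motif(proj[["NPA_LB"]]),
                 start = proj[["NPA_LB"]])
  npa_le <- list(motif = read_motif(proj[["NPA_LE"]]),
                 start = proj[["NPA_LE"]])

  tm <- predict_tm_segments(query, window = config$kd_window,
                            threshold = config$kd_threshold,
                            merge_gap = config$kd_merge_gap,
                            min_len = config$tm_min_len,
                            max_len = config$tm_max_len)
  if (nrow(tm) == 6L) {
    scan <- tryCatch(find_npa_motifs(query, tm), error = function(e) NULL)
    if (!is.null(scan) && scan$source == "scan") {
      if (!identical(scan$lb$start, npa_lb$start) ||
          !identical(scan$le$start, npa_le$start)) {
        warning("extract_feature_profile: N-P-X scan and anchor projection ",
                "disagree for '", query$id, "' (scan LB ", scan$lb$start,
                "/LE ", scan$le$start, ", projection LB ", npa_lb$start,
                "/LE ", npa_le$start, "); using the projection")
      }
    }
  }

  arr <- vapply(proj[c("H2", "H5", "LE1", "LE2")], read_res, "")
  froger <- vapply(proj[paste0("P", 1:5)], read_res, "")
  sdp <- vapply(proj[paste0("SDP", 1:9)], read_res, "")

  structure(
    list(query_id = query$id,
         anchor_ref_id = sel$anchor$sequence$id,
         anchor_subfamily = sel$anchor$subfamily,
         npa_lb = npa_lb, npa_le = npa_le,
         arr = arr, froger = froger, sdp = sdp,
         positions = proj, unresolved = unresolved,
         tm_count = nrow(tm)),
    class = "feature_profile"
  )
}

#' @export
print.feature_profile <- function(x, ...) {
  cat("<feature_profile> ", x$query_id, " (anchor ", x$anchor_ref_id, ")\n",
      "  NPA: ", x$npa_lb$motif, "@", x$npa_lb$start, " / ",
      x$npa_le$motif, "@", x$npa_le$start, "\n",
      "  ar/R: ", paste(x$arr, collapse = "-"),
      "  Froger: ", paste(x$froger, collapse = "-"), "\n",
      "  SDP: ", paste(x$sdp, collapse = " "), "\n", sep = "")
  if (length(x$unresolved)) {
    cat("  unresolved:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}
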