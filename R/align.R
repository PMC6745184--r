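# Anchored pairwise alignment. The optimal global (Needleman-Wunsch, affine
# gap) alignment is computed by Biostrings::pairwiseAlignment; this module
# wraps it in a plain container and provides position projection through
# alignment columns — the core of the anchor-based feature extraction.

load_substitution_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = env)) {
    stop("load_substitution_matrix: unknown matrix '", name, "'")
  }
  get(name, envir = env)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman--Wunsch global alignment under a substitution matrix with
#' affine gap penalties (a gap of length L costs
#' `gap_open + gap_extend * L`); end gaps are penalized. The traceback is
#' deterministic.
#'
#' @param query,ref [protein_sequence()] objects.
#' @param config [aqp_config()] list supplying `substitution_matrix`,
#'   `gap_open` and `gap_extend`.
#' @return An object of class `aqp_alignment` with `query_id`, `ref_id`,
#'   `aligned_query`, `aligned_ref` (equal-length gapped strings), `score`
#'   and `identity` (fraction of identical residues over columns where
#'   neither sequence has a gap).
#' @export
#' @examples
#' a <- global_align(protein_sequence("q", "NPA"),
#'                   protein_sequence("r", "NPG"))
#' a$identity  # 2/3
global_align <- function(query, ref, config = aqp_config()) {
  stopifnot(inherits(query, "protein_sequence"),
            inherits(ref, "protein_sequence"))
  mat <- load_substitution_matrix(config$substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query$residues),
    Biostrings::AAString(ref$residues),
    substitutionMatrix = mat,
    gapOpening = config$gap_open,
    gapExtension = config$gap_extend,
    type = "global"
  )
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aq, "", fixed = TRUE)[[1]]
  rc <- strsplit(ar, "", fixed = TRUE)[[1]]
  both <- qc != "-" & rc != "-"
  ident <- if (any(both)) mean(qc[both] == rc[both]) else 0
  structure(
    list(query_id = query$id, ref_id = ref$id,
         aligned_query = aq, aligned_ref = ar,
         score = Biostrings::score(pa), identity = ident),
    class = "aqp_alignment"
  )
}

#' @export
print.aqp_alignment <- function(x, ...) {
  cat("<alignment> ", x$query_id, " vs ", x$ref_id,
      "  score=", format(x$score), "  identity=",
      sprintf("%.3f", x$identity), "\n", sep = "")
  invisible(x)
}

#' Select the best-scoring reference anchor for a query
#'
#' Aligns the query against every reference and returns the one with the
#' maximal alignment score; ties are broken by input order.
#'
#' @param query a [protein_sequence()].
#' @param refs non-empty list of [reference_anchor()] objects.
#' @param config [aqp_config()].
#' @return A list with `anchor` (the winning [reference_anchor()]) and
#'   `alignment` (its [global_align()] result).
#' @export
select_best_reference <- function(query, refs, config = aqp_config()) {
  if (!length(refs)) stop("select_best_reference: refs must be non-empty")
  alns <- lapply(refs, function(r) global_align(query, r$sequence, config))
  scores <- vapply(alns, `[[`, 0, "score")
  best <- which.max(scores)  # first maximum: tie broken by input order
  list(anchor = refs[[best]], alignment = alns[[best]])
}

#' Project reference positions onto a query through an alignment
#'
#' Each 1-based reference position is carried through its alignment column
#' to the query residue aligned in that column. A reference position that
#' falls in a query gap (a deletion in the query) is unresolved (`NA`).
#'
#' @param aln an [global_align()] result.
#' @param ref_positions named integer vector of 1-based reference positions.
#' @return Named integer vector of query positions; `NA` where unresolved.
#' @export
project_positions <- function(aln, ref_positions) {
  stopifnot(inherits(aln, "aqp_alignment"))
  qc <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  rc <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1]]
  ref_len <- sum(rc != "-")
  if (any(ref_positions < 1L) || any(ref_positions > ref_len)) {
    stop("project_positions: position outside reference (length ",
         ref_len, ")")
  }
  ref_cum <- cumsum(rc != "-")
  qry_cum <- cumsum(qc != "-")
  out <- vapply(as.integer(ref_positions), function(p) {
    col <- match(p, ref_cum)  # first column where ref coordinate reaches p
    if (qc[col] == "-") NA_integer_ else qry_cum[col]
  }, 1L)
  names(out) <- names(ref_positions)
  out
}
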