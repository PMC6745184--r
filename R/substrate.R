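# Rule engine over the published per-substrate SDP allowed-residue sets:
# an SDP string with no mismatch against a substrate pattern marks a
# transporter of that substrate; exactly one mismatch marks a novel-site
# transporter; two or more exclude it.

#' Built-in substrate SDP patterns
#'
#' The six per-substrate patterns (ammonia, boric acid, CO2, H2O2, silicic
#' acid, urea), each an ordered list of nine allowed-residue sets, shipped
#' as a TSV data file with slash-delimited sets.
#'
#' @param path optional path to an alternative pattern file.
#' @return Named list of `substrate_pattern` objects (fields `substrate`
#'   and `allowed`, a list of 9 character vectors).
#' @export
#' @examples
#' builtin_patterns()$ammonia$allowed[[5]]  # "A"
builtin_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sdp_patterns.tsv",
                        package = "aqprofiler")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("builtin_patterns: pattern data file missing")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  cols <- paste0("SDP", 1:9)
  if (!all(c("substrate", cols) %in% names(df))) {
    stop("builtin_patterns: corrupt pattern file (columns missing)")
  }
  pats <- lapply(seq_len(nrow(df)), function(i) {
    allowed <- lapply(df[i, cols], function(x) {
      set <- strsplit(as.character(x), "/", fixed = TRUE)[[1]]
      if (!length(set) || any(!nzchar(set))) {
        stop("builtin_patterns: empty allowed set for ",
             df$substrate[i])
      }
      set
    })
    names(allowed) <- cols
    structure(list(substrate = df$substrate[i], allowed = allowed),
              class = "substrate_pattern")
  })
  names(pats) <- df$substrate
  pats
}

#' Match an SDP residue string against a substrate pattern
#'
#' Position `i` mismatches iff the residue is not in the pattern's allowed
#' set for SDP`i`. No mismatch gives status `member`; up to `max_novel`
#' mismatches give `member_novel`, with the mismatching (position, residue)
#' pairs reported as novel sites; more give `non_member`. Unresolved
#' positions (the `"-"` sentinel) are scored as mismatches and reported
#' distinctly via `unresolved_positions` (with a warning).
#'
#' @param sdp character vector of 9 residues (SDP1..SDP9); `"-"` marks an
#'   unresolved position.
#' @param pattern a `substrate_pattern` from [builtin_patterns()].
#' @param max_novel maximum mismatch count still called a (novel) member.
#' @return An object of class `substrate_call` with `substrate`, `status`,
#'   `mismatch_positions`, `novel_residues` (data.frame of position and
#'   residue) and `unresolved_positions`.
#' @export
match_sdp <- function(sdp, pattern, max_novel = 1) {
  stopifnot(inherits(pattern, "substrate_pattern"))
  sdp <- as.character(unlist(sdp, use.names = FALSE))
  if (length(sdp) != 9L) {
    stop("match_sdp: SDP tuple must have exactly 9 residues (got ",
         length(sdp), ")")
  }
  unresolved <- which(sdp == "-")
  if (length(unresolved)) {
    warning("match_sdp: unresolved SDP position(s) ",
            paste(unresolved, collapse = ", "),
            " scored as mismatches")
  }
  mismatch <- which(!mapply(function(res, set) res %in% set,
                            sdp, pattern$allowed))
  nm <- length(mismatch)
  status <- if (nm == 0L) "member"
            else if (nm <= max_novel) "member_novel"
            else "non_member"
  novel <- if (status == "member_novel") {
    data.frame(sdp = mismatch, residue = sdp[mismatch],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sdp = integer(0), residue = character(0),
               stringsAsFactors = FALSE)
  }
  structure(
    list(substrate = pattern$substrate, status = status,
         mismatch_positions = unname(mismatch),
         novel_residues = novel,
         unresolved_positions = unname(unresolved)),
    class = "substrate_call"
  )
}

#' Substrate-specificity report for a set of feature profiles
#'
#' Runs [match_sdp()] for every profile against all six built-in patterns
#' and returns one row per (protein, substrate).
#'
#' @param profiles list of [extract_feature_profile()] results, or any list
#'   of objects with `query_id` and a 9-residue `sdp` field.
#' @param patterns patterns from [builtin_patterns()].
#' @param max_novel see [match_sdp()].
#' @return A data.frame with columns `query_id`, `substrate`, `status`,
#'   `n_mismatch`, `novel_sdp` and `novel_residue` (NA unless exactly one
#'   novel site).
#' @export
substrate_report <- function(profiles, patterns = builtin_patterns(),
                             max_novel = 1) {
  if (!length(profiles)) {
    return(data.frame(query_id = character(0), substrate = character(0),
                      status = character(0), n_mismatch = integer(0),
                      novel_sdp = integer(0), novel_residue = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(profiles, function(p) {
    calls <- lapply(patterns, function(pat) {
      match_sdp(p$sdp, pat, max_novel = max_novel)
    })
    do.call(rbind, lapply(calls, function(cl) {
      data.frame(
        query_id = p$query_id, substrate = cl$substrate,
        status = cl$status, n_mismatch = length(cl$mismatch_positions),
        novel_sdp = if (nrow(cl$novel_residues) == 1L)
          cl$novel_residues$sdp else NA_integer_,
        novel_residue = if (nrow(cl$novel_residues) == 1L)
          cl$novel_residues$residue else NA_character_,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published SDP residue assignments for the E. salsugineum aquaporins
#'
#' The per-protein SDP residue strings reported for the 35 EsAQPs, grouped
#' by substrate block, together with the positions flagged as novel sites.
#' Used as an in-package fixture for the rule engine.
#'
#' @return A data.frame with columns `name`, `substrate`, `SDP1..SDP9`,
#'   `novel_sdp` and `novel_residue`.
#' @export
esaqp_sdp_table <- function() {
  path <- system.file("extdata", "esaqp_sdp_observed.tsv",
                      package = "aqprofiler")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Published structural characteristics of the E. salsugineum aquaporins
#'
#' Length, transmembrane-domain count, molecular weight, isoelectric point,
#' NPA motifs, ar/R selectivity filter and Froger's positions of the 35
#' EsAQPs, one row per protein.
#'
#' @return A data.frame, one row per EsAQP.
#' @export
esaqp_structural_table <- function() {
  path <- system.file("extdata", "esaqp_structural.tsv",
                      package = "aqprofiler")
  read.delim(path, stringsAsFactors = FALSE)
}
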