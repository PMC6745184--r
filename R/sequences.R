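# Sequence containers and format IO. FASTA parsing/writing is delegated to
# Biostrings; the reference-anchor table is this package's own TSV format.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N",
                 "P","Q","R","S","T","V","W","Y")

#' Names of the 20 anchored feature positions
#'
#' The features projected from a reference anchor onto a query: the two NPA
#' motif starts (loops B and E), the four ar/R selectivity-filter residues
#' (TM2, TM5 and two loop-E positions), the five Froger's positions and the
#' nine specificity-determining positions.
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c("NPA_LB", "NPA_LE", "H2", "H5", "LE1", "LE2",
    paste0("P", 1:5), paste0("SDP", 1:9))
}

#' Construct a protein sequence record
#'
#' @param id sequence identifier (non-empty).
#' @param residues amino-acid string over the 20-letter alphabet; `X` is
#'   accepted and flagged in `has_x`.
#' @param description free-text description.
#'
#' @return An object of class `protein_sequence` with fields `id`,
#'   `description`, `residues` (uppercased) and `has_x`.
#' @export
#' @examples
#' p <- protein_sequence("q1", "npavr")
#' p$residues
protein_sequence <- function(id, residues, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("protein_sequence: residues must be non-empty for '", id, "'")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X"))
  if (length(bad)) {
    stop("protein_sequence: illegal residue character(s) ",
         paste(bad, collapse = ", "), " in record '", id, "'")
  }
  structure(
    list(id = id, description = description, residues = residues,
         has_x = any(chars == "X")),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, "  (", nchar(x$residues), " aa",
      if (x$has_x) ", contains X", ")\n", sep = "")
  invisible(x)
}

seq_length <- function(seq) nchar(seq$residues)

seq_chars <- function(seq) strsplit(seq$residues, "", fixed = TRUE)[[1]]

residue_at <- function(seq, pos) substr(seq$residues, pos, pos)

#' Read protein sequences from a FASTA file
#'
#' The first whitespace in a header splits the id from the description;
#' wrapped and unwrapped sequence lines are both accepted. Residues are
#' uppercased.
#'
#' @param path path to a FASTA file.
#' @return A list of [protein_sequence()] records, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("read_fasta: not a readable FASTA file: ",
                             path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("read_fasta: no records in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- protein_sequence(ids[i], as.character(set[[i]]), desc[i])
  }
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs list of [protein_sequence()] records.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(set) <- vapply(seqs, function(s) {
    if (nzchar(s$description)) paste(s$id, s$description) else s$id
  }, "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a reference anchor
#'
#' A function-known aquaporin whose annotated feature positions (NPA motif
#' starts, ar/R filter, Froger's positions, SDPs) are projected onto query
#' sequences by alignment.
#'
#' @param sequence a [protein_sequence()].
#' @param subfamily one of `"PIP"`, `"TIP"`, `"NIP"`, `"SIP"`.
#' @param class_label class within the subfamily, e.g. `"PIP2"`.
#' @param feature_positions named integer vector with one 1-based position
#'   per [feature_names()] entry; NPA positions point at the motif's first
#'   residue.
#'
#' @return An object of class `reference_anchor`.
#' @export
reference_anchor <- function(sequence, subfamily, class_label,
                             feature_positions) {
  stopifnot(inherits(sequence, "protein_sequence"))
  subfamily <- match.arg(subfamily, c("PIP", "TIP", "NIP", "SIP"))
  want <- feature_names()
  missing_keys <- setdiff(want, names(feature_positions))
  if (length(missing_keys)) {
    stop("reference_anchor '", sequence$id, "': missing feature position(s) ",
         paste(missing_keys, collapse = ", "))
  }
  fp <- as.integer(feature_positions[want])
  names(fp) <- want
  n <- seq_length(sequence)
  if (any(fp < 1L) || any(fp > n)) {
    stop("reference_anchor '", sequence$id,
         "': feature position outside sequence (length ", n, "): ",
         paste(want[fp < 1L | fp > n], collapse = ", "))
  }
  if (fp[["NPA_LB"]] >= fp[["NPA_LE"]]) {
    stop("reference_anchor '", sequence$id,
         "': NPA_LB must precede NPA_LE")
  }
  structure(
    list(sequence = sequence, subfamily = subfamily,
         class_label = class_label, feature_positions = fp),
    class = "reference_anchor"
  )
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("<reference_anchor> ", x$sequence$id, "  [", x$subfamily, "/",
      x$class_label, "]  ", seq_length(x$sequence), " aa\n", sep = "")
  invisible(x)
}

anchor_table_columns <- function() {
  c("id", "subfamily", "class", feature_names(), "sequence")
}

#' Read a reference-anchor table
#'
#' Tab-separated text with header columns
#' `id subfamily class NPA_LB NPA_LE H2 H5 LE1 LE2 P1..P5 SDP1..SDP9
#' sequence`; one row per function-known reference. All positions are
#' validated against the sequence and, for classification use, at least one
#' reference per subfamily is expected (warned about otherwise).
#'
#' @param path path to the TSV file.
#' @return A list of [reference_anchor()] objects.
#' @export
read_anchor_table <- function(path) {
  if (!file.exists(path)) stop("read_anchor_table: file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(anchor_table_columns(), names(df))
  if (length(missing_cols)) {
    stop("read_anchor_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  anchors <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    fp <- as.integer(row[feature_names()])
    names(fp) <- feature_names()
    reference_anchor(
      protein_sequence(row[["id"]], row[["sequence"]]),
      subfamily = row[["subfamily"]],
      class_label = row[["class"]],
      feature_positions = fp
    )
  })
  present <- unique(vapply(anchors, `[[`, "", "subfamily"))
  absent <- setdiff(c("PIP", "TIP", "NIP", "SIP"), present)
  if (length(absent)) {
    warning("read_anchor_table: no reference for subfamily(ies) ",
            paste(absent, collapse = ", "),
            "; classification of those subfamilies will be impossible")
  }
  anchors
}

#' Write a reference-anchor table
#'
#' Inverse of [read_anchor_table()].
#'
#' @param anchors list of [reference_anchor()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(anchors, path) {
  rows <- lapply(anchors, function(a) {
    data.frame(id = a$sequence$id, subfamily = a$subfamily,
               class = a$class_label,
               as.list(a$feature_positions),
               sequence = a$sequence$residues,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
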