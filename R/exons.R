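# Gene models and exon-structure validation. Exon counts per subfamily act
# as an independent check on the sequence-based classification (PIP genes
# carry four exons, SIP three, TIP mostly three or fewer).

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param exons two-column matrix or data.frame of 1-based inclusive
#'   `(start, end)` genomic intervals.
#' @param strand `"+"` or `"-"`.
#'
#' @return An object of class `gene_model`; exons are stored non-overlapping
#'   and ordered 5' to 3' (i.e. by ascending coordinate on `+`, descending
#'   on `-`).
#' @export
#' @examples
#' gm <- gene_model("g1", cbind(c(1, 200), c(100, 300)), "+")
#' exon_count(gm)
gene_model <- function(gene_id, exons, strand = c("+", "-")) {
  strand <- match.arg(strand)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  if (ncol(exons) != 2L || nrow(exons) < 1L) {
    stop("gene_model: exons must be an n x 2 matrix of (start, end)")
  }
  if (any(exons[, 1] > exons[, 2])) {
    stop("gene_model '", gene_id, "': exon start > end")
  }
  ord <- order(exons[, 1])
  exons <- exons[ord, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] <= exons[-nrow(exons), 2])) {
    stop("gene_model '", gene_id, "': overlapping exons")
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  colnames(exons) <- c("start", "end")
  structure(list(gene_id = gene_id, exons = exons, strand = strand),
            class = "gene_model")
}

#' Number of exons in a gene model
#'
#' @param model a [gene_model()].
#' @return Integer exon count.
#' @export
exon_count <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  nrow(model$exons)
}

#' Read gene models from an exon table
#'
#' Accepts either a GFF3 file (features of type `exon`, grouped by
#' `Parent`/`gene_id`; parsed via \pkg{rtracklayer}) or a 4-column TSV with
#' header `gene_id start end strand`.
#'
#' @param path input file.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return A list of [gene_model()] objects.
#' @export
read_exon_table <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_exon_table: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("read_exon_table: GFF3 input requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L) stop("read_exon_table: no exon features in ", path)
    meta <- as.data.frame(gr)
    key <- if (!is.null(meta$Parent) && any(lengths(gr$Parent) > 0)) {
      vapply(gr$Parent, function(p) as.character(p)[1], "")
    } else if (!is.null(meta$gene_id)) {
      as.character(meta$gene_id)
    } else {
      as.character(meta$ID)
    }
    df <- data.frame(gene_id = key, start = meta$start, end = meta$end,
                     strand = as.character(meta$strand),
                     stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "start", "end", "strand")
    if (!all(need %in% names(df))) {
      stop("read_exon_table: TSV must have columns ",
           paste(need, collapse = ", "))
    }
  }
  lapply(split(df, df$gene_id), function(g) {
    gene_model(g$gene_id[1], cbind(g$start, g$end),
               strand = if (g$strand[1] == "-") "-" else "+")
  })
}

#' Validate exon-count conservation within subfamilies
#'
#' Exon counts are strongly conserved inside aquaporin subfamilies; a member
#' deviating from its subfamily's modal count is flagged as a candidate
#' annotation (or classification) problem. Genes without a subfamily
#' assignment are skipped with a warning.
#'
#' @param models list of [gene_model()] objects.
#' @param subfamily_assignments named character vector mapping `gene_id` to
#'   subfamily.
#' @return A list with `distribution` (per-subfamily table of exon counts),
#'   `flags` (data.frame of deviating genes) and `skipped` (unassigned ids).
#' @export
validate_exon_pattern <- function(models, subfamily_assignments) {
  ids <- vapply(models, `[[`, "", "gene_id")
  counts <- vapply(models, exon_count, 1L)
  assigned <- ids %in% names(subfamily_assignments)
  if (any(!assigned)) {
    warning("validate_exon_pattern: skipping unassigned gene(s): ",
            paste(ids[!assigned], collapse = ", "))
  }
  df <- data.frame(gene_id = ids[assigned],
                   subfamily = unname(subfamily_assignments[ids[assigned]]),
                   exons = counts[assigned], stringsAsFactors = FALSE)
  distribution <- lapply(split(df$exons, df$subfamily), table)
  flags <- do.call(rbind, lapply(split(df, df$subfamily), function(g) {
    tab <- table(g$exons)
    modal <- as.integer(names(tab)[which.max(tab)])
    g[g$exons != modal, , drop = FALSE]
  }))
  rownames(flags) <- NULL
  list(distribution = distribution,
       flags = if (is.null(flags)) df[0, ] else flags,
       skipped = ids[!assigned])
}
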