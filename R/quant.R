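# qRT-PCR relative quantification. Ct tables are long-format data frames
# (gene, sample, replicate, ct). Organ-level abundance uses the delta-Ct
# statistic oriented so larger values mean more transcript; stress fold
# changes use 2^-ddCt against a control sample.

validate_ct_table <- function(table, reference) {
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(table))) {
    stop("ct table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0)) {
    stop("ct table: all Ct values must be finite and > 0")
  }
  samples <- unique(table$sample)
  has_ref <- vapply(samples, function(s) {
    any(table$gene == reference & table$sample == s)
  }, TRUE)
  if (any(!has_ref)) {
    stop("ct table: reference gene '", reference,
         "' missing in sample(s): ",
         paste(samples[!has_ref], collapse = ", "))
  }
  invisible(table)
}

#' Read a Ct table from CSV
#'
#' Expected columns: `gene, sample, replicate, ct`.
#'
#' @param path CSV path.
#' @param reference reference (housekeeping) gene that must be present in
#'   every sample.
#' @return The validated data.frame.
#' @export
read_ct_table <- function(path, reference = "actin") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(df, reference)
  df
}

mean_ct <- function(table, gene, sample) {
  ct <- table$ct[table$gene == gene & table$sample == sample]
  if (!length(ct)) return(NA_real_)
  mean(ct)
}

#' Relative expression by the delta-Ct method
#'
#' `dCt = mean Ct(reference) - mean Ct(gene)`; the returned value is
#' `2^dCt`, so more abundant transcripts (lower Ct) give larger values.
#'
#' @param table Ct table (see [read_ct_table()]).
#' @param gene gene of interest.
#' @param sample sample/organ name.
#' @param reference reference gene.
#' @return Relative expression (fold of the reference gene).
#' @export
relative_expression_dct <- function(table, gene, sample,
                                    reference = "actin") {
  validate_ct_table(table, reference)
  g <- mean_ct(table, gene, sample)
  r <- mean_ct(table, reference, sample)
  if (is.na(g)) stop("relative_expression_dct: gene '", gene,
                     "' missing in sample '", sample, "'")
  2^(r - g)
}

#' Fold change by the 2^-ddCt method
#'
#' `dCt = Ct(gene) - Ct(reference)` within each sample;
#' `ddCt = dCt(treated) - dCt(control)`; the fold change is `2^-ddCt`.
#'
#' @inheritParams relative_expression_dct
#' @param treated_sample,control_sample sample names.
#' @return Fold change of the gene in treated vs control.
#' @export
fold_change_ddct <- function(table, gene, treated_sample, control_sample,
                             reference = "actin") {
  validate_ct_table(table, reference)
  for (s in c(treated_sample, control_sample)) {
    if (!any(table$sample == s)) {
      stop("fold_change_ddct: sample '", s, "' missing")
    }
    if (is.na(mean_ct(table, gene, s))) {
      stop("fold_change_ddct: gene '", gene, "' missing in sample '",
           s, "'")
    }
  }
  dct_t <- mean_ct(table, gene, treated_sample) -
    mean_ct(table, reference, treated_sample)
  dct_c <- mean_ct(table, gene, control_sample) -
    mean_ct(table, reference, control_sample)
  2^-(dct_t - dct_c)
}

#' Expression matrix across genes and samples
#'
#' Builds a genes-by-samples matrix of the chosen statistic (`dct`:
#' `2^dCt` relative abundance; `ddct`: `2^-ddCt` fold change against
#' `control_sample`), optionally log2-transformed for heatmap export.
#' Missing (gene, sample) cells are `NA`, never imputed.
#'
#' @inheritParams relative_expression_dct
#' @param mode `"dct"` or `"ddct"`.
#' @param control_sample required for `mode = "ddct"`; that column is
#'   dropped from the output.
#' @param log2 apply `log2` to the result.
#' @return Numeric matrix (genes x samples).
#' @export
expression_matrix <- function(table, mode = c("dct", "ddct"),
                              reference = "actin", control_sample = NULL,
                              log2 = FALSE) {
  mode <- match.arg(mode)
  validate_ct_table(table, reference)
  genes <- setdiff(unique(table$gene), reference)
  samples <- unique(table$sample)
  if (mode == "ddct") {
    if (is.null(control_sample) || !control_sample %in% samples) {
      stop("expression_matrix: ddct mode needs a control_sample present ",
           "in the table")
    }
    samples <- setdiff(samples, control_sample)
  }
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (g in genes) {
    for (s in samples) {
      if (!any(table$gene == g & table$sample == s)) next
      m[g, s] <- if (mode == "dct") {
        relative_expression_dct(table, g, s, reference)
      } else {
        fold_change_ddct(table, g, s, control_sample, reference)
      }
    }
  }
  if (log2) base::log2(m) else m
}
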