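# Pipeline commands: one function per report the package produces. Each
# reads standard input formats, runs the corresponding modules, writes a
# TSV (results only go to files; messages go to the condition system) and
# returns the table invisibly. A thin Rscript wrapper around these lives
# in inst/scripts/aqp-profiler.

#' Annotate queries: structural characteristics report
#'
#' One row per query with length, predicted transmembrane-segment count,
#' molecular weight, isoelectric point, the two NPA motifs, the ar/R
#' selectivity filter and Froger's positions — the standard structural
#' characterization table for an aquaporin family.
#'
#' @param fasta path to the query FASTA.
#' @param anchors path to a reference-anchor TSV (see
#'   [read_anchor_table()]) or a list of [reference_anchor()] objects.
#' @param out output TSV path, or `NULL` to skip writing.
#' @param config [aqp_config()].
#' @return The report data.frame, invisibly.
#' @export
cmd_annotate <- function(fasta, anchors, out = NULL,
                         config = aqp_config()) {
  queries <- read_fasta(fasta)
  refs <- if (is.character(anchors)) read_anchor_table(anchors) else anchors
  rows <- lapply(queries, function(q) {
    phys <- physchem_profile(q, config)
    prof <- extract_feature_profile(q, refs, config)
    if (length(prof$unresolved)) {
      warning("cmd_annotate: unresolved feature(s) for '", q$id, "': ",
              paste(prof$unresolved, collapse = ", "))
    }
    data.frame(
      id = q$id, aa = phys$length_aa, tm = phys$tm_count,
      mw_kda = round(phys$mw_kda, 2), pi = round(phys$pi, 2),
      npa_lb = prof$npa_lb$motif, npa_le = prof$npa_le$motif,
      h2 = prof$arr[["H2"]], h5 = prof$arr[["H5"]],
      le1 = prof$arr[["LE1"]], le2 = prof$arr[["LE2"]],
      p1 = prof$froger[["P1"]], p2 = prof$froger[["P2"]],
      p3 = prof$froger[["P3"]], p4 = prof$froger[["P4"]],
      p5 = prof$froger[["P5"]],
      anchor = prof$anchor_ref_id,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Classify queries into subfamilies and propose names
#'
#' Computes the identity-distance matrix over queries plus references,
#' assigns each query the subfamily/class of its nearest reference, writes
#' the neighbor-joining tree (Newick) and the calls table.
#'
#' @inheritParams cmd_annotate
#' @param tree_out optional Newick output path.
#' @return Data.frame of calls (`id, subfamily, class, proposed_name,
#'   nearest_reference, support`), invisibly.
#' @export
cmd_classify <- function(fasta, anchors, out = NULL, tree_out = NULL,
                         config = aqp_config()) {
  queries <- read_fasta(fasta)
  refs <- if (is.character(anchors)) read_anchor_table(anchors) else anchors
  seqs <- c(queries, lapply(refs, `[[`, "sequence"))
  d <- pairwise_distance_matrix(seqs, config)
  used <- character()
  rows <- lapply(queries, function(q) {
    call <- assign_subfamily(q$id, refs, d)
    name <- propose_name(call, used, prefix = config$species_prefix)
    used <<- c(used, name)
    data.frame(id = q$id, subfamily = call$subfamily,
               class = call$class_label, proposed_name = name,
               nearest_reference = call$nearest_reference_id,
               support = round(call$support, 4),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (!is.null(tree_out) && nrow(d) >= 3L) {
    ape::write.tree(nj_tree(d), file = tree_out)
  }
  if (!is.null(out)) {
    write.table(calls, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(calls)
}

#' Substrate-specificity report
#'
#' Extracts feature profiles and runs the SDP rule engine for all six
#' substrate classes.
#'
#' @inheritParams cmd_annotate
#' @return The [substrate_report()] data.frame, invisibly.
#' @export
cmd_substrate <- function(fasta, anchors, out = NULL,
                          config = aqp_config()) {
  queries <- read_fasta(fasta)
  refs <- if (is.character(anchors)) read_anchor_table(anchors) else anchors
  profiles <- lapply(queries, extract_feature_profile, refs = refs,
                     config = config)
  report <- substrate_report(profiles, max_novel = config$max_novel)
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}

#' Expression matrix from a Ct table
#'
#' @param ct_csv path to a Ct CSV (`gene, sample, replicate, ct`).
#' @param mode `"dct"` or `"ddct"`.
#' @param reference reference gene.
#' @param control_sample control sample (ddct mode).
#' @param log2 log2-transform the matrix.
#' @param out output TSV path, or `NULL`.
#' @return The matrix, invisibly.
#' @export
cmd_expression <- function(ct_csv, mode = c("dct", "ddct"),
                           reference = "actin", control_sample = NULL,
                           log2 = FALSE, out = NULL) {
  mode <- match.arg(mode)
  tab <- read_ct_table(ct_csv, reference)
  m <- expression_matrix(tab, mode, reference, control_sample, log2)
  if (!is.null(out)) {
    write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(m)
}

#' Pf estimation and group comparison from swelling data
#'
#' @param swelling_csv path to a swelling CSV (see [read_swelling_csv()]).
#' @param out per-oocyte Pf TSV path, or `NULL`.
#' @param groups_out group-summary TSV path, or `NULL`.
#' @param config [aqp_config()].
#' @return List with `pf` (per-oocyte data.frame) and `comparison` (from
#'   [pf_group_comparison()], `NULL` with fewer than 2 groups), invisibly.
#' @export
cmd_pf <- function(swelling_csv, out = NULL, groups_out = NULL,
                   config = aqp_config()) {
  series <- read_swelling_csv(swelling_csv)
  results <- lapply(series, compute_pf,
                    window_minutes = config$pf_window_minutes,
                    vw = config$water_molar_volume)
  pf_df <- do.call(rbind, lapply(results, function(r) {
    data.frame(oocyte_id = r$oocyte_id, group = r$group, pf = r$pf,
               slope = r$slope, v0 = r$v0, s0 = r$s0,
               stringsAsFactors = FALSE)
  }))
  rownames(pf_df) <- NULL
  comparison <- if (length(unique(pf_df$group)) >= 2L &&
                    all(table(pf_df$group) >= 2L)) {
    pf_group_comparison(results)
  } else NULL
  if (!is.null(out)) {
    write.table(pf_df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(groups_out) && !is.null(comparison)) {
    write.table(comparison$groups, groups_out, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(pf = pf_df, comparison = comparison))
}

#' Emit a complete synthetic data set
#'
#' Writes a synthetic reference-anchor table, a query FASTA with a JSON
#' truth sidecar, a replicated Ct table and a set of swelling series into
#' a directory — inputs for exercising every other command without real
#' data.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed; the whole set is deterministic per seed.
#' @param n_queries queries per subfamily.
#' @param flank_mutation_rate see [make_query()].
#' @return Named list of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1, n_queries = 3,
                         flank_mutation_rate = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_reference_panel(seed = seed)
  paths <- list(
    anchors = file.path(out_dir, "anchors_synthetic.tsv"),
    fasta = file.path(out_dir, "queries_synthetic.fasta"),
    truth = file.path(out_dir, "queries_truth.json"),
    ct = file.path(out_dir, "ct_synthetic.csv"),
    swelling = file.path(out_dir, "swelling_synthetic.csv")
  )
  write_anchor_table(panel, paths$anchors)
  queries <- list(); truths <- list()
  k <- 0L
  for (sub in c("PIP", "TIP", "NIP", "SIP")) {
    for (i in seq_len(n_queries)) {
      k <- k + 1L
      q <- make_query(panel, sub, flank_mutation_rate = flank_mutation_rate,
                      seed = seed + k, id = sprintf("%s_q%d", sub, i))
      queries[[k]] <- q$sequence
      truths[[q$sequence$id]] <- q$truth
    }
  }
  write_fasta(queries, paths$fasta)
  jsonlite::write_json(truths, paths$truth, auto_unbox = TRUE, digits = NA)
  folds <- matrix(c(1, 1, 2, 0.5), nrow = 2,
                  dimnames = list(c("gene1", "gene2"),
                                  c("control", "treated")))
  utils::write.csv(make_ct_table(folds, noise_sd = 0.2, seed = seed),
                   paths$ct, row.names = FALSE, quote = FALSE)
  series <- c(
    lapply(1:3, function(i) {
      make_swelling_series(1e-3, noise_sd = 5e-4, seed = seed + i,
                           oocyte_id = sprintf("water_%d", i),
                           group = "water")
    }),
    lapply(1:3, function(i) {
      make_swelling_series(5e-3, noise_sd = 5e-4, seed = seed + 10 + i,
                           oocyte_id = sprintf("aqp_%d", i),
                           group = "aqp")
    })
  )
  write_swelling_csv(series, paths$swelling)
  invisible(paths)
}
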