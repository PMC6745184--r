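# Distance-based subfamily classification: pairwise identity distances,
# Saitou-Nei neighbor joining (implemented here, returning an ape "phylo"),
# nearest-reference subfamily calls and nomenclature proposal.

#' Pairwise identity-distance matrix
#'
#' Distance between two sequences is `1 - identity` of their optimal global
#' alignment (identity over columns where neither sequence is gapped);
#' symmetric with a zero diagonal.
#'
#' @param seqs list of [protein_sequence()] objects with unique ids.
#' @param config [aqp_config()].
#' @return Symmetric numeric matrix with the sequence ids as dimnames.
#' @export
pairwise_distance_matrix <- function(seqs, config = aqp_config()) {
  if (length(seqs) < 2L) {
    stop("pairwise_distance_matrix: need at least 2 sequences")
  }
  ids <- vapply(seqs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("pairwise_distance_matrix: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- global_align(seqs[[i]], seqs[[j]], config)
      d[i, j] <- d[j, i] <- 1 - aln$identity
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining: iteratively join the pair minimizing the
#' Q-criterion `(n-2) d_ij - r_i - r_j`, with branch lengths from the
#' standard NJ formulas; negative branch lengths are clamped to zero. Ties
#' are broken by current row order, making the topology deterministic.
#'
#' @param d symmetric distance matrix with dimnames (at least 3 taxa).
#' @return An unrooted `phylo` object (class from \pkg{ape}).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("nj_tree: need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("nj_tree: distance matrix must be symmetric")
  }
  labels <- rownames(d)
  # each active node carries its newick subtree string; placeholder leaf
  # labels keep ids with Newick metacharacters (";", "(", ...) safe
  nwk <- as.list(sprintf("L%d", seq_len(n)))
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[[i]], bi, nwk[[j]], bj)
    du <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    lab <- c(rownames(d)[keep], sprintf("U%d", m))
    dimnames(d2) <- list(lab, lab)
    nwk <- c(nwk[keep], new_nwk)
    d <- d2
  }
  # final three nodes: closed-form three-point branch lengths
  b1 <- max(0, 0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  b2 <- max(0, 0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  b3 <- max(0, 0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nwk[[1]], b1, nwk[[2]], b2, nwk[[3]], b3)
  tree <- ape::read.tree(text = newick)
  tree$tip.label <- labels[as.integer(sub("^L", "", tree$tip.label))]
  tree
}

#' Assign a query to an aquaporin subfamily by nearest reference
#'
#' The query inherits subfamily and class from the closest reference in the
#' distance matrix; support is the margin between the closest reference of
#' a *different* subfamily and the closest reference overall. Ties go to
#' the reference earliest in the table order.
#'
#' @param query_id id of the query (must be in `d`).
#' @param refs list of [reference_anchor()] objects present in `d`.
#' @param d distance matrix from [pairwise_distance_matrix()].
#' @return An object of class `subfamily_call` with `query_id`,
#'   `subfamily`, `class_label`, `nearest_reference_id` and `support`.
#' @export
assign_subfamily <- function(query_id, refs, d) {
  ref_ids <- unname(vapply(refs, function(r) r$sequence$id, ""))
  present <- ref_ids %in% rownames(d)
  if (!any(present)) stop("assign_subfamily: no reference present in d")
  if (!query_id %in% rownames(d)) {
    stop("assign_subfamily: query '", query_id, "' not in distance matrix")
  }
  refs <- refs[present]
  ref_ids <- ref_ids[present]
  dq <- d[query_id, ref_ids]
  best <- which.min(dq)  # ties: earliest reference
  subfam <- refs[[best]]$subfamily
  other <- vapply(refs, `[[`, "", "subfamily") != subfam
  support <- if (any(other)) min(dq[other]) - dq[best] else NA_real_
  structure(
    list(query_id = query_id, subfamily = subfam,
         class_label = refs[[best]]$class_label,
         nearest_reference_id = ref_ids[best],
         support = unname(support)),
    class = "subfamily_call"
  )
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat("<subfamily_call> ", x$query_id, " -> ", x$subfamily, "/",
      x$class_label, " (nearest ", x$nearest_reference_id,
      ", support ", format(x$support, digits = 3), ")\n", sep = "")
  invisible(x)
}

# index after ";" in names like "AtPIP1;4"; NA when absent
parse_name_index <- function(id) {
  m <- regmatches(id, regexpr(";[0-9]+$", id))
  if (length(m) && nzchar(m)) as.integer(sub(";", "", m)) else NA_integer_
}

#' Propose a gene name from a subfamily call
#'
#' Names follow the `<prefix><class>;<index>` convention. The index of the
#' nearest reference is reused when free; otherwise the smallest unused
#' positive integer within the class is taken (so two queries nearest the
#' same reference always receive distinct names).
#'
#' @param call a [assign_subfamily()] result.
#' @param existing_names character vector of already-used names.
#' @param prefix species prefix, e.g. `"Es"`.
#' @return Proposed name, e.g. `"EsTIP2;1"`.
#' @export
propose_name <- function(call, existing_names = character(),
                         prefix = "Es") {
  stopifnot(inherits(call, "subfamily_call"))
  idx <- parse_name_index(call$nearest_reference_id)
  make_name <- function(i) paste0(prefix, call$class_label, ";", i)
  if (!is.na(idx) && !(make_name(idx) %in% existing_names)) {
    return(make_name(idx))
  }
  i <- 1L
  while (make_name(i) %in% existing_names) i <- i + 1L
  make_name(i)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
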