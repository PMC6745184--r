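# Shared fixtures and independent oracles used across test files.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N",
          "P","Q","R","S","T","V","W","Y")

# one shared synthetic anchor panel (deterministic)
.fixture_env <- new.env()
test_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    .fixture_env$panel <- make_reference_panel(seed = 20240901)
  }
  .fixture_env$panel
}

random_protein <- function(n, id = "rnd") {
  protein_sequence(id, paste(sample(AA20, n, replace = TRUE),
                             collapse = ""))
}

# --- exhaustive global-alignment score oracle (affine gaps, end gaps
# penalized); enumerates every alignment path recursively, no DP table
blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

brute_align_score <- function(q, r, gap_open = 10, gap_extend = 0.5) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(qc) && j > length(rc)) return(0)
    best <- -Inf
    if (i <= length(qc) && j <= length(rc)) {
      best <- max(best, blosum62[qc[i], rc[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(qc)) {
      cost <- gap_extend + if (state == "gr") 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, "gr"))
    }
    if (j <= length(rc)) {
      cost <- gap_extend + if (state == "gq") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, "gq"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# --- vectorized 0.001-step grid scan for the isoelectric point, computed
# from residue counts and the Bjellqvist constants (independent of
# net_charge / isoelectric_point internals)
grid_pi_oracle <- function(residues, step = 0.001) {
  chars <- strsplit(residues, "")[[1]]
  ph <- seq(0, 14, by = step)
  nterm_pk <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50)
  npk <- if (chars[1] %in% names(nterm_pk)) nterm_pk[[chars[1]]] else 7.5
  side_pos <- c(K = 10.00, R = 12.00, H = 5.98)
  side_neg <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)
  charge <- 1 / (1 + 10^(ph - npk)) - 1 / (1 + 10^(3.55 - ph))
  for (res in names(side_pos)) {
    charge <- charge + sum(chars == res) / (1 + 10^(ph - side_pos[[res]]))
  }
  for (res in names(side_neg)) {
    charge <- charge - sum(chars == res) / (1 + 10^(side_neg[[res]] - ph))
  }
  ph[which.min(abs(charge))]
}

# --- brute-force least-squares topology search over all unrooted
# topologies (4 or 5 taxa): ordinary LS branch fit per topology, smallest
# residual wins
tip_path_edges <- function(tree, a, b) {
  # BFS over the edge list between two tips; returns edge row indices
  edges <- tree$edge
  nodes <- max(edges)
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- rbind(adj[[edges[e, 1]]], c(edges[e, 2], e))
    adj[[edges[e, 2]]] <- rbind(adj[[edges[e, 2]]], c(edges[e, 1], e))
  }
  prev <- rep(NA_integer_, nodes)
  prev_edge <- rep(NA_integer_, nodes)
  queue <- a
  prev[a] <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == b) break
    for (k in seq_len(NROW(adj[[v]]))) {
      w <- adj[[v]][k, 1]
      if (is.na(prev[w])) {
        prev[w] <- v; prev_edge[w] <- adj[[v]][k, 2]
        queue <- c(queue, w)
      }
    }
  }
  path <- integer(0)
  v <- b
  while (v != a) {
    path <- c(path, prev_edge[v])
    v <- prev[v]
  }
  path
}

ls_best_topology <- function(d) {
  labels <- rownames(d)
  n <- length(labels)
  stopifnot(n %in% c(4L, 5L))
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  pairs <- t(utils::combn(n, 2))
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(topos)) {
    tr <- topos[[ti]]  # [[ decompresses the shared tip labels
    ne <- nrow(tr$edge)
    A <- matrix(0, nrow(pairs), ne)
    y <- numeric(nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      i <- match(labels[pairs[p, 1]], tr$tip.label)
      j <- match(labels[pairs[p, 2]], tr$tip.label)
      A[p, tip_path_edges(tr, i, j)] <- 1
      y[p] <- d[pairs[p, 1], pairs[p, 2]]
    }
    fit <- lm.fit(A, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tr }
  }
  best
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

expect_feature_recovery <- function(prof, truth) {
  expect_identical(prof$npa_lb$motif, truth$npa_lb$motif)
  expect_identical(unname(prof$npa_lb$start), truth$npa_lb$start)
  expect_identical(prof$npa_le$motif, truth$npa_le$motif)
  expect_identical(unname(prof$npa_le$start), truth$npa_le$start)
  expect_identical(unname(prof$arr), unname(truth$arr))
  expect_identical(unname(prof$froger), unname(truth$froger))
  expect_identical(unname(prof$sdp), unname(truth$sdp))
}

sdp_row_call <- function(row, patterns, ...) {
  match_sdp(as.character(row[paste0("SDP", 1:9)]),
            patterns[[row$substrate]], ...)
}
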