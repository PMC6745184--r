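test_that("identity distances: zero for identical, one for disjoint, symmetric", {
  a <- protein_sequence("a", "MKTLLVAG")
  a2 <- protein_sequence("a2", "MKTLLVAG")
  d <- pairwise_distance_matrix(list(a, a2))
  expect_equal(d["a", "a2"], 0)
  mism <- pairwise_distance_matrix(list(protein_sequence("x", "KKKKKK"),
                                        protein_sequence("y", "EEEEEE")))
  expect_equal(mism["x", "y"], 1)
  set.seed(12)
  seqs <- lapply(1:4, function(i) random_protein(40, paste0("s", i)))
  d2 <- pairwise_distance_matrix(seqs)
  expect_identical(d2, t(d2))
  expect_true(all(diag(d2) == 0))
  # element-wise recomputation from the stored alignments
  for (i in 1:3) for (j in (i + 1):4) {
    aln <- global_align(seqs[[i]], seqs[[j]])
    expect_equal(d2[i, j], 1 - aln$identity)
  }
  expect_error(pairwise_distance_matrix(list(a, a)), "duplicate")
})

test_that("three-taxon NJ solves the three-point equations", {
  d <- matrix(c(0, 0.4, 0.6,
                0.4, 0, 0.8,
                0.6, 0.8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0.5 * (0.4 + 0.6 - 0.8))
  expect_equal(bl[["b"]], 0.5 * (0.4 + 0.8 - 0.6))
  expect_equal(bl[["c"]], 0.5 * (0.6 + 0.8 - 0.4))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating topology of additive matrices (<= 8 taxa)", {
  for (k in 1:12) {
    n <- sample(4:8, 1)
    fx <- random_additive_distances(n, seed = 900 + k)
    expect_true(same_topology(nj_tree(fx$d), fx$tree))
    # and branch lengths reproduce the metric on an additive input
    expect_equal(ape::cophenetic.phylo(nj_tree(fx$d))[rownames(fx$d),
                                                      colnames(fx$d)],
                 fx$d, tolerance = 1e-6)
  }
})

test_that("NJ agrees with the brute-force least-squares topology search", {
  agree <- 0L
  for (k in 1:20) {
    n <- if (k %% 2 == 0) 4L else 5L
    fx <- random_additive_distances(n, seed = 3000 + k)
    agree <- agree +
      as.integer(same_topology(nj_tree(fx$d), ls_best_topology(fx$d)))
  }
  expect_identical(agree, 20L)
})

test_that("NJ matches the ape reference implementation topology", {
  for (k in 1:5) {
    fx <- random_additive_distances(7, seed = 40 + k)
    # perturb slightly so the matrix is near- but not exactly additive
    d <- fx$d
    set.seed(k)
    noise <- matrix(runif(49, 0, 0.01), 7, 7)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- d + noise
    expect_true(same_topology(nj_tree(d), ape::nj(as.dist(d))))
  }
})

test_that("subfamily assignment: exact anchor hit, support margin, counts", {
  panel <- test_panel()
  queries <- list()
  truth_sub <- character()
  k <- 0L
  for (sub in c("PIP", "TIP", "NIP", "SIP")) {
    for (i in 1:2) {
      k <- k + 1L
      q <- make_query(panel, sub, flank_mutation_rate = 0.08,
                      seed = 700 + k, id = sprintf("q%d", k))
      queries[[k]] <- q$sequence
      truth_sub[k] <- sub
    }
  }
  seqs <- c(queries, lapply(panel, `[[`, "sequence"))
  d <- pairwise_distance_matrix(seqs)
  calls <- lapply(queries, function(q) assign_subfamily(q$id, panel, d))
  got <- vapply(calls, `[[`, "", "subfamily")
  expect_identical(got, truth_sub)
  expect_true(all(vapply(calls, `[[`, 0, "support") > 0))
  # subfamily counts sum to the number of queries
  expect_identical(sum(table(got)), length(queries))
  # a query equal to an anchor inherits its subfamily and class
  qa <- protein_sequence("qa", panel[["SynTIP2;1"]]$sequence$residues)
  d2 <- pairwise_distance_matrix(c(list(qa), lapply(panel, `[[`, "sequence")))
  call <- assign_subfamily("qa", panel, d2)
  expect_identical(call$subfamily, "TIP")
  expect_identical(call$class_label, "TIP2")
  expect_identical(call$nearest_reference_id, "SynTIP2;1")
})

test_that("assignment is invariant under query input order", {
  panel <- test_panel()
  q1 <- make_query(panel, "NIP", flank_mutation_rate = 0.05, seed = 77,
                   id = "nq")$sequence
  q2 <- make_query(panel, "SIP", flank_mutation_rate = 0.05, seed = 78,
                   id = "sq")$sequence
  refs_seqs <- lapply(panel, `[[`, "sequence")
  dA <- pairwise_distance_matrix(c(list(q1, q2), refs_seqs))
  dB <- pairwise_distance_matrix(c(list(q2, q1), refs_seqs))
  expect_identical(assign_subfamily("nq", panel, dA)$subfamily,
                   assign_subfamily("nq", panel, dB)$subfamily)
  expect_identical(assign_subfamily("sq", panel, dA)$class_label,
                   assign_subfamily("sq", panel, dB)$class_label)
})

test_that("name proposal reuses the anchor index, then the smallest free one", {
  call <- structure(list(query_id = "q", subfamily = "TIP",
                         class_label = "TIP2",
                         nearest_reference_id = "AtTIP2;1",
                         support = 0.2),
                    class = "subfamily_call")
  expect_identical(propose_name(call, character()), "EsTIP2;1")
  call$nearest_reference_id <- "AtPIP1;4"
  call$class_label <- "PIP1"
  taken <- c("EsPIP1;1", "EsPIP1;2", "EsPIP1;3", "EsPIP1;4")
  expect_identical(propose_name(call, taken), "EsPIP1;5")
  # two queries nearest the same reference get distinct names
  n1 <- propose_name(call, taken)
  n2 <- propose_name(call, c(taken, n1))
  expect_false(identical(n1, n2))
})

test_that("phylip distance export is readable square format", {
  fx <- random_additive_distances(4, seed = 2)
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip_distances(fx$d, path)
  lines <- readLines(path)
  expect_identical(as.integer(trimws(lines[1])), 4L)
  expect_length(lines, 5L)
})
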