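test_that("self-alignment has identity 1 and no gaps", {
  s <- random_protein(60, "self")
  a <- global_align(s, s)
  expect_identical(a$identity, 1)
  expect_false(grepl("-", a$aligned_query, fixed = TRUE))
  expect_identical(a$aligned_query, a$aligned_ref)
})

test_that("NPA vs NPG identity is 2/3", {
  a <- global_align(protein_sequence("q", "NPA"),
                    protein_sequence("r", "NPG"))
  expect_equal(a$identity, 2 / 3)
})

test_that("alignment score equals the exhaustive-path oracle (len <= 8)", {
  set.seed(9)
  for (k in 1:10) {
    q <- paste(sample(AA20, sample(2:7, 1), TRUE), collapse = "")
    r <- paste(sample(AA20, sample(2:7, 1), TRUE), collapse = "")
    a <- global_align(protein_sequence("q", q), protein_sequence("r", r))
    expect_equal(a$score, brute_align_score(q, r), tolerance = 1e-9)
  }
  # one pair at the oracle's size limit
  q <- paste(sample(AA20, 8, TRUE), collapse = "")
  r <- paste(sample(AA20, 8, TRUE), collapse = "")
  a <- global_align(protein_sequence("q", q), protein_sequence("r", r))
  expect_equal(a$score, brute_align_score(q, r), tolerance = 1e-9)
})

test_that("optimal score is >= hand-constructed alignments", {
  # ungapped overlay of equal-length strings is one specific alignment
  set.seed(10)
  for (k in 1:5) {
    q <- paste(sample(AA20, 12, TRUE), collapse = "")
    r <- paste(sample(AA20, 12, TRUE), collapse = "")
    hand <- sum(vapply(1:12, function(i) {
      blosum62[substr(q, i, i), substr(r, i, i)]
    }, 0))
    a <- global_align(protein_sequence("q", q), protein_sequence("r", r))
    expect_gte(a$score, hand)
  }
})

test_that("best-reference selection: exact match, ties, planted similarity", {
  panel <- test_panel()
  sel <- select_best_reference(panel[[3]]$sequence, panel)
  expect_identical(sel$anchor$sequence$id, panel[[3]]$sequence$id)
  # two identical refs: first in table order wins
  dup <- list(
    reference_anchor(protein_sequence("first", panel[[1]]$sequence$residues),
                     "PIP", "PIP1", panel[[1]]$feature_positions),
    reference_anchor(protein_sequence("second", panel[[1]]$sequence$residues),
                     "PIP", "PIP2", panel[[1]]$feature_positions)
  )
  attr(dup, "layout") <- attr(panel, "layout")
  sel2 <- select_best_reference(panel[[1]]$sequence, dup)
  expect_identical(sel2$anchor$sequence$id, "first")
  # a PIP-like query picks a PIP anchor out of the mixed panel
  q <- make_query(panel, "PIP", flank_mutation_rate = 0.08, seed = 31)
  sel3 <- select_best_reference(q$sequence, panel)
  expect_identical(sel3$anchor$subfamily, "PIP")
})

test_that("position projection: identity, gaps, planted truth", {
  s <- random_protein(50, "s")
  a <- global_align(s, s)
  pos <- c(A = 1L, B = 25L, C = 50L)
  expect_identical(project_positions(a, pos), pos)
  # reference residues 21-30 deleted from the query -> unresolved
  chars <- strsplit(s$residues, "")[[1]]
  del <- protein_sequence("del", paste(chars[-(21:30)], collapse = ""))
  a2 <- global_align(del, s)
  proj <- project_positions(a2, c(mid = 25L, late = 45L))
  expect_true(is.na(proj[["mid"]]))
  expect_identical(proj[["late"]], 35L)
  expect_error(project_positions(a2, c(bad = 51L)), "outside reference")
})

test_that("NPA motif scan: loop placement, variants, fallback, errors", {
  panel <- test_panel()
  q <- make_query(panel, "PIP", flank_mutation_rate = 0, seed = 3,
                  features = list(npa_lb = "NPT"))
  tm <- predict_tm_segments(q$sequence)
  m <- find_npa_motifs(q$sequence, tm)
  expect_identical(m$source, "scan")
  expect_identical(m$lb$motif, "NPT")
  expect_identical(m$lb$start, q$truth$npa_lb$start)
  expect_identical(m$le$motif, "NPA")
  expect_identical(m$le$start, q$truth$npa_le$start)
  # no N-P-X and no anchor: NotFound error
  expect_error(find_npa_motifs(protein_sequence("x", "AAAA")),
               "no N-P-X")
  # broken TM layout falls back to anchor projection
  m2 <- find_npa_motifs(q$sequence, tm[1:3, , drop = FALSE],
                        anchor_positions = c(NPA_LB = q$truth$npa_lb$start,
                                             NPA_LE = q$truth$npa_le$start))
  expect_identical(m2$source, "anchor")
  expect_identical(m2$lb$motif, "NPT")
})

test_that("profile of a query identical to an anchor equals the anchor annotation", {
  panel <- test_panel()
  anchor <- panel[[5]]
  q <- protein_sequence("copy", anchor$sequence$residues)
  prof <- extract_feature_profile(q, panel)
  fp <- anchor$feature_positions
  expect_identical(unname(prof$positions), unname(fp))
  expect_identical(prof$npa_lb$motif,
                   substr(q$residues, fp[["NPA_LB"]], fp[["NPA_LB"]] + 2))
  expect_length(prof$unresolved, 0)
})

test_that("planted features are fully recovered at moderate flank mutation", {
  panel <- test_panel()
  for (k in 1:12) {
    sub <- c("PIP", "TIP", "NIP", "SIP")[(k - 1) %% 4 + 1]
    q <- make_query(panel, sub, flank_mutation_rate = 0.1, seed = 100 + k)
    prof <- extract_feature_profile(q$sequence, panel)
    expect_feature_recovery(prof, q$truth)
    expect_identical(prof$anchor_subfamily, sub)
  }
})

test_that("feature recovery degrades (non-strictly) with mutation rate", {
  panel <- test_panel()
  recovery_at <- function(rate) {
    hits <- 0L
    for (k in 1:10) {
      q <- make_query(panel, "TIP", flank_mutation_rate = rate,
                      seed = 500 + k)
      prof <- extract_feature_profile(q$sequence, panel)
      hits <- hits + as.integer(
        identical(unname(prof$sdp), unname(q$truth$sdp)) &&
        identical(prof$npa_lb$start, q$truth$npa_lb$start))
    }
    hits
  }
  r_low <- recovery_at(0.05)
  r_mid <- recovery_at(0.3)
  r_high <- recovery_at(0.6)
  expect_identical(r_low, 10L)
  expect_true(r_low >= r_mid && r_mid >= r_high)
})
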