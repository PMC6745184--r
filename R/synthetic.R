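# Ground-truth fixture generators. Synthetic aquaporin-like proteins carry
# six planted hydrophobic transmembrane segments and planted NPA/ar-R/
# Froger/SDP residues at known positions; swelling curves and Ct tables are
# simulated from the same models the estimators assume. Every generator is
# a pure function of its seed.

HYDROPHOBIC_AA <- c("I", "L", "V", "F", "A", "M")
# loop alphabet excludes P so that "NP" dipeptides can only occur at
# planted motifs (keeps the de-novo N-P-X scan unambiguous)
HYDROPHILIC_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H")

#' Canonical synthetic aquaporin layout
#'
#' A fixed 290-residue architecture: six 21-residue transmembrane segments
#' joined by loops, with the loop-B and loop-E NPA motifs, the ar/R filter
#' (H2 in TM2, H5 in TM5, LE1/LE2 in loop E), Froger's positions and nine
#' SDPs at fixed 1-based positions. Planted positions are validated to lie
#' in regions consistent with the segment layout and to not overlap the
#' NPA motif spans.
#'
#' @param tm optional 6x2 matrix of transmembrane (start, end) intervals.
#' @param positions optional named vector overriding the 20 feature
#'   positions (names as in [feature_names()]).
#' @param length_aa total protein length.
#' @return A list of class `aqp_layout` with `length_aa`, `tm` and
#'   `positions`.
#' @export
aqp_layout <- function(tm = NULL, positions = NULL, length_aa = 290L) {
  if (is.null(tm)) {
    starts <- c(26L, 67L, 112L, 153L, 194L, 245L)
    tm <- cbind(start = starts, end = starts + 20L)
  }
  if (is.null(positions)) {
    positions <- c(
      NPA_LB = 95L, NPA_LE = 225L,
      H2 = 80L, H5 = 207L, LE1 = 229L, LE2 = 231L,
      P1 = 233L, P2 = 268L, P3 = 272L, P4 = 276L, P5 = 280L,
      SDP1 = 14L, SDP2 = 51L, SDP3 = 58L, SDP4 = 103L, SDP5 = 137L,
      SDP6 = 177L, SDP7 = 220L, SDP8 = 236L, SDP9 = 284L
    )
  }
  stopifnot(nrow(tm) == 6L, all(tm[, 2] > tm[, 1]),
            all(diff(as.vector(t(tm))) > 0), tm[6, 2] <= length_aa,
            all(feature_names() %in% names(positions)))
  positions <- positions[feature_names()]
  in_tm <- function(p) any(p >= tm[, 1] & p <= tm[, 2])
  # NPA motifs and all loop features must fall outside the TM segments;
  # H2/H5 must fall inside TM2/TM5
  loop_feats <- setdiff(feature_names(), c("H2", "H5"))
  spans <- c(unlist(lapply(positions[c("NPA_LB", "NPA_LE")],
                           function(p) p:(p + 2L))),
             positions[setdiff(loop_feats, c("NPA_LB", "NPA_LE"))])
  if (any(vapply(spans, in_tm, TRUE))) {
    stop("aqp_layout: infeasible layout (loop feature inside a TM segment)")
  }
  if (anyDuplicated(spans)) {
    stop("aqp_layout: infeasible layout (overlapping planted features)")
  }
  if (!(positions["H2"] >= tm[2, 1] && positions["H2"] <= tm[2, 2]) ||
      !(positions["H5"] >= tm[5, 1] && positions["H5"] <= tm[5, 2])) {
    stop("aqp_layout: H2/H5 must lie inside TM2/TM5")
  }
  structure(list(length_aa = as.integer(length_aa), tm = tm,
                 positions = positions),
            class = "aqp_layout")
}

# subfamily-typical planted feature residues (published consensus motifs)
subfamily_features <- function(subfamily) {
  switch(subfamily,
    PIP = list(npa_lb = "NPA", npa_le = "NPA",
               arr = c(H2 = "F", H5 = "H", LE1 = "T", LE2 = "R"),
               froger = c(P1 = "Q", P2 = "S", P3 = "A", P4 = "F", P5 = "W"),
               sdp = c("A", "G", "V", "F", "I", "H", "F", "V", "P")),
    TIP = list(npa_lb = "NPA", npa_le = "NPA",
               arr = c(H2 = "H", H5 = "I", LE1 = "G", LE2 = "R"),
               froger = c(P1 = "T", P2 = "S", P3 = "A", P4 = "Y", P5 = "W"),
               sdp = c("T", "L", "T", "V", "A", "S", "H", "P", "A")),
    NIP = list(npa_lb = "NPA", npa_le = "NPA",
               arr = c(H2 = "W", H5 = "V", LE1 = "A", LE2 = "R"),
               froger = c(P1 = "F", P2 = "S", P3 = "A", P4 = "Y", P5 = "L"),
               sdp = c("F", "K", "F", "T", "A", "D", "L", "E", "T")),
    SIP = list(npa_lb = "NPT", npa_le = "NPA",
               arr = c(H2 = "I", H5 = "V", LE1 = "P", LE2 = "I"),
               froger = c(P1 = "I", P2 = "A", P3 = "A", P4 = "Y", P5 = "W"),
               sdp = c("H", "P", "F", "A", "L", "P", "G", "S", "N")),
    stop("unknown subfamily: ", subfamily)
  )
}

region_alphabet <- function(pos, layout) {
  if (any(pos >= layout$tm[, 1] & pos <= layout$tm[, 2])) HYDROPHOBIC_AA
  else HYDROPHILIC_AA
}

feature_position_span <- function(layout) {
  p <- layout$positions
  sort(unique(c(
    unlist(lapply(p[c("NPA_LB", "NPA_LE")], function(x) x:(x + 2L))),
    p[setdiff(feature_names(), c("NPA_LB", "NPA_LE"))]
  )))
}

plant_features <- function(chars, layout, feats) {
  p <- layout$positions
  put <- function(pos, res) {
    res_chars <- strsplit(paste(res, collapse = ""), "")[[1]]
    chars[pos:(pos + length(res_chars) - 1L)] <<- res_chars
  }
  put(p[["NPA_LB"]], feats$npa_lb)
  put(p[["NPA_LE"]], feats$npa_le)
  for (k in c("H2", "H5", "LE1", "LE2")) put(p[[k]], feats$arr[[k]])
  for (i in 1:5) put(p[[paste0("P", i)]], feats$froger[[i]])
  for (i in 1:9) put(p[[paste0("SDP", i)]], feats$sdp[[i]])
  chars
}

mutate_chars <- function(chars, layout, rate, protect) {
  if (rate <= 0) return(chars)
  n <- length(chars)
  hit <- which(runif(n) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    alpha <- setdiff(region_alphabet(i, layout), chars[i])
    chars[i] <- sample(alpha, 1L)
  }
  chars
}

random_backbone <- function(layout) {
  n <- layout$length_aa
  chars <- character(n)
  for (i in seq_len(n)) {
    alpha <- region_alphabet(i, layout)
    chars[i] <- alpha[sample.int(length(alpha), 1L)]
  }
  chars
}

#' Generate a synthetic reference-anchor panel
#'
#' Builds a shared random backbone, derives one diverged master sequence
#' per subfamily (PIP/TIP/NIP/SIP), and emits `n_per_subfamily` anchors per
#' subfamily, each a lightly mutated copy of its master with the
#' subfamily-typical feature residues planted at the canonical layout
#' positions. Inter-subfamily distances exceed intra-subfamily distances by
#' construction. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_per_subfamily anchors per subfamily (>= 2 recommended).
#' @param layout an [aqp_layout()].
#' @param master_divergence per-site mutation rate from the backbone to
#'   each subfamily master.
#' @param anchor_divergence per-site mutation rate from the master to each
#'   anchor.
#' @return A list of [reference_anchor()] objects with the layout attached
#'   as attribute `layout` (anchor ids look like `"SynPIP1;1"`).
#' @export
make_reference_panel <- function(seed = 1, n_per_subfamily = 2,
                                 layout = aqp_layout(),
                                 master_divergence = 0.25,
                                 anchor_divergence = 0.03) {
  with_seed(seed, {
    protect <- feature_position_span(layout)
    backbone <- random_backbone(layout)
    panel <- list()
    for (sub in c("PIP", "TIP", "NIP", "SIP")) {
      feats <- subfamily_features(sub)
      master <- mutate_chars(backbone, layout, master_divergence, protect)
      for (k in seq_len(n_per_subfamily)) {
        chars <- mutate_chars(master, layout, anchor_divergence, protect)
        chars <- plant_features(chars, layout, feats)
        id <- sprintf("Syn%s%d;1", sub, k)
        panel[[id]] <- reference_anchor(
          protein_sequence(id, paste(chars, collapse = "")),
          subfamily = sub, class_label = paste0(sub, k),
          feature_positions = layout$positions
        )
      }
    }
    attr(panel, "layout") <- layout
    panel
  })
}

#' Generate a synthetic query with a known truth record
#'
#' Takes the first panel anchor of the requested subfamily (and class, when
#' given) as template, mutates non-feature positions at
#' `flank_mutation_rate` within region-appropriate residue alphabets
#' (hydrophobic inside TM segments, hydrophilic in loops), and plants the
#' requested feature residues exactly. The truth record carries every
#' planted position and residue.
#'
#' @param panel output of [make_reference_panel()].
#' @param subfamily target subfamily.
#' @param class_label optional class within the subfamily.
#' @param flank_mutation_rate per-site mutation probability outside planted
#'   features, in `[0, 1]`.
#' @param seed integer seed.
#' @param features optional overrides: list with any of `npa_lb`, `npa_le`
#'   (3-character motifs), `arr` (4 residues), `froger` (5), `sdp` (9).
#' @param id query id.
#' @return List with `sequence` (a [protein_sequence()]) and `truth`
#'   (planted positions, motifs and residue tuples).
#' @export
make_query <- function(panel, subfamily = "PIP", class_label = NULL,
                       flank_mutation_rate = 0.05, seed = 1,
                       features = NULL, id = NULL) {
  stopifnot(flank_mutation_rate >= 0, flank_mutation_rate <= 1)
  layout <- attr(panel, "layout")
  if (is.null(layout)) {
    stop("make_query: panel must come from make_reference_panel()")
  }
  subs <- vapply(panel, `[[`, "", "subfamily")
  cand <- which(subs == subfamily)
  if (!is.null(class_label)) {
    cls <- vapply(panel, `[[`, "", "class_label")
    cand <- intersect(cand, which(cls == class_label))
  }
  if (!length(cand)) stop("make_query: no panel anchor for ", subfamily)
  template <- panel[[cand[1]]]
  feats <- subfamily_features(subfamily)
  if (!is.null(features)) feats[names(features)] <- features
  stopifnot(nchar(feats$npa_lb) == 3L, nchar(feats$npa_le) == 3L,
            length(feats$arr) == 4L, length(feats$froger) == 5L,
            length(feats$sdp) == 9L)
  if (is.null(id)) id <- sprintf("query_%s_s%d", subfamily, seed)
  with_seed(seed, {
    chars <- strsplit(template$sequence$residues, "")[[1]]
    protect <- feature_position_span(layout)
    chars <- mutate_chars(chars, layout, flank_mutation_rate, protect)
    chars <- plant_features(chars, layout, feats)
    p <- layout$positions
    names(feats$sdp) <- paste0("SDP", 1:9)
    truth <- list(
      subfamily = subfamily, class_label = template$class_label,
      positions = p,
      npa_lb = list(motif = feats$npa_lb, start = unname(p[["NPA_LB"]])),
      npa_le = list(motif = feats$npa_le, start = unname(p[["NPA_LE"]])),
      arr = feats$arr, froger = feats$froger, sdp = feats$sdp,
      tm = layout$tm
    )
    list(sequence = protein_sequence(id, paste(chars, collapse = "")),
         truth = truth)
  })
}

#' Simulate an oocyte swelling series with a known Pf
#'
#' Forward-Euler integration of `dV/dt = Pf S(V) Vw (osm_in - osm_out)`
#' with spherical `S(V)`, recorded as cross-sectional areas at `dt`
#' spacing, with optional multiplicative Gaussian area noise. Deterministic
#' per seed.
#'
#' @param pf_true planted permeability (length/time units of the inputs;
#'   cm min^-1 for cm^2 areas and minute sampling).
#' @param area0 initial cross-sectional area (cm^2; default a 0.06 cm
#'   radius oocyte).
#' @param osm_in internal osmolality (osmol cm^-3; default 2e-4, i.e. 200
#'   mOsm L^-1).
#' @param osm_out bath osmolality; default a 5-fold dilution of `osm_in`.
#' @param noise_sd standard deviation of multiplicative area noise.
#' @param dt time step, minutes.
#' @param t_max duration, minutes.
#' @param vw molar volume of water, cm^3 mol^-1.
#' @param seed integer seed.
#' @param oocyte_id,group labels for the resulting series.
#' @return A [swelling_series()].
#' @export
make_swelling_series <- function(pf_true, area0 = 0.0113,
                                 osm_in = 2e-4, osm_out = osm_in / 5,
                                 noise_sd = 0, dt = 0.25, t_max = 10,
                                 vw = 18, seed = 1,
                                 oocyte_id = "sim1", group = "construct") {
  stopifnot(pf_true >= 0, dt > 0, t_max > 0)
  times <- seq(0, t_max, by = dt)
  v <- sphere_geometry(area0)$volume
  vols <- numeric(length(times))
  vols[1] <- v
  dosm <- osm_in - osm_out
  for (i in seq_along(times)[-1]) {
    s <- 4 * pi * (3 * v / (4 * pi))^(2 / 3)
    v <- v + pf_true * s * vw * dosm * dt
    vols[i] <- v
  }
  areas <- pi * (3 * vols / (4 * pi))^(2 / 3)
  with_seed(seed, {
    if (noise_sd > 0) {
      areas <- areas * (1 + rnorm(length(areas), 0, noise_sd))
      areas[areas <= 0] <- min(areas[areas > 0])
    }
    swelling_series(oocyte_id, times, areas, osm_in, osm_out, group)
  })
}

#' Simulate a replicated qRT-PCR Ct table with known fold structure
#'
#' `Ct(gene, sample) = ref_ct - log2(abundance) + noise`, with the
#' reference gene at `ref_ct` in every sample; three biological times three
#' technical replicates by default. Biological noise (shared by the
#' technical replicates of one cDNA sample) has standard deviation
#' `noise_sd`; technical noise has `noise_sd / 2`.
#'
#' @param abundance named numeric matrix (genes x samples) of true
#'   abundance relative to the reference gene; a named vector is treated
#'   as a single-sample matrix.
#' @param ref_ct Ct of the reference gene.
#' @param noise_sd biological replicate noise (cycles).
#' @param bio_replicates,tech_replicates replicate structure.
#' @param seed integer seed.
#' @param reference reference gene name.
#' @return A Ct table data.frame (`gene, sample, replicate, ct`).
#' @export
make_ct_table <- function(abundance, ref_ct = 20, noise_sd = 0,
                          bio_replicates = 3, tech_replicates = 3,
                          seed = 1, reference = "actin") {
  if (is.null(dim(abundance))) {
    abundance <- matrix(abundance, ncol = 1,
                        dimnames = list(names(abundance), "S1"))
  }
  stopifnot(all(abundance > 0))
  genes <- rownames(abundance)
  samples <- colnames(abundance)
  with_seed(seed, {
    rows <- list()
    for (s in samples) {
      for (g in c(reference, genes)) {
        base <- if (g == reference) ref_ct else
          ref_ct - log2(abundance[g, s])
        for (b in seq_len(bio_replicates)) {
          bio <- if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0
          for (k in seq_len(tech_replicates)) {
            tech <- if (noise_sd > 0) rnorm(1, 0, noise_sd / 2) else 0
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, sample = s,
              replicate = sprintf("b%d.t%d", b, k),
              ct = base + bio + tech, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Random additive (tree-metric) distance matrix
#'
#' Draws a random unrooted tree with uniform branch lengths and returns its
#' patristic (cophenetic) distance matrix, which is additive by
#' construction. Used as a ground-truth fixture for neighbor joining.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param seed integer seed.
#' @param min_branch,max_branch branch-length range.
#' @return List with `tree` (a `phylo`) and `d` (the distance matrix).
#' @export
random_additive_distances <- function(n_taxa, seed = 1,
                                      min_branch = 0.05, max_branch = 1) {
  stopifnot(n_taxa >= 4)
  with_seed(seed, {
    tree <- ape::rtree(n_taxa, rooted = FALSE,
                       br = function(k) runif(k, min_branch, max_branch))
    list(tree = tree, d = ape::cophenetic.phylo(tree))
  })
}
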