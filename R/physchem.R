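# Physicochemical profiling: molecular weight (average isotopic masses),
# Henderson-Hasselbalch net charge, isoelectric point by bisection, and
# Kyte-Doolittle hydropathy transmembrane-segment prediction.

# average residue (i.e. water-loss corrected) masses, Da
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy index
KD_INDEX <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# pK sets for ionizable groups. "expasy" carries the Bjellqvist values with
# residue-specific N-terminal pKs; "emboss" is the EMBOSS iep set.
pk_values <- function(set = c("expasy", "emboss")) {
  set <- match.arg(set)
  if (set == "expasy") {
    list(
      cterm = 3.55,
      nterm_default = 7.5,
      nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50),
      side = c(D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00,
               K = 10.00, R = 12.00)
    )
  } else {
    list(
      cterm = 3.6,
      nterm_default = 8.6,
      nterm = c(),
      side = c(D = 3.9, E = 4.1, H = 6.5, C = 8.5, Y = 10.1,
               K = 10.8, R = 12.5)
    )
  }
}

#' Molecular weight of a protein
#'
#' Sum of average-isotopic residue masses plus one water, reported in kDa.
#' The initiator methionine, when present in the sequence, is counted like
#' any other residue.
#'
#' @param seq a [protein_sequence()] without `X` residues.
#' @return Molecular weight in kDa.
#' @export
#' @examples
#' molecular_weight(protein_sequence("g", "G"))  # 0.07507 kDa
molecular_weight <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (seq$has_x) {
    stop("molecular_weight: sequence '", seq$id,
         "' contains X (ambiguous mass)")
  }
  chars <- seq_chars(seq)
  (sum(AA_AVG_MASS[chars]) + WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, K, R, H) using a fixed pK set.
#' Strictly decreasing in pH.
#'
#' @param seq a [protein_sequence()].
#' @param ph pH in `[0, 14]`.
#' @param pk_set `"expasy"` (Bjellqvist) or `"emboss"`.
#' @return Signed net charge (elementary charges).
#' @export
net_charge <- function(seq, ph, pk_set = c("expasy", "emboss")) {
  stopifnot(inherits(seq, "protein_sequence"), ph >= 0, ph <= 14)
  pk <- pk_values(match.arg(pk_set))
  chars <- seq_chars(seq)
  first <- chars[1]
  nterm_pk <- if (first %in% names(pk$nterm)) pk$nterm[[first]] else
    pk$nterm_default
  pos <- 1 / (1 + 10^(ph - nterm_pk))
  for (res in c("K", "R", "H")) {
    n <- sum(chars == res)
    if (n > 0 && res %in% names(pk$side)) {
      pos <- pos + n / (1 + 10^(ph - pk$side[[res]]))
    }
  }
  neg <- 1 / (1 + 10^(pk$cterm - ph))
  for (res in c("D", "E", "C", "Y")) {
    n <- sum(chars == res)
    if (n > 0 && res %in% names(pk$side)) {
      neg <- neg + n / (1 + 10^(pk$side[[res]] - ph))
    }
  }
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection on `[0, 14]`.
#' The charge function is continuous and strictly monotone decreasing, so
#' the root is unique; bisection is iterated to near machine precision
#' (well below the 0.01 pH reporting resolution).
#'
#' @inheritParams net_charge
#' @param tol bisection half-interval tolerance.
#' @return Isoelectric point in pH units.
#' @export
isoelectric_point <- function(seq, pk_set = c("expasy", "emboss"),
                              tol = 1e-10) {
  pk_set <- match.arg(pk_set)
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, pk_set) > 0) lo <- mid else hi <- mid
    if ((hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Predict transmembrane segments by Kyte--Doolittle hydropathy
#'
#' Hydropathy is averaged over a centred sliding window; maximal runs of
#' window centres above the threshold are merged when separated by fewer
#' than `merge_gap` residues, expanded by the half-window on both sides,
#' then discarded if shorter than `min_len` or trimmed (centred on the
#' hydropathy peak) if longer than `max_len`. Aquaporins are expected to
#' yield six segments.
#'
#' @param seq a [protein_sequence()].
#' @param window odd window width.
#' @param threshold window-mean hydropathy threshold.
#' @param merge_gap merge runs separated by fewer than this many residues.
#' @param min_len,max_len segment length bounds after expansion.
#' @return Integer matrix with columns `start`, `end` (possibly 0 rows),
#'   ordered, non-overlapping. A sequence shorter than the window yields an
#'   empty matrix with a warning.
#' @export
predict_tm_segments <- function(seq, window = 19, threshold = 1.6,
                                merge_gap = 4, min_len = 15, max_len = 30) {
  stopifnot(inherits(seq, "protein_sequence"), window %% 2 == 1)
  chars <- seq_chars(seq)
  n <- length(chars)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (n < window) {
    warning("predict_tm_segments: sequence '", seq$id,
            "' shorter than window (", window, ")")
    return(empty)
  }
  h <- (window - 1L) %/% 2L
  vals <- KD_INDEX[chars]
  win_mean <- as.numeric(stats::filter(vals, rep(1 / window, window),
                                       sides = 2))
  centers <- which(!is.na(win_mean) & win_mean > threshold)
  if (!length(centers)) return(empty)
  # maximal runs of above-threshold centres
  run_break <- c(TRUE, diff(centers) > 1L)
  run_id <- cumsum(run_break)
  runs <- lapply(split(centers, run_id), range)
  # merge runs separated by fewer than merge_gap residues
  merged <- list(runs[[1]])
  if (length(runs) > 1L) {
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] - last[2] - 1L < merge_gap) {
        merged[[length(merged)]] <- c(last[1], r[2])
      } else {
        merged[[length(merged) + 1L]] <- r
      }
    }
  }
  segs <- lapply(merged, function(r) {
    start <- max(1L, r[1] - h)
    end <- min(n, r[2] + h)
    len <- end - start + 1L
    if (len < min_len) return(NULL)
    if (len > max_len) {
      centres <- r[1]:r[2]
      peak <- centres[which.max(win_mean[centres])]
      start2 <- peak - (max_len - 1L) %/% 2L
      start2 <- min(max(start2, start), end - max_len + 1L)
      start <- max(start, start2)
      end <- start + max_len - 1L
    }
    c(start, end)
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  if (is.null(segs)) return(empty)
  # enforce non-overlap (possible after expansion of close runs)
  if (nrow(segs) > 1L) {
    for (i in 2:nrow(segs)) {
      if (segs[i, 1] <= segs[i - 1, 2]) segs[i, 1] <- segs[i - 1, 2] + 1L
    }
    segs <- segs[segs[, 2] - segs[, 1] + 1L >= min_len, , drop = FALSE]
  }
  dimnames(segs) <- list(NULL, c("start", "end"))
  segs
}

#' Full physicochemical profile
#'
#' @param seq a [protein_sequence()].
#' @param config a [aqp_config()] list.
#' @return A list of class `physchem_profile` with `length_aa`, `mw_kda`,
#'   `pi`, `tm_segments` and `tm_count`.
#' @export
physchem_profile <- function(seq, config = aqp_config()) {
  tm <- predict_tm_segments(seq, window = config$kd_window,
                            threshold = config$kd_threshold,
                            merge_gap = config$kd_merge_gap,
                            min_len = config$tm_min_len,
                            max_len = config$tm_max_len)
  structure(
    list(length_aa = seq_length(seq),
         mw_kda = if (seq$has_x) NA_real_ else molecular_weight(seq),
         pi = isoelectric_point(seq, pk_set = config$pk_set),
         tm_segments = tm,
         tm_count = nrow(tm)),
    class = "physchem_profile"
  )
}
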