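# Oocyte osmotic water-permeability: spherical geometry from the measured
# cross-sectional area, initial-slope Pf estimation, and one-way
# ANOVA/Fisher-LSD comparison between injection groups.
#
# Units: times in minutes, areas in cm^2, osmolality in osmol cm^-3, water
# molar volume Vw = 18 cm^3 mol^-1; Pf then comes out in cm min^-1
# (divide by 60 for cm s^-1).

#' Construct an oocyte swelling series
#'
#' @param oocyte_id identifier.
#' @param times minutes, strictly increasing, starting at 0.
#' @param areas measured cross-sectional areas (length^2 units, > 0).
#' @param osm_in,osm_out internal/external osmolality (osmol per
#'   volume-unit^3); a hypo-osmotic assay has `osm_in > osm_out`.
#' @param group e.g. `"water"` or a construct name.
#' @return An object of class `swelling_series`.
#' @export
swelling_series <- function(oocyte_id, times, areas, osm_in, osm_out,
                            group = "water") {
  stopifnot(length(times) == length(areas))
  if (length(times) < 1L || times[1] != 0) {
    stop("swelling_series: times must start at 0")
  }
  if (any(diff(times) <= 0)) {
    stop("swelling_series: times must be strictly increasing")
  }
  if (any(areas <= 0)) stop("swelling_series: areas must be > 0")
  if (osm_in <= osm_out) {
    stop("swelling_series: hypo-osmotic assay requires osm_in > osm_out")
  }
  structure(
    list(oocyte_id = oocyte_id, times = as.numeric(times),
         areas = as.numeric(areas), osm_in = osm_in, osm_out = osm_out,
         group = group),
    class = "swelling_series"
  )
}

#' Read swelling series from CSV
#'
#' Expected columns:
#' `oocyte_id, group, time_min, area, osm_in, osm_out`.
#'
#' @param path CSV path.
#' @return List of [swelling_series()] objects.
#' @export
read_swelling_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("oocyte_id", "group", "time_min", "area", "osm_in", "osm_out")
  if (!all(need %in% names(df))) {
    stop("read_swelling_csv: need columns ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$oocyte_id), function(g) {
    g <- g[order(g$time_min), ]
    swelling_series(g$oocyte_id[1], g$time_min, g$area,
                    g$osm_in[1], g$osm_out[1], g$group[1])
  })
}

#' Write swelling series to CSV
#'
#' @param series list of [swelling_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_swelling_csv <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(oocyte_id = s$oocyte_id, group = s$group,
               time_min = s$times, area = s$areas,
               osm_in = s$osm_in, osm_out = s$osm_out,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sphere volume and surface area from a cross-sectional area
#'
#' Oocytes are modelled as spheres; the measured image area is the great
#' circle, so `r = sqrt(area / pi)`, `V = 4/3 pi r^3`, `S = 4 pi r^2`.
#'
#' @param area cross-sectional area (> 0).
#' @return List with `radius`, `volume`, `surface`.
#' @export
#' @examples
#' sphere_geometry(pi)$volume  # 4*pi/3
sphere_geometry <- function(area) {
  if (any(area <= 0)) stop("sphere_geometry: area must be > 0")
  r <- sqrt(area / pi)
  list(radius = r, volume = 4 / 3 * pi * r^3, surface = 4 * pi * r^2)
}

#' Osmotic water permeability from a swelling series
#'
#' `Pf = V0 [d(V/V0)/dt] / (S0 Vw (osm_in - osm_out))`, with `V0` and `S0`
#' the initial volume and surface area (from the t = 0 area) and the slope
#' `d(V/V0)/dt` estimated by an ordinary least-squares fit of relative
#' volume against time over the first `window_minutes` minutes. A
#' hypo-osmotic gradient with swelling yields `Pf > 0`.
#'
#' @param series a [swelling_series()].
#' @param window_minutes initial fitting window (default the first 10
#'   minutes).
#' @param vw molar volume of water, 18 cm^3 mol^-1.
#' @return An object of class `pf_result` with `pf` (length/time units of
#'   the inputs, cm min^-1 for cm/minute data), `v0`, `s0`, `slope`, `vw`
#'   and the group/oocyte labels.
#' @export
compute_pf <- function(series, window_minutes = 10, vw = 18) {
  stopifnot(inherits(series, "swelling_series"))
  keep <- series$times <= window_minutes
  if (sum(keep) < 3L) {
    stop("compute_pf: need at least 3 time points within the window")
  }
  dosm <- series$osm_in - series$osm_out
  if (dosm == 0) stop("compute_pf: zero osmotic gradient")
  geom0 <- sphere_geometry(series$areas[1])
  v <- sphere_geometry(series$areas[keep])$volume
  rel <- v / geom0$volume
  t <- series$times[keep]
  slope <- unname(coef(lm(rel ~ t))[2])
  structure(
    list(pf = geom0$volume * slope / (geom0$surface * vw * dosm),
         v0 = geom0$volume, s0 = geom0$surface, slope = slope, vw = vw,
         oocyte_id = series$oocyte_id, group = series$group),
    class = "pf_result"
  )
}

#' @export
print.pf_result <- function(x, ...) {
  cat("<pf_result> ", x$oocyte_id, " [", x$group, "]  Pf = ",
      format(x$pf, digits = 4), " (slope ", format(x$slope, digits = 4),
      " per min)\n", sep = "")
  invisible(x)
}

#' Compare Pf between injection groups (one-way ANOVA + Fisher LSD)
#'
#' Per-group mean Pf and fold change against the control group, the
#' one-way ANOVA F statistic, and Fisher's Least Significant Difference
#' pairwise p-values (t tests on the pooled within-group mean square with
#' `N - k` degrees of freedom).
#'
#' @param results list of [compute_pf()] results carrying group labels.
#' @param control_group group used as the fold-change baseline (default
#'   `"water"` when present, else the first group).
#' @return A list with `groups` (data.frame: group, n, mean_pf,
#'   fold_change), `anova` (`f`, `df1`, `df2`, `p`) and `lsd` (data.frame
#'   of pairwise comparisons with `diff` and `p`).
#' @export
pf_group_comparison <- function(results, control_group = NULL) {
  pf <- vapply(results, `[[`, 0, "pf")
  grp <- vapply(results, `[[`, "", "group")
  groups <- unique(grp)
  if (length(groups) < 2L) {
    stop("pf_group_comparison: need at least 2 groups")
  }
  n <- vapply(groups, function(g) sum(grp == g), 1L)
  if (any(n < 2L)) {
    stop("pf_group_comparison: every group needs at least 2 oocytes")
  }
  if (is.null(control_group)) {
    control_group <- if ("water" %in% groups) "water" else groups[1]
  }
  means <- vapply(groups, function(g) mean(pf[grp == g]), 0)
  gm <- mean(pf)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((pf - means[match(grp, groups)])^2)
  df1 <- length(groups) - 1L
  df2 <- length(pf) - length(groups)
  mse <- ssw / df2
  f <- if (ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df1) / mse
  p <- if (ssb == 0) 1 else if (ssw == 0) 0 else
    stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(groups, 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    diff <- means[[a]] - means[[b]]
    pv <- if (diff == 0) 1 else if (mse == 0) 0 else {
      tt <- diff / sqrt(mse * (1 / n[[a]] + 1 / n[[b]]))
      2 * stats::pt(-abs(tt), df2)
    }
    data.frame(group1 = a, group2 = b, diff = diff, p = pv,
               stringsAsFactors = FALSE)
  }))
  list(
    groups = data.frame(group = groups, n = unname(n),
                        mean_pf = unname(means),
                        fold_change = unname(means / means[[control_group]]),
                        stringsAsFactors = FALSE),
    anova = list(f = f, df1 = df1, df2 = df2, p = p),
    lsd = lsd,
    control_group = control_group
  )
}
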