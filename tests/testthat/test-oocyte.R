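test_that("sphere geometry: unit sphere, V/S identity, scaling law", {
  g <- sphere_geometry(pi)
  expect_equal(g$radius, 1)
  expect_equal(g$volume, 4 * pi / 3)
  expect_equal(g$surface, 4 * pi)
  for (a in c(0.01, 1, 37.5)) {
    g <- sphere_geometry(a)
    expect_equal(g$volume / g$surface, g$radius / 3)
    expect_equal(sphere_geometry(2 * a)$volume, g$volume * 2^(3 / 2))
  }
  expect_error(sphere_geometry(0), "> 0")
})

test_that("swelling series invariants are enforced", {
  expect_error(swelling_series("o", c(1, 2), c(1, 1), 2e-4, 4e-5),
               "start at 0")
  expect_error(swelling_series("o", c(0, 2, 2), c(1, 1, 1), 2e-4, 4e-5),
               "strictly increasing")
  expect_error(swelling_series("o", c(0, 1), c(1, -1), 2e-4, 4e-5), "> 0")
  expect_error(swelling_series("o", c(0, 1), c(1, 1), 4e-5, 2e-4),
               "osm_in > osm_out")
})

test_that("exactly linear relative volume gives the closed-form Pf", {
  area0 <- 0.0113
  g0 <- sphere_geometry(area0)
  b <- 5e-4  # d(V/V0)/dt per minute
  times <- seq(0, 10, by = 0.5)
  vols <- g0$volume * (1 + b * times)
  areas <- pi * (3 * vols / (4 * pi))^(2 / 3)
  s <- swelling_series("lin", times, areas, 2e-4, 4e-5)
  r <- compute_pf(s)
  expect_equal(r$slope, b, tolerance = 1e-8)
  expect_equal(r$pf, g0$volume * b / (g0$surface * 18 * (2e-4 - 4e-5)),
               tolerance = 1e-8)
})

test_that("zero slope means zero Pf; error cases", {
  times <- seq(0, 10, by = 1)
  s <- swelling_series("flat", times, rep(0.01, length(times)), 2e-4, 4e-5)
  expect_equal(compute_pf(s)$pf, 0)
  s2 <- swelling_series("short", c(0, 8, 16), c(0.01, 0.0101, 0.0102),
                        2e-4, 4e-5)
  expect_error(compute_pf(s2, window_minutes = 10), "at least 3")
})

test_that("simulated swelling round-trips the planted Pf within 2%", {
  for (pf_true in c(1e-3, 5e-3)) {
    s <- make_swelling_series(pf_true, noise_sd = 0)
    r <- compute_pf(s)
    expect_lt(abs(r$pf - pf_true) / pf_true, 0.02)
  }
  r0 <- compute_pf(make_swelling_series(0, noise_sd = 0))
  expect_lt(abs(r0$pf), 1e-12)
})

test_that("halving the simulation step moves recovered Pf by < 0.5%", {
  r1 <- compute_pf(make_swelling_series(5e-3, dt = 0.25, noise_sd = 0))
  r2 <- compute_pf(make_swelling_series(5e-3, dt = 0.125, noise_sd = 0))
  expect_lt(abs(r1$pf - r2$pf) / r2$pf, 0.005)
})

test_that("Pf estimation is dimensionally consistent under unit rescaling", {
  # lengths in cm vs mm: areas x 100, osmolality (per volume) / 1000,
  # Vw (volume per mol) x 1000 -> Pf scales by 10 (cm -> mm per minute)
  s_cm <- make_swelling_series(2e-3, noise_sd = 0)
  s_mm <- swelling_series(s_cm$oocyte_id, s_cm$times, s_cm$areas * 100,
                          s_cm$osm_in / 1000, s_cm$osm_out / 1000,
                          s_cm$group)
  pf_cm <- compute_pf(s_cm, vw = 18)$pf
  pf_mm <- compute_pf(s_mm, vw = 18000)$pf
  expect_equal(pf_mm, pf_cm * 10, tolerance = 1e-9)
})

test_that("Pf recovery is unbiased under symmetric area noise", {
  pf_true <- 3e-3
  est <- vapply(1:100, function(k) {
    compute_pf(make_swelling_series(pf_true, noise_sd = 0.001,
                                    seed = 7000 + k))$pf
  }, 0)
  expect_lt(abs(mean(est) - pf_true) / pf_true, 0.05)
})

test_that("group comparison: identical groups give fold 1 and p ~ 1", {
  mk <- function(id, grp, pf) {
    r <- compute_pf(make_swelling_series(pf, noise_sd = 0.002,
                                         seed = id, oocyte_id = paste0("o", id),
                                         group = grp))
    r
  }
  res <- c(lapply(1:3, mk, grp = "water", pf = 2e-3),
           lapply(1:3, function(i) mk(i, "construct", 2e-3)))
  cmp <- pf_group_comparison(res)
  expect_equal(cmp$groups$fold_change[cmp$groups$group == "construct"], 1)
  expect_gte(cmp$anova$p, 0.99)
  expect_equal(cmp$lsd$p, 1)
  expect_error(pf_group_comparison(res[1:3]), "at least 2 groups")
  expect_error(pf_group_comparison(res[c(1, 4, 5)]), "at least 2 oocytes")
})

test_that("ANOVA F equals the hand-computed mean-square ratio", {
  vals <- list(water = c(1, 2, 3), construct = c(4, 5, 6))
  res <- unlist(lapply(names(vals), function(g) {
    lapply(vals[[g]], function(v) {
      structure(list(pf = v, group = g, oocyte_id = "x",
                     v0 = 1, s0 = 1, slope = v, vw = 18),
                class = "pf_result")
    })
  }), recursive = FALSE)
  cmp <- pf_group_comparison(res, control_group = "water")
  means <- vapply(vals, mean, 0)
  gm <- mean(unlist(vals))
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((unlist(vals) - rep(means, each = 3))^2)
  expect_equal(cmp$anova$f, (ssb / 1) / (ssw / 4))
  expect_equal(cmp$groups$fold_change, unname(means / means["water"]))
})

test_that("a planted 2-fold Pf difference is detected at low noise", {
  water <- lapply(1:5, function(i) {
    compute_pf(make_swelling_series(2.5e-3, noise_sd = 0.002,
                                    seed = 100 + i,
                                    oocyte_id = paste0("w", i),
                                    group = "water"))
  })
  aqp <- lapply(1:5, function(i) {
    compute_pf(make_swelling_series(5e-3, noise_sd = 0.002,
                                    seed = 200 + i,
                                    oocyte_id = paste0("a", i),
                                    group = "construct"))
  })
  cmp <- pf_group_comparison(c(water, aqp))
  fold <- cmp$groups$fold_change[cmp$groups$group == "construct"]
  expect_equal(fold, 2, tolerance = 0.25)
  expect_lt(cmp$anova$p, 0.05)
  expect_lt(cmp$lsd$p[1], 0.05)
})

test_that("swelling CSV round-trips through the readers", {
  series <- list(
    make_swelling_series(1e-3, seed = 1, oocyte_id = "w1", group = "water"),
    make_swelling_series(5e-3, seed = 2, oocyte_id = "a1", group = "aqp")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_swelling_csv(series, path)
  back <- read_swelling_csv(path)
  expect_setequal(names(back), c("w1", "a1"))
  expect_equal(back$w1$areas, series[[1]]$areas, tolerance = 1e-12)
  expect_equal(compute_pf(back$a1)$pf, compute_pf(series[[2]])$pf,
               tolerance = 1e-10)
})
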