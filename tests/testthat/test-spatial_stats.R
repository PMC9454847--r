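test_that("nearest-neighbor distances match geometry and the brute-force oracle", {
  expect_equal(nn_distances(data.frame(x = 0, y = 0),
                            data.frame(x = c(3, 10), y = c(4, 0))), 5)
  # symmetric pair with self-exclusion
  pair <- data.frame(x = c(0, 0), y = c(0, 2))
  expect_equal(nn_distances(pair, pair, exclude_self = TRUE), c(2, 2))
  # no eligible target is a missing-metric signal, not an error
  expect_null(nn_distances(pair, pair[0, ]))
  expect_null(nn_distances(pair[1, ], pair[1, ], exclude_self = TRUE))

  withr::with_seed(BASE_SEED + 1, {
    for (rep in 1:5) {
      ref <- disc_points(100); tgt <- disc_points(100)
      expect_equal(nn_distances(ref, tgt), bf_nn(ref, tgt))
      expect_equal(nn_distances(ref, ref, exclude_self = TRUE),
                   bf_nn(ref, ref, exclude_self = TRUE))
    }
  })
})

test_that("engagement uses an inclusive 40 um boundary and matches brute force", {
  expect_equal(
    engagement_stats(data.frame(x = 0, y = 0),
                     data.frame(x = c(30, 50), y = c(0, 0)))[c("engaged_pct", "mean_contacts")],
    list(engaged_pct = 100, mean_contacts = 1)
  )
  # a target exactly at the radius counts as engaged
  at_r <- engagement_stats(data.frame(x = 0, y = 0),
                           data.frame(x = 40, y = 0))
  expect_equal(at_r$engaged_pct, 100)
  expect_equal(at_r$mean_contacts, 1)
  # empty target: engaged 0%, contacts missing
  none <- engagement_stats(data.frame(x = 0, y = 0),
                           data.frame(x = numeric(0), y = numeric(0)))
  expect_equal(none$engaged_pct, 0)
  expect_true(is.na(none$mean_contacts))

  withr::with_seed(BASE_SEED + 2, {
    for (rep in 1:3) {
      ref <- disc_points(200); tgt <- disc_points(200)
      got <- engagement_stats(ref, tgt, radius = 40)
      want <- bf_engagement(ref, tgt, radius = 40)
      expect_equal(got$engaged_pct, want$engaged_pct)
      expect_equal(got$mean_contacts, want$mean_contacts)
      # cross-operation consistency: engagement at r equals share of nn <= r
      expect_equal(got$engaged_pct,
                   100 * mean(nn_distances(ref, tgt) <= 40))
    }
  })
})

test_that("theoretical Poisson G obeys its closed form", {
  expect_equal(poisson_g(0, 17), 0)
  expect_equal(poisson_g(0.002, 0), 0)
  expect_equal(poisson_g(log(2) / (pi * 60^2), 60), 0.5)
  expect_error(poisson_g(-1, 10), "nonnegative")
  expect_error(poisson_g(0.001, -2), "nonnegative")
})

test_that("curve AUC integrates correctly", {
  r <- 0:60
  expect_equal(curve_auc(list(r = r, g = rep(1, 61))), 60)
  expect_equal(curve_auc(list(r = r, g = rep(0, 61))), 0)
  # trapezoid on a 1 um grid agrees with adaptive quadrature within 0.5%
  lam <- 0.001
  auc_trap <- curve_auc(list(r = r, g = poisson_g(lam, r)))
  auc_quad <- stats::integrate(function(s) poisson_g(lam, s), 0, 60)$value
  expect_lt(abs(auc_trap - auc_quad) / auc_quad, 0.005)
  # grid not covering r_max is an error
  expect_error(curve_auc(list(r = 0:30, g = rep(1, 31))), "cover")
  # grids extending beyond r_max integrate only to r_max
  expect_equal(curve_auc(list(r = seq(0, 100, 5), g = rep(1, 21)), r_max = 60), 60)
})

test_that("KM distance CDF handles degenerate and censor-free cases", {
  r <- 0:60
  # every reference cell has a coincident target: G(r) = 1 for all r
  g <- km_distance_cdf(rep(0, 5), rep(50, 5), r)
  expect_equal(g, rep(1, 61))
  # no censoring (all boundary distances beyond observations): exact ECDF
  withr::with_seed(BASE_SEED + 3, {
    d <- runif(40, 0, 50)
    g <- km_distance_cdf(d, rep(1000, 40), r)
    expect_equal(g, stats::ecdf(d)(r))
  })
  # all-censored data carry no events: G stays 0
  expect_equal(km_distance_cdf(c(10, 20), c(5, 5), r), rep(0, 61))
})

test_that("KM distance CDF agrees with the survival-package product-limit fit", {
  skip_if_not_installed("survival")
  withr::with_seed(BASE_SEED + 4, {
    for (rep in 1:5) {
      d <- rexp(80, 1 / 30)
      cens <- runif(80, 0, 60)
      r <- seq(0, 60, 1)
      mine <- km_distance_cdf(d, cens, r)
      fit <- survival::survfit(
        survival::Surv(pmin(d, cens), d <= cens) ~ 1
      )
      oracle <- 1 - summary(fit, times = r, extend = TRUE)$surv
      expect_equal(mine, oracle, tolerance = 1e-12)
    }
  })
})

test_that("cross-type G curves are monotone, bounded, and isometry-invariant", {
  withr::with_seed(BASE_SEED + 5, {
    w <- circle_window(0, 0, 300)
    ref <- disc_points(150); tgt <- disc_points(200)
    crv <- cross_g_km(ref, tgt, w)
    expect_true(all(diff(crv$g) >= 0))
    expect_true(all(crv$g >= 0 & crv$g <= 1))
    expect_gte(curve_auc(crv), 0)
    expect_lte(curve_auc(crv), 60)

    # joint translation + rotation of cells and window leaves G unchanged
    th <- 0.77; dx <- 1234; dy <- -987
    rot <- function(p) data.frame(x = cos(th) * p$x - sin(th) * p$y + dx,
                                  y = sin(th) * p$x + cos(th) * p$y + dy)
    w2 <- circle_window(dx, dy, 300)
    crv2 <- cross_g_km(rot(ref), rot(tgt), w2)
    expect_equal(crv2$g, crv$g, tolerance = 1e-9)
    expect_equal(mean(nn_distances(rot(ref), rot(tgt))),
                 mean(nn_distances(ref, tgt)), tolerance = 1e-9)

    # enlarging the target set never decreases G or engagement,
    # and never increases any nearest-neighbor distance
    extra <- rbind(tgt, disc_points(100))
    crv3 <- cross_g_km(ref, extra, w)
    expect_true(all(crv3$g >= crv$g - 1e-12))
    expect_true(all(nn_distances(ref, extra) <= nn_distances(ref, tgt) + 1e-12))
    expect_gte(engagement_stats(ref, extra)$engaged_pct,
               engagement_stats(ref, tgt)$engaged_pct)
  })
})

test_that("KM correction brings the CSR G estimate closer to theory than the raw ECDF", {
  # smaller sibling of the acceptance experiment: one pooled estimate
  lam <- 0.002
  w <- circle_window(0, 0, 300)
  r <- 0:60
  withr::with_seed(BASE_SEED + 6, {
    d_all <- c(); c_all <- c()
    for (s in 1:8) {
      core <- sample_csr_core(c(OTHER = lam, APC = lam), 300)
      ref <- core$cells[core$cells$phenotype == "OTHER", ]
      tgt <- core$cells[core$cells$phenotype == "APC", ]
      d_all <- c(d_all, nn_distances(ref, tgt))
      c_all <- c(c_all, edge_distance(w, ref$x, ref$y))
    }
    theory <- poisson_g(lam, r)
    err_km <- max(abs(km_distance_cdf(d_all, c_all, r) - theory))
    err_ecdf <- max(abs(stats::ecdf(d_all)(r) - theory))
    expect_lt(err_km, 0.05)
    expect_lt(err_km, err_ecdf)
  })
})

test_that("core summaries compose from the individual operations", {
  withr::with_seed(BASE_SEED + 7, {
    w <- circle_window(0, 0, 300)
    cells <- rbind(
      make_cells(runif(40, -200, 200), runif(40, -200, 200), "TCELL_HELPER"),
      make_cells(runif(25, -200, 200), runif(25, -200, 200), "APC"),
      make_cells(runif(60, -200, 200), runif(60, -200, 200), "EPITHELIAL"),
      make_cells(runif(80, -200, 200), runif(80, -200, 200), "OTHER")
    )
    s <- summarize_core(cells, w)
    get <- function(id) s$value[s$metric_id == id]
    th <- cells[cells$phenotype == "TCELL_HELPER", ]
    apc <- cells[cells$phenotype == "APC", ]
    expect_equal(get("mean_nn|TCELL_HELPER|APC"), mean(nn_distances(th, apc)))
    expect_equal(get("engagement_pct|TCELL_HELPER|APC"),
                 engagement_stats(th, apc, radius = 40)$engaged_pct)
    expect_equal(get("g_auc|TCELL_HELPER|APC"),
                 curve_auc(cross_g_km(th, apc, w, 0:60)))
    expect_equal(get("fraction_pct|IMMUNE"), 100 * (40 + 25) / nrow(cells))

    # missing propagation: no CTLs and no Tregs
    expect_true(is.na(get("mean_nn|TCELL_CTL|EPITHELIAL")))
    expect_true(is.na(get("count_ratio|TCELL_CTL|TCELL_TREG")))
    expect_false(is.na(get("mean_nn|TCELL|APC")))
  })

  # fraction bookkeeping on a hand-built core: 10 EC, 5 CTL, 5 other
  cells <- rbind(
    make_cells(1:10, rep(0, 10), "EPITHELIAL"),
    make_cells(1:5, rep(5, 5), "TCELL_CTL"),
    make_cells(1:5, rep(9, 5), "OTHER")
  )
  s <- summarize_core(cells, rect_window(0, 11, -1, 10))
  frac <- function(g) 100 * sum(cells$phenotype == g) / nrow(cells)
  expect_equal(s$value[s$metric_id == "fraction_pct|TCELL_CTL"], 25)
  expect_equal(s$value[s$metric_id == "fraction_pct|TCELL"], 25)
  expect_equal(frac("EPITHELIAL"), 50)
})

test_that("state filters select activation subsets for summaries", {
  w <- rect_window(-10, 110, -10, 110)
  ctl_act <- make_cells(c(0, 10), c(0, 0), "TCELL_CTL",
                        states = list(GZMB = c(1, 1), Ki67 = c(1, 0)))
  ec <- make_cells(c(5, 100), c(0, 100), "EPITHELIAL",
                   states = list(PDL1 = c(0, 1)))
  cells <- rbind(ctl_act, ec)
  s <- summarize_core(cells, w)
  # only the GZMB+Ki67+ CTL is the activated reference; EC at (5,0) engages it
  act <- s[s$metric_id == "engagement_pct|TCELL_CTL[GZMB+Ki67+]|EPITHELIAL", ]
  expect_equal(act$n_ref, 1)
  expect_equal(act$value, 100)
  # PD-L1 stratified engagement sees one EC on each side
  pdl_neg <- s[s$metric_id == "engagement_pct|TCELL_CTL|EPITHELIAL[PDL1-]", ]
  expect_equal(pdl_neg$n_target, 1)
  expect_equal(pdl_neg$value, 100)  # both CTLs within 40 um of the PDL1- EC
  pdl_pos <- s[s$metric_id == "engagement_pct|TCELL_CTL|EPITHELIAL[PDL1+]", ]
  expect_equal(pdl_pos$value, 0)    # the PDL1+ EC is far away
})

test_that("patient aggregation averages over non-missing cores", {
  rows <- function(vals, n_ref = 10, n_target = 10, metric = "mean_nn") {
    data.frame(unit_id = paste0("C", seq_along(vals)), level = "CORE",
               patient_id = "P1", metric = metric, family = "distances",
               ref = "TCELL", ref_state = NA, target = "APC", target_state = NA,
               value = vals, n_ref = n_ref, n_target = n_target,
               metric_id = paste0(metric, "|TCELL|APC"),
               stringsAsFactors = FALSE)
  }
  expect_equal(aggregate_patients(rows(c(1, 2, 3)))$value, 2)
  expect_equal(aggregate_patients(rows(c(4, NA, 6)))$value, 5)
  expect_true(is.na(aggregate_patients(rows(c(NA, NA)))$value))

  # pooled aggregation weights cores by their reference count
  cs <- rows(c(10, 40), n_ref = c(1, 3))
  expect_equal(aggregate_patients(cs, method = "pooled")$value,
               (1 * 10 + 3 * 40) / 4)
  # which matches computing the metric on the pooled cells directly
  withr::with_seed(BASE_SEED + 8, {
    w <- circle_window(0, 0, 300)
    core1 <- list(ref = disc_points(7), tgt = disc_points(30))
    core2 <- list(ref = disc_points(19), tgt = disc_points(40))
    v1 <- mean(nn_distances(core1$ref, core1$tgt))
    v2 <- mean(nn_distances(core2$ref, core2$tgt))
    pooled_direct <- mean(c(nn_distances(core1$ref, core1$tgt),
                            nn_distances(core2$ref, core2$tgt)))
    cs <- rows(c(v1, v2), n_ref = c(7, 19))
    expect_equal(aggregate_patients(cs, method = "pooled")$value, pooled_direct)
  })
})
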