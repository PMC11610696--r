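mk_stations <- function(sar, gradient_id = "g1", scale = "sar",
                        gear = "grab_core") {
  tibble::tibble(
    gradient_id = gradient_id,
    station_id = paste0("s", seq_along(sar)),
    pressure_value = sar,
    pressure_type = "trawling", pressure_scale = scale,
    gear = gear, depth_m = 30, sediment = "mud", salinity = NA,
    worsening = "increasing"
  )
}

test_that("station selection follows the SAR threshold rules", {
  ## general case: low < 0.35; five highest when >= 5 exceed SAR 1
  ct <- select_low_high_stations(
    mk_stations(c(0.1, 0.3, 0.4, 1.5, 2.0, 2.5, 3.0, 3.5)))
  expect_setequal(ct$low, c("s1", "s2"))
  expect_setequal(ct$high, c("s4", "s5", "s6", "s7", "s8"))
  expect_true(ct$evaluable)

  ## fewer than five above SAR 1: all of them
  ct2 <- select_low_high_stations(mk_stations(c(0.1, 0.2, 0.5, 1.5, 3)))
  expect_setequal(ct2$high, c("s4", "s5"))

  ## stations between the thresholds stay out of the contrast
  expect_false("s3" %in% c(ct2$low, ct2$high))
})

test_that("all-fished gradients fall back to the two least-fished stations", {
  ## every station above the low-SAR threshold
  ct <- select_low_high_stations(mk_stations(c(0.5, 0.8, 1.4, 2.2, 3.1,
                                               4.0, 5.5)))
  expect_setequal(ct$low, c("s1", "s2"))
  expect_setequal(ct$high, c("s3", "s4", "s5", "s6", "s7"))
})

test_that("gradients without SAR use zero-fished stations", {
  ## relative intensity: zero-pressure stations are the controls and the
  ## three most heavily fished the impact group
  ct <- select_low_high_stations(
    mk_stations(c(0, 0, 2, 5, 7, 9), scale = "relative"))
  expect_setequal(ct$low, c("s1", "s2"))
  expect_setequal(ct$high, c("s4", "s5", "s6"))
  expect_true(ct$evaluable)

  ## single zero station -> two least-fished fallback
  ct2 <- select_low_high_stations(
    mk_stations(c(0, 1, 2, 5, 7), scale = "relative"))
  expect_setequal(ct2$low, c("s1", "s2"))

  ## a one-station high group is non-evaluable
  ct3 <- select_low_high_stations(mk_stations(c(0, 0, 5), scale = "sar"))
  expect_setequal(ct3$low, c("s1", "s2"))
  expect_false(ct3$evaluable)
})

ind_for <- function(values, stations, indicator = "B") {
  tibble::tibble(gradient_id = stations$gradient_id[1],
                 station_id = stations$station_id,
                 indicator = indicator, value = values)
}

test_that("log response-ratios match the delta-method closed form", {
  st <- mk_stations(c(0.1, 0.2, 2, 3, 4, 5, 6))
  ct <- select_low_high_stations(st)
  ## low stations s1, s2 -> values 2, 2; high s3..s7 -> 1 each
  e <- log_response_ratio(ind_for(c(2, 2, 1, 1, 1, 1, 1), st), ct, "B")
  expect_equal(e$lnRR, log(0.5), tolerance = 1e-12)
  expect_equal(e$v, 0)
  expect_true(e$degenerate)

  ## nonzero SDs: v = sd_h^2/(n_h m_h^2) + sd_l^2/(n_l m_l^2)
  vals <- c(2, 4, 1, 2, 3, 1, 2)
  e2 <- log_response_ratio(ind_for(vals, st), ct, "B")
  lo <- vals[1:2]; hi <- vals[3:7]
  expect_equal(e2$lnRR, log(mean(hi) / mean(lo)), tolerance = 1e-12)
  expect_equal(e2$v, sd(hi)^2 / (5 * mean(hi)^2) + sd(lo)^2 / (2 * mean(lo)^2),
               tolerance = 1e-12)

  ## swapping the groups negates the effect
  ct_swap <- ct
  ct_swap$low <- ct$high
  ct_swap$high <- ct$low
  e3 <- log_response_ratio(ind_for(vals, st), ct_swap, "B")
  expect_equal(e3$lnRR, -e2$lnRR, tolerance = 1e-12)
})

test_that("the 0.01 floor applies exactly to the fraction-valued indices", {
  st <- mk_stations(c(0.1, 0.2, 2, 3, 4, 5, 6))
  ct <- select_low_high_stations(st)
  vals <- c(0.5, 0.5, 0, 0, 0, 0, 0)     # trawled mean 0
  e_sos <- log_response_ratio(ind_for(vals, st, "SoS"), ct, "SoS")
  expect_equal(e_sos$lnRR, log(0.01 / 0.5), tolerance = 1e-12)
  ## an unfloored indicator with a zero mean is missing instead
  e_b <- log_response_ratio(ind_for(vals, st, "B"), ct, "B")
  expect_true(is.na(e_b$lnRR))
  expect_equal(e_b$missing_reason, "nonpositive_mean")
  ## fewer than two non-missing stations per group -> missing
  e_na <- log_response_ratio(
    ind_for(c(1, NA, 2, 2, 2, NA, NA), st, "TDI"), ct, "TDI")
  expect_equal(e_na$missing_reason, "insufficient_stations")
})

test_that("random-effects pooling reduces to the inverse-variance average", {
  eff <- function(y, v) tibble::tibble(lnRR = y, v = v)
  ## single effect passes through
  p1 <- pool_random_effects(eff(-0.4, 0.02))
  expect_equal(p1$estimate, -0.4)
  expect_equal(p1$k, 1L)
  expect_equal(p1$tau2, 0)

  ## equal variances, tau2 irrelevant: plain average
  p2 <- pool_random_effects(eff(c(-0.2, -0.4), c(0.05, 0.05)))
  expect_equal(p2$estimate, -0.3, tolerance = 1e-8)

  ## identical effects: zero heterogeneity, pooled = common value
  p3 <- pool_random_effects(eff(rep(-0.25, 4), c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(p3$tau2, 0, tolerance = 1e-10)
  expect_equal(p3$estimate, -0.25, tolerance = 1e-8)

  ## homogeneous effects with tau2 = 0: hand inverse-variance average
  y <- c(0.10, 0.12, 0.11, 0.09, 0.105)
  v <- c(0.04, 0.02, 0.03, 0.05, 0.025)
  p4 <- pool_random_effects(eff(y, v))
  expect_equal(p4$tau2, 0, tolerance = 1e-10)
  expect_equal(p4$estimate, sum(y / v) / sum(1 / v), tolerance = 1e-8)
  expect_equal(p4$se, sqrt(1 / sum(1 / v)), tolerance = 1e-8)

  ## with tau2 = 0 the pooled value lies within the inputs' range
  expect_true(p4$estimate >= min(y) && p4$estimate <= max(y))
  ## empty input: empty result
  expect_equal(nrow(pool_random_effects(eff(NA_real_, NA_real_))), 0)
})

test_that("gear subgroups partition the effects and pool independently", {
  study <- tiny_study(seed = 21)
  ind <- study_indicators(study$samples, study$stations, study$traits)
  trawl <- study$stations[study$stations$pressure_type == "trawling", ]
  meta <- meta_sensitivity(ind[ind$gradient_id %in% trawl$gradient_id, ],
                           trawl)
  eff <- meta$effects
  by_gear <- split(eff, eff$gear)
  expect_equal(sum(purrr::map_int(by_gear, nrow)), nrow(eff))
  ## subgroup k never exceeds the overall k
  pooled <- meta$pooled
  for (id in unique(pooled$indicator)) {
    k_all <- pooled$k[pooled$indicator == id & pooled$subgroup == "all"]
    k_sub <- pooled$k[pooled$indicator == id & pooled$subgroup != "all"]
    if (length(k_all) == 1 && length(k_sub) > 0) {
      expect_equal(sum(k_sub), k_all)
    }
  }
  expect_s3_class(tidy(meta), "tbl_df")
  expect_equal(glance(meta)$n_gradients, length(meta$contrasts))
})
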