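# Closed-form checks of the indicator suite on hand-constructed
# communities, plus the structural invariants (permutation, scaling,
# monotone mass transfer, range).

full_traits <- function(taxa, n = length(taxa)) {
  make_traits(taxa, group = "III", besito = 3, longevity = 5, score = 6,
              mass = 1)
}

test_that("whole-community and diversity indices match closed forms", {
  ## uniform 4-taxon community
  comm <- make_community("s1", paste0("t", 1:4), abundance = rep(25, 4),
                         biomass = rep(2, 4))
  ind <- compute_indicators(comm, full_traits(paste0("t", 1:4)))
  expect_equal(ival(ind, "A"), 100, tolerance = 1e-12)
  expect_equal(ival(ind, "B"), 8, tolerance = 1e-12)
  expect_equal(ival(ind, "R"), 4, tolerance = 1e-12)
  expect_equal(ival(ind, "H"), log(4), tolerance = 1e-10)
  expect_equal(ival(ind, "SI"), 0.25, tolerance = 1e-10)
  expect_equal(ival(ind, "IS"), 4, tolerance = 1e-10)

  ## monoculture
  mono <- make_community("s1", "t1", abundance = 10)
  ind_m <- compute_indicators(mono, full_traits("t1"))
  expect_equal(ival(ind_m, "H"), 0, tolerance = 1e-12)
  expect_equal(ival(ind_m, "SI"), 1, tolerance = 1e-12)
  expect_equal(ival(ind_m, "IS"), 1, tolerance = 1e-12)

  ## skewed abundances: hand-computed -sum(p log p)
  sk <- make_community("s1", c("a", "b", "c"), abundance = c(50, 30, 20))
  ind_s <- compute_indicators(sk, full_traits(c("a", "b", "c")))
  expect_equal(ival(ind_s, "H"),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-10)

  ## Margalef with explicit reference: DM = (R-1)/ln(A), scaled and capped
  refs <- list(r_ref = 3, h_ref = log(3), d_ref = 2 / log(100),
               ambi_good = 0)
  ind_r <- compute_indicators(sk, full_traits(c("a", "b", "c")), refs)
  expect_equal(ival(ind_r, "DM"), 1, tolerance = 1e-10)   # at reference
})

test_that("degenerate stations are flagged, not computed", {
  one <- make_community("s1", "t1", abundance = 1)
  ind <- compute_indicators(one, full_traits("t1"))
  expect_true(is.na(ival(ind, "DM")))       # A = 1: Margalef undefined
  expect_equal(ireason(ind, "DM"), "degenerate")
  expect_true(is.na(ival(ind, "B")))
  expect_equal(ireason(ind, "B"), "no_biomass")
})

test_that("AMBI and BENTIX hit their boundary and mixture values", {
  taxa <- c("a", "b")
  mk <- function(groups, ab = c(50, 50)) {
    comm <- make_community("s1", taxa, abundance = ab)
    traits <- make_traits(taxa, group = groups)
    compute_indicators(comm, traits)
  }
  all_I <- mk(c("I", "I"))
  expect_equal(ival(all_I, "AMBI"), 0, tolerance = 1e-10)
  expect_equal(ival(all_I, "BENTIX"), 6, tolerance = 1e-10)
  all_V <- mk(c("V", "V"))
  expect_equal(ival(all_V, "AMBI"), 6, tolerance = 1e-10)
  expect_equal(ival(all_V, "BENTIX"), 2, tolerance = 1e-10)
  half <- mk(c("I", "III"))
  expect_equal(ival(half, "AMBI"), 1.5, tolerance = 1e-10)
  expect_equal(ival(half, "BENTIX"), 4, tolerance = 1e-10)
})

test_that("group coverage below threshold yields missing with reason", {
  comm <- make_community("s1", c("a", "b"), abundance = c(30, 70))
  traits <- make_traits(c("a", "b"), group = c("I", NA))  # 30% coverage
  ind <- compute_indicators(comm, traits)
  expect_true(is.na(ival(ind, "AMBI")))
  expect_equal(ireason(ind, "AMBI"), "coverage")
})

test_that("M-AMBI is the anchored projection and DKI the AMBI/Shannon blend", {
  refs <- list(r_ref = 20, h_ref = 2, d_ref = 5, ambi_good = 0)
  ## independent 3-vector geometry oracle: projection coefficient of the
  ## standardized station vector u on the segment from (0,0,0) to (1,1,1)
  proj <- function(u) sum(u * rep(1, 3)) / sum(rep(1, 3)^2)
  mambi_oracle <- function(ambi, H, R) {
    u <- c((6 - ambi) / 6, H / refs$h_ref, R / refs$r_ref)
    min(1, max(0, proj(u)))
  }

  mk_station <- function(groups, ab) {
    comm <- make_community("s1", paste0("t", seq_along(ab)), abundance = ab)
    traits <- make_traits(paste0("t", seq_along(ab)), group = groups)
    compute_indicators(comm, traits, refs)
  }
  ## 20 equally-abundant group-III taxa: AMBI = 3, H = ln 20, R = 20
  ind <- mk_station(rep("III", 20), rep(5, 20))
  expect_equal(ival(ind, "MAMBI"), mambi_oracle(3, log(20), 20),
               tolerance = 1e-10)
  ## clipped at the high anchor and zero at the bad anchor by construction
  expect_equal(mambi_oracle(0, 2, 20), 1)
  expect_equal(mambi_oracle(6, 0, 0), 0)
  ## exact midpoint of the standardized segment
  expect_equal(mambi_oracle(3, 1, 10), 0.5, tolerance = 1e-12)

  ## DKI = 0.5 * ((1 - AMBI/7) + H/H_ref); worst corner gives 1/14
  expect_equal(ival(ind, "DKI"), 0.5 * ((1 - 3 / 7) + log(20) / 2),
               tolerance = 1e-10)
  mono <- make_community("s1", "t1", abundance = 10)
  ind_m <- compute_indicators(mono, make_traits("t1", group = "V"), refs)
  expect_equal(ival(ind_m, "DKI"), 0.5 * (1 - 6 / 7), tolerance = 1e-10)
})

test_that("TDI family matches the weighting closed forms", {
  ## two species, equal abundance, scores 1 and 3 -> mTDI = 2
  comm <- make_community("s1", c("a", "b"), abundance = c(10, 10))
  traits <- make_traits(c("a", "b"), score = c(1, 3))
  ind <- compute_indicators(comm, traits)
  expect_equal(ival(ind, "mTDI"), 2, tolerance = 1e-10)

  ## log weighting: abundances 1 and e-1 give ln-weights ln 2 and 1
  comm2 <- make_community("s1", c("a", "b"), abundance = c(1, exp(1) - 1))
  traits2 <- make_traits(c("a", "b"), score = c(0, 15))
  ind2 <- compute_indicators(comm2, traits2)
  expect_equal(ival(ind2, "TDI"), 15 * 1 / (1 + log(2)), tolerance = 1e-10)

  ## single species, score 9: TDI = mTDI = 9, and the analysis-scale
  ## (reversed) mT equals 9 too when nothing is protected
  comm3 <- make_community("s1", "a", abundance = 5)
  traits3 <- make_traits("a", score = 9)
  ind3 <- compute_indicators(comm3, traits3)
  expect_equal(ival(ind3, "TDI"), 9, tolerance = 1e-10)
  expect_equal(ival(ind3, "mTDI"), 9, tolerance = 1e-10)
  rev3 <- apply_reversal(ind3)
  expect_equal(ival(rev3, "mT"), 9, tolerance = 1e-10)

  ## protected taxa raise the analysis-scale mT by their weighted share
  traits4 <- make_traits(c("a", "b"), score = c(9, 9),
                         protected = c(TRUE, FALSE))
  ind4 <- apply_reversal(compute_indicators(
    make_community("s1", c("a", "b"), abundance = c(10, 30)), traits4))
  expect_equal(ival(ind4, "mT"), 9 + 0.25, tolerance = 1e-10)
})

test_that("sensitive-fraction and longevity indices follow the biomass rules", {
  taxa <- c("sens", "tol")
  comm <- make_community("s1", taxa, abundance = c(5, 5),
                         biomass = c(3, 9))
  traits <- make_traits(taxa, besito = c(5, 1), longevity = c(12, 2),
                        score = c(12, 3))
  ind <- compute_indicators(comm, traits)
  expect_equal(ival(ind, "SoS"), 0.25, tolerance = 1e-10)  # 3 g of 12 g
  expect_equal(ival(ind, "Lf"), 0.25, tolerance = 1e-10)   # longevity > 10

  ## boundaries
  all_sens <- compute_indicators(
    make_community("s1", taxa, c(5, 5), biomass = c(3, 9)),
    make_traits(taxa, besito = 5, longevity = 12, score = 12))
  expect_equal(ival(all_sens, "SoS"), 1, tolerance = 1e-12)
  expect_equal(ival(all_sens, "Lf"), 1, tolerance = 1e-12)
  none <- compute_indicators(
    make_community("s1", taxa, c(5, 5), biomass = c(3, 9)),
    make_traits(taxa, besito = 1, longevity = 2, score = 1))
  expect_equal(ival(none, "SoS"), 0, tolerance = 1e-12)
  expect_equal(ival(none, "Lf"), 0, tolerance = 1e-12)

  ## non-trawl pressures switch SoS to the ecological groups
  tr_grp <- make_traits(taxa, group = c("I", "IV"), longevity = c(12, 2))
  ind_nt <- compute_indicators(
    make_community("s1", taxa, c(5, 5), biomass = c(3, 9)), tr_grp,
    pressure_type = "pollution")
  expect_equal(ival(ind_nt, "SoS"), 0.25, tolerance = 1e-10)

  ## BESITO missing entirely -> longevity fallback drives SoS
  tr_fall <- make_traits(taxa, longevity = c(12, 2))
  ind_f <- compute_indicators(
    make_community("s1", taxa, c(5, 5), biomass = c(6, 6)), tr_fall)
  expect_equal(ival(ind_f, "SoS"), 0.5, tolerance = 1e-10)
})

test_that("median longevity walks the cumulative biomass curve", {
  taxa <- c("short", "long")
  mk <- function(bm) compute_indicators(
    make_community("s1", taxa, c(5, 5), biomass = bm),
    make_traits(taxa, longevity = c(2, 12)))
  expect_equal(ival(mk(c(6, 4)), "Lm"), 2)    # 60/40: median in short class
  expect_equal(ival(mk(c(5, 5)), "Lm"), 2)    # tie: first to reach 0.5
  expect_equal(ival(mk(c(4, 6)), "Lm"), 12)
  all5 <- compute_indicators(
    make_community("s1", "x", 5, biomass = 10),
    make_traits("x", longevity = 5))
  expect_equal(ival(all5, "Lm"), 5)
})

test_that("orientation reversal is an involution with the right endpoints", {
  expect_equal(reverse_orientation(0, 6), 6)
  expect_equal(reverse_orientation(6, 6), 0)
  expect_equal(reverse_orientation(2, 6), 4)
  v <- c(0.3, 2.2, 5.9)
  expect_equal(reverse_orientation(reverse_orientation(v, 6), 6), v)
})

test_that("indicator invariants hold on random communities", {
  set.seed(5)
  taxa <- paste0("t", 1:12)
  traits <- make_traits(taxa,
                        group = sample(c("I", "II", "III", "IV", "V"), 12,
                                       replace = TRUE),
                        besito = sample(1:5, 12, replace = TRUE),
                        longevity = runif(12, 1, 20),
                        score = sample(0:15, 12, replace = TRUE))
  refs <- list(r_ref = 12, h_ref = log(12), d_ref = 5, ambi_good = 0)
  for (rep in 1:5) {
    ab <- rpois(12, 20) + 1
    bm <- ab * runif(12, 0.1, 2)
    comm <- make_community("s1", taxa, ab, biomass = bm)
    ind <- compute_indicators(comm, traits, refs)

    ## ranges
    expect_true(all(ival(ind, c("SoS")) >= 0 & ival(ind, "SoS") <= 1))
    expect_true(ival(ind, "Lf") >= 0 && ival(ind, "Lf") <= 1)
    expect_true(ival(ind, "pTDI") >= 0 && ival(ind, "pTDI") <= 1)
    expect_true(ival(ind, "MAMBI") >= 0 && ival(ind, "MAMBI") <= 1)
    expect_true(ival(ind, "AMBI") >= 0 && ival(ind, "AMBI") <= 6)
    expect_true(ival(ind, "BENTIX") >= 2 && ival(ind, "BENTIX") <= 6)
    expect_true(ival(ind, "IS") >= 1 && ival(ind, "IS") <= ival(ind, "R"))

    ## permutation invariance
    perm <- sample(12)
    comm_p <- make_community("s1", taxa[perm], ab[perm], biomass = bm[perm])
    ind_p <- compute_indicators(comm_p, traits, refs)
    expect_equal(ind_p$value, ind$value, tolerance = 1e-12)

    ## doubling abundances and biomass: composition-based indices fixed,
    ## totals double
    comm_d <- make_community("s1", taxa, 2 * ab, biomass = 2 * bm)
    ind_d <- compute_indicators(comm_d, traits, refs)
    for (id in c("H", "SI", "IS", "AMBI", "BENTIX", "mTDI", "SoS", "Lf",
                 "Lm")) {
      expect_equal(ival(ind_d, id), ival(ind, id), tolerance = 1e-10)
    }
    expect_equal(ival(ind_d, "A"), 2 * ival(ind, "A"))
    expect_equal(ival(ind_d, "B"), 2 * ival(ind, "B"))
  }
})

test_that("AMBI is monotone under mass transfer from group I to group V", {
  taxa <- c("gI", "gV", "gIII")
  traits <- make_traits(taxa, group = c("I", "V", "III"))
  prev <- -Inf
  for (shift in seq(0, 40, by = 10)) {
    comm <- make_community("s1", taxa, c(50 - shift, 10 + shift, 20))
    v <- ival(compute_indicators(comm, traits), "AMBI")
    expect_gte(v, prev)
    prev <- v
  }
})

test_that("reference conditions come from the low-pressure subset", {
  study <- tiny_study(seed = 7, n_trawl = 1)
  s <- study$samples[study$samples$gradient_id == "tg01", ]
  st <- study$stations[study$stations$gradient_id == "tg01", ]
  comm <- aggregate_replicates(s)
  refs <- reference_conditions(comm, st, study$traits)
  low_ids <- st$station_id[st$pressure_value < 0.35]
  base_R <- comm |>
    dplyr::filter(station_id %in% low_ids) |>
    dplyr::group_by(station_id) |>
    dplyr::summarise(R = sum(abundance > 0))
  expect_equal(refs$r_ref, max(base_R$R))
  expect_equal(refs$n_reference, length(low_ids))
})
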