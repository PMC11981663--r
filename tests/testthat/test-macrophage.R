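test_that("sub-population decomposition conserves activated macrophages", {
  tr <- ref_sim(horizon = 40, grid_step = 0.1)
  dec <- decompose_activation(tr)
  d <- dec$trajectories
  total <- d$Ma_damp + d$Ma_antigen + d$Ma_cd40
  scale <- pmax(d$M_a, 1)
  expect_lt(max(abs(total - d$M_a) / scale), 1e-4)
  expect_equal(sum(dec$summary$fraction), 1, tolerance = 1e-9)
  expect_true(all(dec$summary$fraction >= 0))
})

test_that("conservation holds across random parameter draws", {
  for (k in 1:8) {
    sp <- sample_patient_params(patient_archetype("responder_cr"), 500 + k)
    tr <- simulate_therapy(sp$p, sp$q, sp$init, sp$regimen, horizon = 45,
                           grid_step = 0.2)
    dec <- decompose_activation(tr)
    d <- dec$trajectories
    dev <- abs(d$Ma_damp + d$Ma_antigen + d$Ma_cd40 - d$M_a) /
      pmax(d$M_a, 1)
    expect_lt(max(dev), 1e-4)
  }
})

test_that("mechanisms switched off leave their sub-population empty", {
  q <- ref_cytokine_params(beta_B = 0, beta_C = 0)
  tr <- simulate_therapy(ref_cart_params(), q, ref_init(),
                         dose_regimen(0, 1e8), horizon = 30,
                         grid_step = 0.1)
  dec <- decompose_activation(tr)
  expect_equal(max(dec$trajectories$Ma_antigen), 0)
  expect_equal(max(dec$trajectories$Ma_cd40), 0)
  expect_equal(dec$summary$fraction[dec$summary$mechanism == "damp"], 1)
  # zeroed mechanisms drop out of the timeline, flagged
  tl <- activation_timeline(dec, tr)
  expect_false(any(grepl("antigen|cd40", tl$event)))
  expect_setequal(attr(tl, "excluded"), c("antigen", "cd40"))
})

test_that("cumulative integrals match direct quadrature with beta_C = 0", {
  # with the CD40 feedback off, activation fractions equal the
  # time-integral ratio of h_1 M_i vs h_2 M_i computed independently
  q <- ref_cytokine_params(beta_C = 0)
  p <- ref_cart_params()
  tr <- simulate_therapy(p, q, ref_init(), dose_regimen(0, 1e8),
                         horizon = 30, grid_step = 0.05)
  dec <- decompose_activation(tr)
  d <- tr$data
  h1 <- q$beta_K * d$C_E / (p$B + d$C_E) * (d$T_P + p$g0 * d$T_N)
  h2 <- q$beta_B * d$T_P / (p$A + d$T_P) * d$C_E
  trap <- function(y) sum(diff(d$time) * (head(y, -1) + y[-1]) / 2)
  i1 <- trap(h1 * d$M_i); i2 <- trap(h2 * d$M_i)
  fr <- dec$summary$fraction
  expect_equal(fr[dec$summary$mechanism == "damp"], i1 / (i1 + i2),
               tolerance = 1e-3)
  expect_equal(fr[dec$summary$mechanism == "antigen"], i2 / (i1 + i2),
               tolerance = 1e-3)
})

test_that("CD40 alone cannot move IL-6 off baseline", {
  q <- ref_cytokine_params()
  init <- ref_init(M_i = q$sigma_M / q$delta_M, M_a = 0,
                   IL6 = q$sigma_I / q$delta_I)
  tr <- single_mechanism_simulation(ref_cart_params(), q, init,
                                    dose_regimen(0, 1e8),
                                    mechanisms = "cd40", horizon = 30,
                                    grid_step = 0.1)
  expect_lt(diff(range(tr$data$IL6)) / tr$data$IL6[1], 1e-6)
  # the full subset reproduces the unrestricted simulation
  tr_all <- single_mechanism_simulation(
    ref_cart_params(), q, init, dose_regimen(0, 1e8),
    mechanisms = c("damp", "antigen", "cd40"), horizon = 30,
    grid_step = 0.1)
  tr_ref <- simulate_therapy(ref_cart_params(), q, init,
                             dose_regimen(0, 1e8), horizon = 30,
                             grid_step = 0.1)
  expect_equal(tr_all$data$IL6, tr_ref$data$IL6)
})

test_that("DAMP-only IL-6 peaks during tumour shrinkage", {
  q <- ref_cytokine_params(beta_K = 2e-10)
  init <- ref_init()
  tr <- single_mechanism_simulation(ref_cart_params(), q, init,
                                    dose_regimen(0, 1e8),
                                    mechanisms = "damp", horizon = 60,
                                    grid_step = 0.1)
  seg <- segment_phases(tr)
  shr <- seg[seg$phase == "shrinkage", ]
  il6_day <- tr$data$time[which.max(tr$data$IL6)]
  expect_gte(il6_day, shr$t_start)
  # allow the IL-6 decay timescale after the activation pulse
  expect_lte(il6_day, shr$t_end + 2)
})

test_that("peak ordering is DAMP, antigen, CD40 with CD40 dominance", {
  # structure with small DAMP/antigen triggers and a dominant CD40 axis
  for (k in 1:4) {
    sp <- sample_patient_params(patient_archetype("high_crs"), 700 + k)
    tr <- simulate_therapy(sp$p, sp$q, sp$init, sp$regimen, horizon = 60,
                           grid_step = 0.1)
    dec <- decompose_activation(tr)
    s <- dec$summary
    pk <- setNames(s$peak_day, s$mechanism)
    expect_lte(pk[["damp"]], pk[["antigen"]])
    expect_lte(pk[["antigen"]], pk[["cd40"]])
  }
})

test_that("raising beta_C raises the CD40 share and the IL-6 peak", {
  p <- ref_cart_params()
  fr <- peak <- numeric(0)
  for (bc in c(2e-9, 8e-9, 3e-8)) {
    q <- ref_cytokine_params(beta_C = bc)
    tr <- simulate_therapy(p, q, ref_init(), dose_regimen(0, 1e8),
                           horizon = 40, grid_step = 0.1)
    dec <- decompose_activation(tr)
    fr <- c(fr, dec$summary$fraction[dec$summary$mechanism == "cd40"])
    peak <- c(peak, max(tr$data$IL6))
  }
  expect_true(all(diff(fr) >= 0))
  expect_true(all(diff(peak) >= 0))
})
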