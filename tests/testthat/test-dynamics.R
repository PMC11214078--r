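test_that("phosphorylated fraction follows the Hill curve", {
  expect_equal(phospho_fraction(0, 1, 2), 0)
  expect_equal(phospho_fraction(1, 1, 4), 0.5)    # half-saturation at K_c
  expect_equal(phospho_fraction(2, 1, 2), 0.8)    # 4 / (1 + 4)
  x <- seq(0, 5, by = 0.1)
  expect_true(all(diff(phospho_fraction(x, 0.7, 3)) >= 0))  # monotone
  expect_error(phospho_fraction(1, 0, 2), "K_c")
  expect_error(phospho_fraction(-1, 1, 2), "cuc")
})

test_that("up-the-gradient weights normalize and respond as specified", {
  expect_equal(utg_weights(c(2, 2, 2), kappa = 3), rep(1 / 3, 3))
  expect_equal(utg_weights(c(0, log(3)), kappa = 1), c(0.25, 0.75))
  expect_equal(utg_weights(c(0.3, 9, 2.2), kappa = 0), rep(1 / 3, 3))
  # power form is invariant to rescaling all concentrations
  a <- c(0.2, 0.5, 1.1, 0.05)
  expect_equal(utg_weights(a, 2, form = "power"),
               utg_weights(10 * a, 2, form = "power"))
  expect_equal(sum(utg_weights(runif(4), 5, form = "power")), 1)
  expect_error(utg_weights(numeric(0), 1), "neighbor")
  expect_error(utg_weights(c(1, 2), -1), "kappa")
})

test_that("with-the-flux weights rectify, normalize, and fall back to uniform", {
  expect_equal(wtf_weights(c(-1, -0.2, 0), 2, beta = 0.5), rep(1 / 3, 3))
  expect_equal(wtf_weights(c(1, 0), 2, beta = 1), c(2 / 3, 1 / 3))
  expect_equal(wtf_weights(c(0.7, 0.7), 2, beta = 0.1), c(0.5, 0.5))
  expect_error(wtf_weights(c(1, 2), 2, beta = 0), "beta")
})

test_that("edge flux is antisymmetric and scales with efficiency", {
  expect_equal(edge_flux(1, 1, 0.3, 0.3, T_rate = 2), 0)
  expect_equal(edge_flux(2, 0, 1, 1, T_rate = 1), 2)
  for (k in 1:20) {
    a <- runif(2); P <- runif(2); e <- 1 + runif(2)
    expect_equal(edge_flux(a[1], a[2], P[1], P[2], 1.3, e[1], e[2]),
                 -edge_flux(a[2], a[1], P[2], P[1], 1.3, e[2], e[1]))
  }
  # efficiency multiplies the effluxing cell's own term
  expect_equal(edge_flux(2, 0, 1, 1, 1, eff_i = 3), 6)
})

test_that("target allocation mixes UTG and WTF by the phosphorylated fraction", {
  tpl <- make_template("wt", n_rows = 5, n_cols = 3, prox_start_row = 2,
                       prox_ramp_rows = 1, cuc_max = 2)
  p <- margin_params("pmm", rho = 1)
  st <- init_state(tpl, p)
  st$auxin <- seq(0.1, 1.5, length.out = tpl$tissue$n_cells)
  tg <- target_allocation(st, tpl$tissue, p)
  expect_equal(rowSums(tg), rep(p$P_tot, tpl$tissue$n_cells))
  # recompose one cell's target from the exported weight functions
  tis <- tpl$tissue
  i <- marginpin:::.cell_id(tis, 3, 2)
  phi_i <- phospho_fraction(tis$cuc[i], p$K_c, p$h_c)
  ex <- which(!is.na(tis$nb[i, ]))
  w_utg <- utg_weights(st$auxin[tis$nb[i, ex]], p$kappa, form = p$utg_form)
  J <- marginpin:::.flux_matrix(st$auxin, st$pin, st$phi, tis, p)
  a_nb <- st$auxin[tis$nb[i, ex]]
  J_sense <- J[i, ex] + p$D * (st$auxin[i] - a_nb)
  w_wtf <- wtf_weights(J_sense, p$wtf_exponent, p$beta)
  expect_equal(unname(tg[i, ex]),
               unname(p$P_tot * ((1 - phi_i) * w_utg + phi_i * w_wtf)),
               tolerance = 1e-12)
  # phi = 0 under the PMM reduces to the UTG-only targets
  mut <- make_template("cuc_mutant", n_rows = 5, n_cols = 3,
                       prox_start_row = 2, prox_ramp_rows = 1)
  st0 <- init_state(mut, p)
  st0$auxin <- st$auxin
  p_utg <- margin_params("utg_only", rho = 1)
  expect_equal(target_allocation(st0, mut$tissue, p),
               target_allocation(st0, mut$tissue, p_utg))
})

test_that("a symmetric closed state is a fixed point of the auxin update", {
  tpl <- make_template("cuc_mutant", n_rows = 3, n_cols = 3,
                       prox_start_row = 1, prox_ramp_rows = 1)
  p <- margin_params("utg_only", sigma_src = 0, sigma_bg = 0, mu_a = 0,
                     rho = 0, dt = 0.05)
  st <- init_state(tpl, p)
  st$auxin <- rep(0.7, 9)
  st$pin <- matrix(0.2, 9, 4, dimnames = list(NULL, colnames(st$pin)))
  st$pin[is.na(tpl$tissue$nb)] <- 0   # symmetric allocation on existing edges
  st2 <- sim_step(st, tpl$tissue, p)
  expect_equal(st2$auxin, st$auxin)
  expect_equal(attr(st2, "residual"), 0)
})

test_that("closed systems conserve total auxin to machine precision", {
  tpl <- make_template("wt", n_rows = 6, n_cols = 5)
  p <- margin_params("pmm", sigma_src = 0, sigma_bg = 0, mu_a = 0, dt = 0.05)
  tis <- tpl$tissue
  set.seed(42)
  for (rep in 1:5) {
    st <- init_state(tpl, p)
    st$auxin <- runif(tis$n_cells, 0.1, 2)
    w <- matrix(runif(tis$n_cells * 4), tis$n_cells, 4)
    w[is.na(tis$nb)] <- 0
    st$pin <- p$P_tot * w / rowSums(w)
    colnames(st$pin) <- colnames(tis$nb)
    total0 <- sum(st$auxin)
    for (k in 1:50) st <- sim_step(st, tis, p)
    expect_lt(abs(sum(st$auxin) - total0), 1e-10 * total0 * 50)
  }
})

test_that("the stability guard rejects too-large steps and states stay finite", {
  expect_error(margin_params("emm", dt = 0.5, epsilon = 3), "stability guard")
  tpl <- make_template("wt", n_rows = 4, n_cols = 3, prox_start_row = 2,
                       prox_ramp_rows = 1)
  p <- margin_params("pmm")
  st <- init_state(tpl, p)
  st$auxin[1] <- Inf
  expect_error(sim_step(st, tpl$tissue, p), "non-finite")
})

test_that("steady-state runs converge, conserve allocation, and avoid clamps", {
  sim <- cached_sim("pmm")
  expect_true(sim$converged)
  expect_lt(sim$residual, sim$params$tol_ss)
  expect_equal(sim$final_state$clamp_count, 0L)
  expect_equal(rowSums(sim$final_state$pin),
               rep(sim$params$P_tot, sim$tissue$n_cells),
               tolerance = 1e-8)
  expect_true(all(sim$final_state$auxin >= 0))
})

test_that("steady state of a mirror-symmetric template is mirror-symmetric", {
  sim <- cached_sim("pmm")
  tis <- sim$tissue
  refl <- marginpin:::.cell_id(tis, tis$row, tis$n_cols + 1 - tis$col)
  expect_equal(sim$final_state$auxin, sim$final_state$auxin[refl],
               tolerance = 1e-6)
  # left/right membrane allocations swap under reflection
  expect_equal(sim$final_state$pin[, "left"],
               sim$final_state$pin[refl, "right"], tolerance = 1e-6)
})

test_that("model variants collapse to the UTG control in their limits", {
  # EMM with epsilon = 1 is arithmetically identical to utg_only
  sim_u <- cached_sim("utg_only")
  sim_e1 <- run_to_steady_state(make_template("wt"),
                                margin_params("emm", epsilon = 1))
  expect_equal(sim_e1$final_state$auxin, sim_u$final_state$auxin,
               tolerance = 1e-12)
  expect_equal(sim_e1$final_state$pin, sim_u$final_state$pin,
               tolerance = 1e-12)
  # cuc_max = 0 makes PMM and EMM agree with the control
  for (v in c("pmm", "emm")) {
    sim_m <- cached_sim(v, "cuc_mutant")
    sim_mu <- cached_sim("utg_only", "cuc_mutant")
    expect_equal(sim_m$final_state$auxin, sim_mu$final_state$auxin,
                 tolerance = 1e-10)
  }
})

test_that("the UTG control polarizes every middle-column cell apically", {
  rep_u <- pattern_report(cached_sim("utg_only"))
  expect_equal(rep_u$apical_below_fraction, 1)
  expect_true(rep_u$monotone_below_source)
  expect_equal(nrow(rep_u$peaks), 0)
})

test_that("fixed-PIN steady state matches the direct linear solve (1x3)", {
  tpl <- make_template("cuc_mutant", n_rows = 3, n_cols = 1, md_width = 1,
                       prox_start_row = 1, prox_ramp_rows = 1,
                       init_pin = "uniform")
  p <- margin_params("utg_only", rho = 0, sigma_bg = 0.01, mu_a = 0.05,
                     D = 0.1, T_rate = 0.4, dt = 0.05, tol_ss = 1e-10,
                     t_max = 5000)
  sim <- run_to_steady_state(tpl, p)
  expect_true(sim$converged)
  oracle <- linear_steady_auxin(tpl$tissue, init_state(tpl, p)$pin, p)
  expect_equal(sim$final_state$auxin, oracle, tolerance = 1e-6)
})

test_that("simulation state exports carry the documented columns", {
  sim <- cached_sim("pmm")
  df <- export_state(sim)
  expect_equal(names(df), c("row", "col", "auxin", "phospho_fraction",
                            "pin_up", "pin_down", "pin_left", "pin_right"))
  expect_equal(nrow(df), 100)
  f <- tempfile(fileext = ".csv")
  export_state(sim, f)
  expect_equal(read.csv(f)$auxin, df$auxin)
})
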