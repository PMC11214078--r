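# Core PIN-auxin dynamics on the margin grid.
#
# Per-cell auxin a_i obeys
#   da_i/dt = sigma_src 1(source) + sigma_bg - mu_a a_i
#             + D sum_j (a_j - a_i) - sum_j J_ij
# with PIN-mediated net flux J_ij = T (eff_i P_ij a_i - eff_j P_ji a_j),
# eff = 1 + (epsilon - 1) phi under the EMM and 1 otherwise. PIN allocation
# relaxes at rate rho toward rule-dependent targets that always sum to P_tot.
# Integration is explicit fixed-step with a stability guard (see
# margin_params); the tissue boundary is closed (no ghost cells), so with
# production and decay off total auxin is conserved exactly.

#' Phosphorylated PIN fraction as a Hill function of CUC
#'
#' phi = cuc^h / (K_c^h + cuc^h): monotone in CUC, 0 at cuc = 0, 1/2 at
#' cuc = K_c. CUC is a static input, so phosphorylation is treated at
#' quasi-equilibrium (no separate state variable).
#'
#' @param cuc CUC concentration(s), a.u. (>= 0).
#' @param K_c Half-saturation constant (> 0).
#' @param h_c Hill coefficient.
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' phospho_fraction(c(0, 1, 2), K_c = 1, h_c = 2)
#' @export
phospho_fraction <- function(cuc, K_c, h_c) {
  if (K_c <= 0) stop("K_c must be > 0")
  if (any(cuc < 0)) stop("cuc must be >= 0")
  ch <- cuc^h_c
  ch / (K_c^h_c + ch)
}

#' Up-the-gradient membrane weights
#'
#' Two response forms are available. `"softmax"` is exponential in absolute
#' neighbor auxin, w_j = exp(kappa a_j) / sum_k exp(kappa a_k). `"power"`
#' senses relative differences, w_j = a_j^kappa / sum_k a_k^kappa
#' (equivalently softmax in log-auxin); because it is invariant to rescaling
#' all concentrations, a geometric auxin profile polarizes every cell of a
#' file equally, which is what lets the whole margin column polarize toward
#' the distal maximum. The baseline model uses `"power"`; see the methods
#' vignette. kappa = 0 gives uniform weights under either form.
#'
#' @param neighbor_auxin Auxin concentrations of the neighbors (length >= 1).
#' @param kappa Sensitivity (>= 0): per a.u. for `"softmax"`, a
#'   dimensionless exponent for `"power"`.
#' @param form Response form, `"softmax"` (default) or `"power"`.
#' @return Normalized weights summing to 1.
#' @export
utg_weights <- function(neighbor_auxin, kappa, form = c("softmax", "power")) {
  form <- match.arg(form)
  if (length(neighbor_auxin) < 1) stop("at least one neighbor is required")
  if (kappa < 0) stop("kappa must be >= 0")
  if (form == "softmax") {
    e <- exp(kappa * (neighbor_auxin - max(neighbor_auxin)))
  } else {
    if (any(neighbor_auxin < 0)) stop("auxin must be >= 0")
    e <- (neighbor_auxin + 1e-12)^kappa
  }
  e / sum(e)
}

#' With-the-flux membrane weights
#'
#' Rectified power-law response with a baseline affinity:
#' w_j = (max(J_j, 0)^p + beta) / sum_k (...). When every flux is inward
#' (all J <= 0) the weights are uniform (beta-only limit).
#'
#' @param edge_fluxes Net efflux across each membrane (length >= 1).
#' @param wtf_exponent Flux-response exponent p.
#' @param beta Baseline affinity (> 0).
#' @return Normalized weights summing to 1.
#' @export
wtf_weights <- function(edge_fluxes, wtf_exponent, beta) {
  if (length(edge_fluxes) < 1) stop("at least one edge is required")
  if (beta <= 0) stop("beta must be > 0")
  w <- pmax(edge_fluxes, 0)^wtf_exponent + beta
  w / sum(w)
}

#' PIN-mediated net flux across one membrane
#'
#' J_ij = T (eff_i P_ij a_i - eff_j P_ji a_j); antisymmetric in (i, j).
#' The efficiency multiplier applies to each cell's own efflux term.
#'
#' @param a_i,a_j Auxin in cells i and j (a.u.).
#' @param P_ij,P_ji PIN allocated by i toward j and by j toward i.
#' @param T_rate Transport rate per PIN unit.
#' @param eff_i,eff_j Transport efficiencies (1 outside the EMM).
#' @return Net flux i -> j (a.u. / t).
#' @export
edge_flux <- function(a_i, a_j, P_ij, P_ji, T_rate, eff_i = 1, eff_j = 1) {
  T_rate * (eff_i * P_ij * a_i - eff_j * P_ji * a_j)
}

# --- vectorized internals ------------------------------------------------

# Gather a per-cell vector over the neighbor matrix; missing neighbors -> NA.
.nb_gather <- function(v, nb) {
  m <- matrix(NA_real_, nrow(nb), 4L, dimnames = dimnames(nb))
  ok <- !is.na(nb)
  m[ok] <- v[nb[ok]]
  m
}

# Per-cell transport efficiency vector.
.eff_vec <- function(phi, params) {
  if (params$variant == "emm") 1 + (params$epsilon - 1) * phi else rep(1, length(phi))
}

# PIN-mediated flux matrix J[i, d] = net efflux of cell i across membrane d.
.flux_matrix <- function(auxin, pin, phi, tissue, params) {
  nb <- tissue$nb
  eff <- .eff_vec(phi, params)
  a_nb <- .nb_gather(auxin, nb)
  eff_nb <- .nb_gather(eff, nb)
  # neighbor's allocation on the membrane facing back at i
  p_back <- matrix(NA_real_, tissue$n_cells, 4L)
  for (d in 1:4) {
    j <- nb[, d]
    ok <- !is.na(j)
    p_back[ok, d] <- pin[cbind(j[ok], .dir_opposite[d])]
  }
  J <- params$T_rate * (eff * pin * auxin - eff_nb * p_back * a_nb)
  J[is.na(nb)] <- 0
  J
}

# Target PIN allocation matrix (n_cells x 4), summing to P_tot per cell.
# a_nb and J may be supplied to avoid recomputation in the stepper.
.targets_matrix <- function(auxin, pin, phi, tissue, params,
                            a_nb = NULL, J = NULL) {
  nb <- tissue$nb
  exists_m <- !is.na(nb)
  if (is.null(a_nb)) a_nb <- .nb_gather(auxin, nb)
  # UTG over existing membranes (missing -> weight 0)
  if (identical(params$utg_form, "softmax")) {
    amax <- pmax(a_nb[, 1], a_nb[, 2], a_nb[, 3], a_nb[, 4], na.rm = TRUE)
    E <- exp(params$kappa * (a_nb - amax))
  } else {
    E <- (a_nb + 1e-12)^params$kappa
  }
  E[!exists_m] <- 0
  W_utg <- E / rowSums(E)
  if (params$variant == "pmm" && any(phi > 0)) {
    # WTF senses total net efflux: PIN-mediated plus passive diffusive
    # (the canalization assumption; see the methods vignette)
    if (is.null(J)) J <- .flux_matrix(auxin, pin, phi, tissue, params)
    Jd <- J + params$D * (auxin - a_nb)
    Jd[!exists_m] <- 0
    Wf <- pmax(Jd, 0)^params$wtf_exponent + params$beta
    Wf[!exists_m] <- 0
    W_wtf <- Wf / rowSums(Wf)
    tg <- params$P_tot * ((1 - phi) * W_utg + phi * W_wtf)
  } else {
    tg <- params$P_tot * W_utg
  }
  tg[!exists_m] <- 0
  tg
}

#' Target PIN allocation for cells of a state
#'
#' Computes, for every cell, the membrane allocation the polarization rule is
#' currently driving toward. Under the PMM the target is the phi-weighted
#' convex mix of up-the-gradient and with-the-flux weights; under the EMM and
#' the UTG-only control it is the pure up-the-gradient allocation. Rows sum
#' to `P_tot` exactly.
#'
#' @param state A `margin_state`.
#' @param tissue The `margin_tissue` the state lives on.
#' @param params A `margin_params`.
#' @return Matrix (n_cells x 4) of per-membrane targets, columns
#'   up/down/left/right.
#' @export
target_allocation <- function(state, tissue, params) {
  .targets_matrix(state$auxin, state$pin, state$phi, tissue, params)
}

#' Initialize a simulation state from a template
#'
#' @param template A `margin_template`.
#' @param params A `margin_params`.
#' @return A `margin_state`: per-cell `auxin`, allocation matrix `pin`
#'   (n_cells x 4, rows summing to `P_tot`), `phi`, and time `t`.
#' @export
init_state <- function(template, params) {
  stopifnot(inherits(template, "margin_template"),
            inherits(params, "margin_params"))
  tis <- template$tissue
  exists_m <- !is.na(tis$nb)
  deg <- rowSums(exists_m)
  pin <- matrix(0, tis$n_cells, 4L, dimnames = list(NULL, .dir_names))
  if (template$init_pin == "uniform") {
    pin[exists_m] <- (params$P_tot / deg)[row(pin)[exists_m]]
  } else { # apical: all PIN on the distal membrane where it exists
    up_ok <- exists_m[, "up"]
    pin[up_ok, "up"] <- params$P_tot
    pin[!up_ok, ][exists_m[!up_ok, , drop = FALSE]] <-
      (params$P_tot / deg[!up_ok])[row(pin[!up_ok, , drop = FALSE])[exists_m[!up_ok, , drop = FALSE]]]
  }
  structure(list(
    auxin = template$init_auxin,
    pin = pin,
    phi = phospho_fraction(tis$cuc, params$K_c, params$h_c),
    t = 0,
    clamp_count = 0L
  ), class = "margin_state")
}

#' Advance a state by one time step
#'
#' Explicit Euler update of auxin and relaxation of PIN toward the current
#' targets; phi is recomputed from the (static) CUC field. Negative values
#' produced by the update are clamped at 0 and counted in
#' `state$clamp_count` (zero on any run satisfying the stability guard with
#' baseline parameters).
#'
#' @param state A `margin_state`.
#' @param tissue The `margin_tissue`.
#' @param params A `margin_params`.
#' @return The updated state; attribute `"residual"` holds max |da/dt|.
#' @export
sim_step <- function(state, tissue, params) {
  a <- state$auxin
  if (any(!is.finite(a)) || any(!is.finite(state$pin)))
    stop("non-finite simulation state at t = ", format(state$t),
         " (max auxin ", format(max(a)), ")")
  phi <- phospho_fraction(tissue$cuc, params$K_c, params$h_c)
  a_nb <- .nb_gather(a, tissue$nb)
  J <- .flux_matrix(a, state$pin, phi, tissue, params)
  tg <- .targets_matrix(a, state$pin, phi, tissue, params,
                        a_nb = a_nb, J = J)
  diff_in <- params$D * rowSums(a_nb - a, na.rm = TRUE)
  dadt <- params$sigma_src * as.numeric(tissue$is_source) + params$sigma_bg -
    params$mu_a * a + diff_in - rowSums(J)
  a_new <- a + params$dt * dadt
  pin_new <- state$pin + params$dt * params$rho * (tg - state$pin)
  clamps <- sum(a_new < 0) + sum(pin_new < 0)
  if (clamps > 0) {
    a_new[a_new < 0] <- 0
    pin_new[pin_new < 0] <- 0
  }
  pin_new[is.na(tissue$nb)] <- 0
  out <- structure(list(
    auxin = a_new, pin = pin_new, phi = phi,
    t = state$t + params$dt,
    clamp_count = state$clamp_count + clamps
  ), class = "margin_state")
  attr(out, "residual") <- max(abs(dadt))
  attr(out, "pin_residual") <- params$rho * max(abs(tg - state$pin))
  out
}

#' Integrate a scenario to steady state
#'
#' Runs the explicit scheme until both max |da/dt| and the PIN reallocation
#' rate max |dP/dt| fall below `tol_ss`, or until `t_max`. Noise-free runs
#' are fully deterministic. With an auxin `noise` spec on a
#' resample-every-tau schedule, the state is perturbed multiplicatively
#' during integration and the run is scored at `t_max` (such runs normally
#' report `converged = FALSE`; they are evaluated on their final pattern).
#'
#' @param template A `margin_template`.
#' @param params A `margin_params`.
#' @param noise Optional `noise_spec` applied during the run (see
#'   [apply_noise()]); a CUC-targeted spec perturbs the template once before
#'   integration.
#' @param t_relax Extra noise-free relaxation time appended after a
#'   resample-schedule noise run (0 = none), letting the last perturbation
#'   settle before the state is scored.
#' @param save_trajectory Keep sampled intermediate states?
#' @param sample_every Sampling stride (steps) for the trajectory.
#' @return A `margin_sim` object: `final_state`, `converged`, `residual`,
#'   the tissue, params, and optionally `trajectory`.
#' @examples
#' \donttest{
#' sim <- run_to_steady_state(make_template("wt"), margin_params("pmm"))
#' summary(sim)
#' }
#' @export
run_to_steady_state <- function(template, params, noise = NULL, t_relax = 0,
                                save_trajectory = FALSE, sample_every = 50) {
  stopifnot(inherits(template, "margin_template"),
            inherits(params, "margin_params"))
  tissue <- template$tissue
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (!is.null(noise$seed)) set.seed(noise$seed)
    if (noise$target == "cuc") {
      tissue$cuc <- .perturb(tissue$cuc, noise$amplitude)
      template$tissue <- tissue
    }
  }
  state <- init_state(template, params)
  if (!is.null(noise) && noise$target == "auxin")
    state$auxin <- .perturb(state$auxin, noise$amplitude)
  n_steps <- ceiling(params$t_max / params$dt)
  noise_stride <- if (!is.null(noise) && noise$target == "auxin" &&
                      noise$schedule == "resample_every")
    max(1L, round(noise$tau / params$dt)) else NA_integer_
  traj <- if (save_trajectory) list(state) else NULL
  residual <- Inf; pin_res <- Inf
  converged <- FALSE
  for (k in seq_len(n_steps)) {
    state <- sim_step(state, tissue, params)
    residual <- attr(state, "residual")
    pin_res <- attr(state, "pin_residual")
    if (save_trajectory && k %% sample_every == 0)
      traj[[length(traj) + 1L]] <- state
    if (!is.na(noise_stride) && k %% noise_stride == 0L)
      state$auxin <- .perturb(state$auxin, noise$amplitude)
    if (is.na(noise_stride) && residual < params$tol_ss &&
        pin_res < params$tol_ss) {
      converged <- TRUE
      break
    }
  }
  if (!is.na(noise_stride) && t_relax > 0) {
    # let the last perturbation settle before the state is scored
    for (k in seq_len(ceiling(t_relax / params$dt))) {
      state <- sim_step(state, tissue, params)
      residual <- attr(state, "residual")
      pin_res <- attr(state, "pin_residual")
      if (residual < params$tol_ss && pin_res < params$tol_ss) {
        converged <- TRUE
        break
      }
    }
  }
  if (is.na(noise_stride) && !converged && residual < params$tol_ss &&
      pin_res < params$tol_ss)
    converged <- TRUE
  structure(list(
    final_state = state, converged = converged, residual = residual,
    pin_residual = pin_res, tissue = tissue, params = params,
    template_name = template$name, trajectory = traj
  ), class = "margin_sim")
}

#' @export
print.margin_sim <- function(x, ...) {
  cat("Margin patterning simulation (", x$params$variant, ", template '",
      x$template_name, "')\n", sep = "")
  cat("  t = ", format(x$final_state$t),
      "; converged: ", x$converged,
      "; residual max|da/dt| = ", format(x$residual, digits = 3), "\n",
      sep = "")
  cat("  auxin range: [", format(min(x$final_state$auxin), digits = 3), ", ",
      format(max(x$final_state$auxin), digits = 3), "]; clamps: ",
      x$final_state$clamp_count, "\n", sep = "")
  invisible(x)
}

#' @export
summary.margin_sim <- function(object, ...) {
  field <- net_polarity(object$final_state, object$tissue,
                        P_tot = object$params$P_tot)
  conv <- detect_convergences(field, object$tissue)
  prof <- column_profile(object$final_state, object$tissue,
                         object$tissue$mid_col)
  src_row <- unique(object$tissue$row[object$tissue$is_source])
  peaks <- detect_emergent_maxima(prof, source_row = src_row)
  out <- list(sim = object, polarity = field, convergences = conv,
              profile = prof, peaks = peaks,
              class_counts = table(field$class))
  class(out) <- "summary.margin_sim"
  out
}

#' @export
print.summary.margin_sim <- function(x, ...) {
  print(x$sim)
  cat("  polarity classes: ",
      paste(names(x$class_counts), x$class_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  convergences (row, col): ",
      if (nrow(x$convergences)) paste(sprintf("(%d,%d)", x$convergences$row,
                                              x$convergences$col),
                                      collapse = " ") else "none", "\n",
      sep = "")
  cat("  emergent auxin maxima on middle column: ",
      if (nrow(x$peaks)) paste(sprintf("row %d (%.3g a.u.)", x$peaks$row,
                                       x$peaks$amplitude), collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Export a simulation state as a per-cell table
#'
#' Columns `row,col,auxin,phospho_fraction,pin_up,pin_down,pin_left,pin_right`.
#'
#' @param sim A `margin_sim`.
#' @param path Optional CSV output path.
#' @return The data.frame (invisibly if `path` is given).
#' @export
export_state <- function(sim, path = NULL) {
  stopifnot(inherits(sim, "margin_sim"))
  s <- sim$final_state
  df <- data.frame(row = sim$tissue$row, col = sim$tissue$col,
                   auxin = s$auxin, phospho_fraction = s$phi,
                   pin_up = s$pin[, "up"], pin_down = s$pin[, "down"],
                   pin_left = s$pin[, "left"], pin_right = s$pin[, "right"])
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Heatmap of steady-state auxin with net-polarity arrows
#'
#' Base-graphics rendering in the style of the model output figures: auxin as
#' a cell heatmap, CUC band outline, and an arrow per cell along its net
#' PIN-mediated transport direction.
#'
#' @param x A `margin_sim`.
#' @param arrow_scale Arrow length per unit polarity magnitude (cell widths).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.margin_sim <- function(x, arrow_scale = 0.45, ...) {
  tis <- x$tissue
  a <- matrix(x$final_state$auxin, nrow = tis$n_cols)  # col-major by row
  z <- t(a)  # rows x cols
  graphics::image(x = seq_len(tis$n_rows), y = seq_len(tis$n_cols),
                  z = z, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "row (distal → proximal)", ylab = "column",
                  main = paste0("auxin (", x$params$variant, ")"), ...)
  field <- net_polarity(x$final_state, tis, P_tot = x$params$P_tot)
  mag <- field$magnitude / max(field$magnitude, 1e-12)
  ok <- mag > 0.05
  # plot x-axis = row, y-axis = col; distal (+y model axis) points to -x here
  graphics::arrows(tis$row[ok], tis$col[ok],
                   tis$row[ok] - arrow_scale * field$vy[ok] / x$params$P_tot,
                   tis$col[ok] + arrow_scale * field$vx[ok] / x$params$P_tot,
                   length = 0.04)
  band <- cuc_band_rows(tis)
  if (length(band))
    graphics::rect(min(band) - 0.5, tis$mid_col - 0.5, max(band) + 0.5,
                   tis$mid_col + 0.5, border = "cyan3", lwd = 2)
  src <- tis$is_source
  graphics::points(tis$row[src], tis$col[src], pch = 21, bg = "white")
  invisible(x)
}
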