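# Pattern analysis: polarity fields, convergence points, auxin profiles,
# emergent maxima, and noise-robustness ensembles.

#' Net polarity field of a simulation state
#'
#' The net polarity vector of a cell is the allocation-weighted sum of unit
#' vectors toward its neighbors, v_i = sum_j P_ij u_ij (x along columns, y
#' along the distal axis). Cells are classified as:
#' \itemize{
#'   \item \code{bipolar} — the strongest membrane and its opposite hold
#'     comparable PIN (within ratio `r_bi`) and that axis dominates the
#'     orthogonal one;
#'   \item \code{nonpolar} — |v| < `theta_np` * P_tot;
#'   \item \code{apical} / \code{basal} / \code{lateral} — 45-degree sector of
#'     v around the distal / proximal / column axis (sector boundaries are
#'     assigned to apical/basal).
#' }
#'
#' @param state A `margin_state`.
#' @param tissue The `margin_tissue`.
#' @param theta_np Nonpolar threshold as a fraction of `P_tot`.
#' @param r_bi Bipolar ratio threshold.
#' @param P_tot Total PIN per cell (defaults to the max row sum of the
#'   allocation, which equals P_tot at and near steady state).
#' @return A `polarity_field` data.frame: `row`, `col`, `vx`, `vy`,
#'   `magnitude`, `class`; attributes `P_tot` and `theta_np`.
#' @export
net_polarity <- function(state, tissue, theta_np = 0.1, r_bi = 1.5,
                         P_tot = NULL) {
  pin <- state$pin
  if (is.null(P_tot)) P_tot <- max(rowSums(pin))
  vx <- pin[, "right"] - pin[, "left"]
  vy <- pin[, "up"] - pin[, "down"]
  mag <- sqrt(vx^2 + vy^2)
  n <- nrow(pin)
  cls <- character(n)
  s_sorted_max <- max.col(pin, ties.method = "first")
  for (i in seq_len(n)) {
    p <- pin[i, ]
    d1 <- which.max(p)
    s1 <- p[d1]
    s_opp <- p[.dir_opposite[d1]]
    orth <- setdiff(1:4, c(d1, .dir_opposite[d1]))
    axis_mean <- (s1 + s_opp) / 2
    orth_mean <- (p[orth[1]] + p[orth[2]]) / 2
    if (s1 >= theta_np * P_tot && s_opp >= s1 / r_bi &&
        axis_mean >= r_bi * orth_mean) {
      cls[i] <- "bipolar"
    } else if (mag[i] < theta_np * P_tot) {
      cls[i] <- "nonpolar"
    } else if (vy[i] >= abs(vx[i])) {
      cls[i] <- "apical"
    } else if (-vy[i] >= abs(vx[i])) {
      cls[i] <- "basal"
    } else {
      cls[i] <- "lateral"
    }
  }
  out <- data.frame(row = tissue$row, col = tissue$col,
                    vx = vx, vy = vy, magnitude = mag,
                    class = factor(cls, levels = c("apical", "basal",
                                                   "lateral", "bipolar",
                                                   "nonpolar")))
  attr(out, "P_tot") <- P_tot
  attr(out, "theta_np") <- theta_np
  class(out) <- c("polarity_field", "data.frame")
  out
}

#' Detect polarity convergence points
#'
#' A cell is a convergence if at least `min(k_min, #neighbors)` of its
#' existing neighbors have a net polarity component toward it exceeding the
#' directional threshold, and the cell itself is not strongly polarized
#' toward any neighbor that does not point back at it (mutually pointing
#' pairs straddle an auxin maximum and belong to the same convergence, so
#' reciprocated pointing does not disqualify; one-way outflow marks a
#' pass-through cell and does). Boundary cells are evaluated over their
#' existing neighbors only, so the distal boundary cell of a uniformly
#' apical column qualifies (documented behavior) while interior pass-through
#' cells never do.
#'
#' @param field A `polarity_field` from [net_polarity()].
#' @param tissue The `margin_tissue`.
#' @param k_min Minimum number of inward-pointing neighbors (>= 2).
#' @param theta_pt Directional threshold on the dot product of a neighbor's
#'   polarity with the unit vector toward the cell; defaults to the field's
#'   `theta_np * P_tot`.
#' @return Data.frame of convergence cells (`row`, `col`, `cell`, `cluster`),
#'   sorted by row then column; `cluster` labels connected components of
#'   adjacent convergence cells (one physical convergence point can span a
#'   mutually pointing pair of cells).
#' @export
detect_convergences <- function(field, tissue, k_min = 2, theta_pt = NULL) {
  if (k_min < 2) stop("k_min must be >= 2")
  if (is.null(theta_pt))
    theta_pt <- attr(field, "theta_np") * attr(field, "P_tot")
  vx <- field$vx; vy <- field$vy
  nb <- tissue$nb
  n <- tissue$n_cells
  # toward[i, d]: cell i's polarity has a component > theta toward neighbor d
  hit <- logical(n)
  toward <- matrix(FALSE, n, 4L)
  for (d in 1:4)
    toward[, d] <- !is.na(nb[, d]) &
      (vx * .dir_ux[d] + vy * .dir_uy[d] > theta_pt)
  for (i in seq_len(n)) {
    js <- nb[i, ]
    ex <- which(!is.na(js))
    if (!length(ex)) next
    inward <- 0L
    self_out <- FALSE
    for (d in ex) {
      j <- js[d]
      points_back <- toward[j, .dir_opposite[d]]
      if (points_back) inward <- inward + 1L
      if (toward[i, d] && !points_back) self_out <- TRUE
    }
    hit[i] <- !self_out && inward >= min(k_min, length(ex))
  }
  idx <- which(hit)
  out <- data.frame(row = tissue$row[idx], col = tissue$col[idx], cell = idx)
  out <- out[order(out$row, out$col), , drop = FALSE]
  out$cluster <- .cluster_cells(out$cell, tissue)
  rownames(out) <- NULL
  out
}

# Label connected components (4-neighborhood) among a set of cell ids.
.cluster_cells <- function(cells, tissue) {
  if (!length(cells)) return(integer(0))
  lab <- rep(NA_integer_, length(cells))
  next_lab <- 0L
  for (k in seq_along(cells)) {
    if (!is.na(lab[k])) next
    next_lab <- next_lab + 1L
    queue <- k
    lab[k] <- next_lab
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nbs <- tissue$nb[cells[i], ]
      hits <- which(cells %in% nbs[!is.na(nbs)] & is.na(lab))
      lab[hits] <- next_lab
      queue <- c(queue, hits)
    }
  }
  lab
}

#' Auxin profile along one column
#'
#' @param state A `margin_state`.
#' @param tissue The `margin_tissue`.
#' @param col Column index (defaults to the middle column, the margin proper).
#' @return Numeric vector of length `n_rows`, ordered distal to proximal.
#' @export
column_profile <- function(state, tissue, col = tissue$mid_col) {
  if (col < 1 || col > tissue$n_cols)
    stop("column ", col, " out of range [1, ", tissue$n_cols, "]")
  sel <- tissue$col == col
  state$auxin[sel][order(tissue$row[sel])]
}

#' Detect emergent auxin maxima in a profile
#'
#' Local maxima at least `min_separation` rows away from the source row,
#' whose amplitude is at least `(1 + prominence)` times the profile median
#' (prominence is measured against the median rather than the source peak,
#' which dominates the scale). An interior row must be strictly greater than
#' both neighbors; because the tissue boundary is closed, transported auxin
#' can pile against the proximal wall, so an endpoint row strictly greater
#' than its single neighbor also counts when `include_boundary` is TRUE
#' (default). Plateau cells fail the strict inequality and are never peaks,
#' so a monotone profile yields none; among the returned peaks the most
#' distal row comes first.
#'
#' @param profile Numeric auxin profile (distal to proximal).
#' @param source_row Row index of the auxin source.
#' @param min_separation Minimum row distance from the source (>= 1).
#' @param prominence Required fractional excess over the profile median (> 0).
#' @param include_boundary Count a strict crest at a profile endpoint?
#' @return Data.frame with columns `row` and `amplitude` (possibly 0 rows).
#' @export
detect_emergent_maxima <- function(profile, source_row, min_separation = 3,
                                   prominence = 0.2,
                                   include_boundary = TRUE) {
  if (min_separation < 1) stop("min_separation must be >= 1")
  if (prominence <= 0) stop("prominence must be > 0")
  n <- length(profile)
  thr <- (1 + prominence) * stats::median(profile)
  is_peak <- function(i) {
    left_ok <- i == 1 || profile[i] > profile[i - 1]
    right_ok <- i == n || profile[i] > profile[i + 1]
    interior <- i > 1 && i < n
    (interior || include_boundary) && left_ok && right_ok &&
      abs(i - source_row) >= min_separation && profile[i] >= thr
  }
  rows <- which(vapply(seq_len(n), is_peak, logical(1)))
  data.frame(row = rows, amplitude = profile[rows])
}

#' Noise specification for robustness runs
#'
#' Multiplicative perturbation x <- x (1 + amplitude u), u ~ Uniform(-1, 1)
#' i.i.d. per cell. Auxin noise may be re-applied every `tau` time units
#' during integration; CUC noise is applied once per replicate before
#' integration (CUC is a static input).
#'
#' @param target `"auxin"` or `"cuc"`.
#' @param amplitude Fraction in \[0, 1) (e.g. 0.10 for +/-10%).
#' @param schedule `"per_replicate_init"` or `"resample_every"`; CUC noise
#'   must be `"per_replicate_init"`.
#' @param tau Resampling interval (t) for `"resample_every"`.
#' @param seed Optional integer seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(target = c("auxin", "cuc"), amplitude,
                       schedule = c("per_replicate_init", "resample_every"),
                       tau = NULL, seed = NULL) {
  target <- match.arg(target)
  schedule <- match.arg(schedule)
  if (amplitude < 0 || amplitude >= 1)
    stop("amplitude must be in [0, 1)")
  if (target == "cuc" && schedule != "per_replicate_init")
    stop("CUC noise must use the per_replicate_init schedule (CUC is static)")
  if (schedule == "resample_every" && (is.null(tau) || tau <= 0))
    stop("resample_every schedule requires tau > 0")
  structure(list(target = target, amplitude = amplitude,
                 schedule = schedule, tau = tau, seed = seed),
            class = "noise_spec")
}

.perturb <- function(x, amplitude) {
  x * (1 + amplitude * stats::runif(length(x), -1, 1))
}

#' Apply a noise spec to a state or template
#'
#' Returns a perturbed copy; the input is not modified. Reproducible given
#' the spec's seed (set before drawing).
#'
#' @param x A `margin_state` (auxin target) or `margin_template` (cuc or
#'   auxin target; auxin perturbs the initial auxin).
#' @param spec A `noise_spec`.
#' @return Perturbed copy of `x`.
#' @export
apply_noise <- function(x, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (inherits(x, "margin_state")) {
    if (spec$target != "auxin")
      stop("only auxin noise applies to a simulation state")
    x$auxin <- .perturb(x$auxin, spec$amplitude)
  } else if (inherits(x, "margin_template")) {
    if (spec$target == "cuc") {
      x$tissue$cuc <- .perturb(x$tissue$cuc, spec$amplitude)
    } else {
      x$init_auxin <- .perturb(x$init_auxin, spec$amplitude)
    }
  } else stop("x must be a margin_state or margin_template")
  x
}

#' Run a noise-robustness ensemble
#'
#' Integrates `n_reps` replicates of a scenario under a noise spec, scoring
#' each replicate for (a) repolarization — at least one middle-column cell
#' inside the CUC band classified basal — and (b) an emergent auxin maximum
#' on the middle column (first, i.e. most distal, peak from
#' [detect_emergent_maxima()]). A replicate is a success if both hold.
#' Replicates that fail to converge are recorded, never dropped. Given a
#' fixed seed vector the per-replicate records are bitwise reproducible and
#' the summary is invariant to replicate order.
#'
#' @param template A `margin_template` (wild-type pattern for the band
#'   definition).
#' @param params A `margin_params`.
#' @param spec A `noise_spec`.
#' @param n_reps Number of replicates (>= 1).
#' @param seeds Optional integer vector of per-replicate seeds (default
#'   `spec$seed + 0:(n_reps-1)`, or `1:n_reps` when the spec has no seed).
#' @param t_relax Noise-free relaxation time before each replicate is scored
#'   (see [run_to_steady_state()]).
#' @param min_separation,prominence Passed to [detect_emergent_maxima()].
#' @return A `margin_ensemble`: `$replicates` data.frame (seed, converged,
#'   repolarized, peak_row, peak_amplitude, success) and `$summary` list
#'   (success_fraction, mean/sd of position, mean/sd/cv of amplitude).
#' @export
run_ensemble <- function(template, params, spec, n_reps = 20, seeds = NULL,
                         t_relax = 100, min_separation = 3, prominence = 0.2) {
  stopifnot(n_reps >= 1)
  if (is.null(seeds)) {
    base <- if (!is.null(spec$seed)) spec$seed else 1L
    seeds <- base + seq_len(n_reps) - 1L
  }
  if (length(seeds) != n_reps)
    stop("need exactly n_reps seeds (got ", length(seeds), ")")
  tis <- template$tissue
  band <- cuc_band_rows(tis)
  src_row <- unique(tis$row[tis$is_source])
  recs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sp <- spec; sp$seed <- seeds[r]
    sim <- run_to_steady_state(template, params, noise = sp, t_relax = t_relax)
    field <- net_polarity(sim$final_state, sim$tissue, P_tot = params$P_tot)
    mid_band <- field$col == tis$mid_col & field$row %in% band
    repol <- any(field$class[mid_band] == "basal")
    prof <- column_profile(sim$final_state, sim$tissue)
    pk <- detect_emergent_maxima(prof, source_row = src_row,
                                 min_separation = min_separation,
                                 prominence = prominence)
    recs[[r]] <- data.frame(
      seed = seeds[r], converged = sim$converged,
      repolarized = repol,
      peak_row = if (nrow(pk)) pk$row[1] else NA_integer_,
      peak_amplitude = if (nrow(pk)) pk$amplitude[1] else NA_real_,
      success = repol && nrow(pk) > 0
    )
  }
  reps <- do.call(rbind, recs)
  amp <- reps$peak_amplitude[!is.na(reps$peak_amplitude)]
  pos <- reps$peak_row[!is.na(reps$peak_row)]
  summ <- list(
    n_reps = n_reps,
    success_fraction = mean(reps$success),
    repolarized_fraction = mean(reps$repolarized),
    peak_fraction = mean(!is.na(reps$peak_row)),
    position_mean = if (length(pos)) mean(pos) else NA_real_,
    position_sd = if (length(pos) > 1) stats::sd(pos) else NA_real_,
    amplitude_mean = if (length(amp)) mean(amp) else NA_real_,
    amplitude_sd = if (length(amp) > 1) stats::sd(amp) else NA_real_,
    amplitude_cv = if (length(amp) > 1 && mean(amp) > 0)
      stats::sd(amp) / mean(amp) else NA_real_
  )
  structure(list(replicates = reps, summary = summ, spec = spec,
                 variant = params$variant),
            class = "margin_ensemble")
}

#' @export
print.margin_ensemble <- function(x, ...) {
  s <- x$summary
  cat("Noise ensemble (", x$variant, "; ", x$spec$target, " +/-",
      100 * x$spec$amplitude, "%, n = ", s$n_reps, ")\n", sep = "")
  cat(sprintf("  success: %.0f%% (repolarized %.0f%%, emergent peak %.0f%%)\n",
              100 * s$success_fraction, 100 * s$repolarized_fraction,
              100 * s$peak_fraction))
  cat(sprintf("  peak position: %.2f +/- %.2f (rows); amplitude: %.3g +/- %.3g (CV %.3f)\n",
              s$position_mean, s$position_sd, s$amplitude_mean,
              s$amplitude_sd, s$amplitude_cv))
  invisible(x)
}

#' Export a profile as a two-column table
#'
#' @param profile Numeric profile from [column_profile()].
#' @param path CSV output path.
#' @return The data.frame, invisibly.
#' @export
export_profile <- function(profile, path) {
  df <- data.frame(row = seq_along(profile), auxin = profile)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
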