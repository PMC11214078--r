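# Independent oracles and small fixture builders shared across the suite.
# These deliberately re-derive results from first principles (loops, direct
# linear algebra, exhaustive enumeration) so they never share code paths
# with the package implementation they check.

# Build a polarity_field data.frame for a tissue from per-cell class tags
# ("apical", "basal", "nonpolar"), with unit-magnitude vectors.
make_polarity_field <- function(tissue, classes, P_tot = 1) {
  vy <- ifelse(classes == "apical", 1, ifelse(classes == "basal", -1, 0))
  out <- data.frame(row = tissue$row, col = tissue$col,
                    vx = 0, vy = vy, magnitude = abs(vy),
                    class = factor(classes,
                                   levels = c("apical", "basal", "lateral",
                                              "bipolar", "nonpolar")))
  attr(out, "P_tot") <- P_tot
  attr(out, "theta_np") <- 0.1
  class(out) <- c("polarity_field", "data.frame")
  out
}

# Brute-force convergence detection, written straight from the definition:
# >= min(k_min, #neighbors) neighbors point at i (dot product > theta), and
# i does not point at any neighbor that fails to point back. Plain nested
# loops over cells and directions; no shared helpers with the package.
brute_force_convergences <- function(field, tissue, k_min = 2,
                                     theta = 0.1 * attr(field, "P_tot")) {
  dirs <- list(up = c(0, 1), down = c(0, -1), left = c(-1, 0), right = c(1, 0))
  opp <- c(up = "down", down = "up", left = "right", right = "left")
  hits <- integer(0)
  for (i in seq_len(tissue$n_cells)) {
    n_ex <- 0L; inward <- 0L; bad <- FALSE
    for (d in names(dirs)) {
      j <- tissue$nb[i, d]
      if (is.na(j)) next
      n_ex <- n_ex + 1L
      u_ij <- dirs[[d]]
      u_ji <- dirs[[opp[[d]]]]
      j_points_at_i <- (field$vx[j] * u_ji[1] + field$vy[j] * u_ji[2]) > theta
      i_points_at_j <- (field$vx[i] * u_ij[1] + field$vy[i] * u_ij[2]) > theta
      if (j_points_at_i) inward <- inward + 1L
      if (i_points_at_j && !j_points_at_i) bad <- TRUE
    }
    if (n_ex > 0 && !bad && inward >= min(k_min, n_ex)) hits <- c(hits, i)
  }
  hits
}

# Jarvis-march (gift wrapping) convex hull oracle over a point set; returns
# the hull vertex indices in traversal order.
jarvis_hull <- function(pts) {
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  current <- start
  repeat {
    candidate <- if (current == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == current) next
      cr <- (pts[candidate, 1] - pts[current, 1]) * (pts[k, 2] - pts[current, 2]) -
            (pts[candidate, 2] - pts[current, 2]) * (pts[k, 1] - pts[current, 1])
      if (cr < 0 ||
          (cr == 0 &&
           sum((pts[k, ] - pts[current, ])^2) >
           sum((pts[candidate, ] - pts[current, ])^2)))
        candidate <- k
    }
    current <- candidate
    if (current == start) break
    hull <- c(hull, current)
  }
  hull
}

# Direct steady-state auxin solve for fixed PIN (linear balance equations).
linear_steady_auxin <- function(tissue, pin, params) {
  n <- tissue$n_cells
  M <- matrix(0, n, n)
  S <- params$sigma_src * as.numeric(tissue$is_source) + params$sigma_bg
  for (i in seq_len(n)) {
    M[i, i] <- M[i, i] - params$mu_a
    for (d in 1:4) {
      j <- tissue$nb[i, d]
      if (is.na(j)) next
      M[i, i] <- M[i, i] - params$D - params$T_rate * pin[i, d]
      M[i, j] <- M[i, j] + params$D +
        params$T_rate * pin[j, marginpin:::.dir_opposite[d]]
    }
  }
  as.numeric(solve(M, -S))
}

# Shared steady-state runs, computed once per session.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(variant, template_name = "wt", ...) {
  key <- paste(variant, template_name, ...)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_to_steady_state(
      make_template(template_name),
      margin_params(variant, ...))
  }
  .sim_cache[[key]]
}

# Emergent structure report used by the acceptance suite: convergence
# clusters away from the source, CUC-band repolarization, emergent maxima.
pattern_report <- function(sim) {
  s <- sim$final_state
  tis <- sim$tissue
  prof <- column_profile(s, tis)
  src_row <- unique(tis$row[tis$is_source])
  peaks <- detect_emergent_maxima(prof, source_row = src_row)
  field <- net_polarity(s, tis, P_tot = sim$params$P_tot)
  conv <- detect_convergences(field, tis)
  band <- cuc_band_rows(tis)
  src_cl <- if (nrow(conv))
    unique(conv$cluster[abs(conv$row - src_row) <= 1 & conv$col == tis$mid_col])
  else integer(0)
  emer <- conv[!(conv$cluster %in% src_cl), , drop = FALSE]
  mid_band <- field$col == tis$mid_col & field$row %in% band
  mid_below <- field$col == tis$mid_col & field$row > src_row
  list(
    profile = prof,
    peaks = peaks,
    convergences = conv,
    has_source_convergence = length(src_cl) > 0,
    n_emergent_clusters = if (nrow(emer)) length(unique(emer$cluster)) else 0L,
    emergent_rows = unique(emer$row),
    n_basal_in_band = sum(field$class[mid_band] == "basal"),
    band_start = if (length(band)) min(band) else NA_integer_,
    apical_below_fraction = mean(field$class[mid_below] == "apical"),
    monotone_below_source = all(diff(prof[src_row:length(prof)]) < 1e-9)
  )
}
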