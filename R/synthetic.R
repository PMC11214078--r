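# Seeded synthetic-data generators with planted ground truth. These stand in
# for the study-style microscopy exports and leaf silhouettes so that every
# quantification stage can be validated against known answers. Each generator
# takes a single spec with a seed; the ambient RNG state is restored on exit.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification for a synthetic cell table
#'
#' Emulates a margin-cell microscopy export: cells along an arc with
#' distances from the protrusion tip, a planted polarity reversal at `d*`
#' (apical distal to it, basal proximal to it, with Gaussian positional
#' jitter of the boundary and optional mislabeling), two reporter channels
#' with a planted linear relation (`ch_wag = a + b ch_cuc + N(0, sigma)`),
#' log-normal intensities, and a planted point-biserial correlation `rho_pb`
#' between the CUC channel and basal polarity. The CUC channel is log-normal
#' within each polarity group; the group mean-log realizing `rho_pb` is
#' solved from the closed-form log-normal mixture moments.
#'
#' @param n_cells Number of cells.
#' @param arc_length_um Margin arc length covered (micrometres).
#' @param reversal_um Planted reversal distance d* (micrometres).
#' @param position_noise_sd_um Gaussian SD of the polarity boundary jitter.
#' @param mislabel_prob Probability of flipping a cell's polarity label.
#' @param expr_intercept,expr_slope,expr_sigma Linear expression model of the
#'   WAG channel on the CUC channel.
#' @param rho_pb Planted point-biserial correlation between the CUC channel
#'   and basal polarity.
#' @param meanlog,sdlog Log-scale parameters of the CUC channel in the
#'   apical group.
#' @param seed Integer seed.
#' @return A `synth_cells_spec` list.
#' @export
synth_cells_spec <- function(n_cells = 60, arc_length_um = 80,
                             reversal_um = 30, position_noise_sd_um = 6,
                             mislabel_prob = 0, expr_intercept = 5,
                             expr_slope = 2, expr_sigma = 1,
                             rho_pb = 0.6, meanlog = 0, sdlog = 0.4,
                             seed = 1) {
  if (mislabel_prob < 0 || mislabel_prob > 1)
    stop("mislabel_prob must be in [0, 1]")
  if (position_noise_sd_um < 0 || expr_sigma < 0)
    stop("noise SDs must be >= 0")
  if (reversal_um <= 0 || reversal_um >= arc_length_um)
    stop("reversal_um must lie inside (0, arc_length_um)")
  if (abs(rho_pb) >= 1) stop("rho_pb must be in (-1, 1)")
  structure(as.list(environment()), class = "synth_cells_spec")
}

# Population point-biserial correlation of a two-group log-normal mixture:
# group j has meanlog m_j, common sdlog s, and P(basal) = p.
.lognorm_rpb <- function(m1, m0, s, p) {
  M1 <- exp(m1 + s^2 / 2); M0 <- exp(m0 + s^2 / 2)
  V1 <- (exp(s^2) - 1) * exp(2 * m1 + s^2)
  V0 <- (exp(s^2) - 1) * exp(2 * m0 + s^2)
  q <- 1 - p
  sd_x <- sqrt(p * V1 + q * V0 + p * q * (M1 - M0)^2)
  (M1 - M0) * sqrt(p * q) / sd_x
}

#' Generate a synthetic cell table with ground truth
#'
#' Produces a validated cell table (see [read_cell_table()] for the schema,
#' plus `grid_row`/`grid_col` and a `polarity_true` column is NOT included —
#' truth is returned separately, never embedded in the table) and the
#' ground-truth record needed by the estimator-recovery harness.
#'
#' Segment signals are synthesized consistently with each cell's polarity
#' class: the dominant segment carries a margin above the default
#' classification thresholds, so [classify_polarity_table()] recovers the
#' planted classes exactly in the absence of mislabeling.
#'
#' @param spec A `synth_cells_spec`.
#' @return List with `table` (data.frame) and `truth` (list: planted
#'   `reversal_um`, `rho_pb`, expression coefficients, and the per-cell true
#'   polarity labels).
#' @examples
#' g <- gen_cell_table(synth_cells_spec(seed = 42))
#' head(g$table)
#' g$truth$reversal_um
#' @export
gen_cell_table <- function(spec) {
  stopifnot(inherits(spec, "synth_cells_spec"))
  # feasibility of the planted correlation given the intensity spread
  p_expect <- 1 - spec$reversal_um / spec$arc_length_um
  bound <- abs(.lognorm_rpb(spec$meanlog + sign(spec$rho_pb) * 25,
                            spec$meanlog, spec$sdlog, p_expect))
  if (abs(spec$rho_pb) >= bound)
    stop("rho_pb = ", spec$rho_pb, " is infeasible for sdlog = ",
         spec$sdlog, " and this geometry; attainable |rho_pb| < ",
         format(bound, digits = 4))
  m1 <- stats::uniroot(
    function(m) .lognorm_rpb(m, spec$meanlog, spec$sdlog, p_expect) -
      spec$rho_pb,
    interval = spec$meanlog + sort(c(0, sign(spec$rho_pb) * 25)),
    tol = 1e-10)$root
  .with_seed(spec$seed, {
    n <- spec$n_cells
    d <- sort(stats::runif(n, 0, spec$arc_length_um))
    basal <- d + stats::rnorm(n, 0, spec$position_noise_sd_um) >=
      spec$reversal_um
    flip <- stats::runif(n) < spec$mislabel_prob
    basal <- xor(basal, flip)
    # CUC channel: log-normal within polarity groups, planted r_pb
    ch_cuc <- exp(stats::rnorm(n, ifelse(basal, m1, spec$meanlog),
                               spec$sdlog))
    ch_wag <- spec$expr_intercept + spec$expr_slope * ch_cuc +
      stats::rnorm(n, 0, spec$expr_sigma)
    ch_wag <- pmax(ch_wag, 0)
    # membrane segments consistent with the class: dominant = 2.5 x base,
    # base segments jittered in [0.8, 1.2]; margins clear both default
    # thresholds (dominance 1.5, bipolar 1.5) at any common scale
    scale <- exp(stats::rnorm(n, 0, 0.2))
    seg <- matrix(stats::runif(4 * n, 0.8, 1.2), n, 4)
    dom <- ifelse(basal, 2L, 1L)  # 1 = distal, 2 = proximal
    seg[cbind(seq_len(n), dom)] <- 2.5
    seg <- seg * scale
    tab <- data.frame(
      cell_id = sprintf("c%03d", seq_len(n)),
      x_um = d,
      y_um = stats::rnorm(n, 0, 0.5),
      dist_tip_um = d,
      ch_cuc = ch_cuc, ch_wag = ch_wag,
      ch_pin = rowSums(seg),
      seg_distal = seg[, 1], seg_proximal = seg[, 2],
      seg_lat1 = seg[, 3], seg_lat2 = seg[, 4],
      group = "synthetic",
      grid_row = seq_len(n), grid_col = 1L
    )
    validate_cell_table(tab)
    list(table = tab,
         truth = list(reversal_um = spec$reversal_um,
                      rho_pb = spec$rho_pb,
                      meanlog_basal = m1,
                      expr_intercept = spec$expr_intercept,
                      expr_slope = spec$expr_slope,
                      expr_sigma = spec$expr_sigma,
                      basal = basal,
                      seed = spec$seed))
  })
}

#' Specification for a synthetic lobed leaf silhouette
#'
#' A base ellipse whose radius is modulated by `n_lobes` sinusoidal lobes of
#' fractional depth `depth`: r(theta) = R_ellipse(theta) * (1 - depth/2 +
#' (depth/2) cos(n_lobes * theta)). The polygon is star-shaped around the
#' origin for any depth < 1, hence always simple. `depth = 0` returns the
#' convex ellipse polygon.
#'
#' @param semi_major,semi_minor Ellipse semi-axes (mm).
#' @param n_lobes Number of lobes (>= 1).
#' @param depth Lobe depth fraction in \[0, 1).
#' @param pts_per_lobe Polygon vertices per lobe.
#' @param jitter_sd Optional radial jitter SD as a fraction of the local
#'   radius (default 0 — deterministic outline).
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @return A `synth_silhouette_spec` list.
#' @export
synth_silhouette_spec <- function(semi_major = 30, semi_minor = 15,
                                  n_lobes = 5, depth = 0.3,
                                  pts_per_lobe = 40, jitter_sd = 0,
                                  seed = 1) {
  if (depth < 0 || depth >= 1) stop("depth must be in [0, 1)")
  if (n_lobes < 1) stop("n_lobes must be >= 1")
  if (jitter_sd < 0 || jitter_sd >= (1 - depth) / 3)
    if (jitter_sd < 0) stop("jitter_sd must be >= 0") else
      stop("jitter_sd too large for this depth (risks self-intersection); ",
           "limit is (1 - depth)/3 = ", format((1 - depth) / 3, digits = 3))
  structure(as.list(environment()), class = "synth_silhouette_spec")
}

#' Generate a synthetic lobed leaf silhouette
#'
#' @param spec A `synth_silhouette_spec`.
#' @return A `leaf_silhouette`.
#' @examples
#' sil <- gen_silhouette(synth_silhouette_spec(depth = 0.4))
#' ndmc(sil)
#' @export
gen_silhouette <- function(spec) {
  stopifnot(inherits(spec, "synth_silhouette_spec"))
  n <- spec$n_lobes * spec$pts_per_lobe
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  a <- spec$semi_major; b <- spec$semi_minor
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  mod <- 1 - spec$depth / 2 + (spec$depth / 2) * cos(spec$n_lobes * theta)
  r <- r_ell * mod
  if (spec$jitter_sd > 0) {
    r <- .with_seed(spec$seed,
                    r * (1 + stats::rnorm(n, 0, spec$jitter_sd)))
  }
  leaf_silhouette(cbind(r * cos(theta), r * sin(theta)),
                  name = sprintf("synthetic k=%d d=%.2f", spec$n_lobes,
                                 spec$depth))
}

#' Write a ground-truth record as structured text
#'
#' Truth is always written alongside, never embedded in, the data table.
#'
#' @param truth Ground-truth list from [gen_cell_table()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  truth$basal <- as.logical(truth$basal)
  yaml::write_yaml(truth, path)
  invisible(path)
}
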