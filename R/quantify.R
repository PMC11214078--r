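# Cell-resolution quantification over microscopy-style cell tables:
# polarity classification from membrane-segment signal, reversal-position
# estimation, polarity frequency / contingency analysis, expression-polarity
# correlation, per-sample regression, and region-of-interest selection.

.cell_table_cols <- c("cell_id", "x_um", "y_um", "dist_tip_um",
                      "ch_cuc", "ch_wag", "ch_pin",
                      "seg_distal", "seg_proximal", "seg_lat1", "seg_lat2")

#' Read / write a cell table
#'
#' Delimited text with the documented header
#' `cell_id,x_um,y_um,dist_tip_um,ch_cuc,ch_wag,ch_pin,seg_distal,seg_proximal,seg_lat1,seg_lat2[,group][,grid_row,grid_col]`
#' (one record per cell; distances in micrometres along the margin to the
#' protrusion-tip landmark, intensities in arbitrary units, one PIN signal
#' per membrane-segment orientation class).
#'
#' @param path File path.
#' @param table A cell-table data.frame.
#' @return `read_cell_table` returns a validated data.frame.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_table(df)
  df
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(table, path) {
  validate_cell_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Validate a cell table against its contract
#'
#' Checks required columns, non-negative distances and intensities, and
#' complete segment signals (cells with any missing segment are flagged).
#'
#' @param table A data.frame.
#' @return The table, invisibly; attribute `"unusable"` lists cell_ids with
#'   incomplete segment records.
#' @export
validate_cell_table <- function(table) {
  miss <- setdiff(.cell_table_cols, names(table))
  if (length(miss))
    stop("cell table is missing columns: ", paste(miss, collapse = ", "))
  if (any(table$dist_tip_um < 0, na.rm = TRUE))
    stop("distances must be >= 0")
  ints <- c("ch_cuc", "ch_wag", "ch_pin",
            "seg_distal", "seg_proximal", "seg_lat1", "seg_lat2")
  for (cn in ints)
    if (any(table[[cn]] < 0, na.rm = TRUE))
      stop("intensities must be >= 0 (column ", cn, ")")
  segs <- c("seg_distal", "seg_proximal", "seg_lat1", "seg_lat2")
  bad <- rowSums(is.na(table[segs])) > 0
  attr(table, "unusable") <- table$cell_id[bad]
  invisible(table)
}

#' Classify the PIN polarity of one cell from membrane-segment signals
#'
#' Given the four segment signals, let s_max be the strongest and s_opp its
#' opposite. The cell is `bipolar` when s_opp is within ratio `r_b` of s_max
#' and the dominant axis also dominates the orthogonal pair (so a uniform
#' cell is nonpolar, not bipolar); otherwise `apical`/`basal` by the
#' orientation of s_max when s_max >= `r_d` x mean(other segments), with
#' "-lateral" appended when a lateral segment is within `r_b` of s_max; a
#' cell whose dominant segment is lateral without appreciable distal/proximal
#' signal is `lateral`; anything else is `nonpolar`. The call is invariant to
#' rescaling all four signals by a common positive factor.
#'
#' @param seg_distal,seg_proximal,seg_lat1,seg_lat2 Segment signals (a.u.).
#' @param dominance_ratio r_d: dominance threshold of s_max over the mean of
#'   the other segments.
#' @param bipolar_ratio r_b: ratio within which the opposite (or a lateral)
#'   segment counts as comparable.
#' @return A `polarity_call` list: `class` and `confidence` (ratio of the
#'   dominant to the subdominant segment signal).
#' @export
classify_cell_polarity <- function(seg_distal, seg_proximal, seg_lat1,
                                   seg_lat2, dominance_ratio = 1.5,
                                   bipolar_ratio = 1.5) {
  s <- c(distal = seg_distal, proximal = seg_proximal,
         lat1 = seg_lat1, lat2 = seg_lat2)
  if (any(is.na(s)))
    stop("missing segment signal: ", paste(names(s)[is.na(s)], collapse = ", "))
  if (any(s < 0)) stop("segment signals must be >= 0")
  opp <- c(distal = "proximal", proximal = "distal",
           lat1 = "lat2", lat2 = "lat1")
  d1 <- names(which.max(s))
  s1 <- s[[d1]]
  s_opp <- s[[opp[[d1]]]]
  orth <- setdiff(names(s), c(d1, opp[[d1]]))
  sorted <- sort(s, decreasing = TRUE)
  confidence <- if (sorted[2] > 0) sorted[1] / sorted[2] else Inf
  axis_mean <- (s1 + s_opp) / 2
  orth_mean <- mean(s[orth])
  others_mean <- mean(s[setdiff(names(s), d1)])
  cls <-
    if (s1 > 0 && s_opp >= s1 / bipolar_ratio && axis_mean >= dominance_ratio * orth_mean) {
      "bipolar"
    } else if (s1 >= dominance_ratio * others_mean && s1 > 0) {
      if (d1 %in% c("distal", "proximal")) {
        base <- if (d1 == "distal") "apical" else "basal"
        if (max(s[c("lat1", "lat2")]) >= s1 / bipolar_ratio)
          paste0(base, "-lateral") else base
      } else {
        dp <- s[c("distal", "proximal")]
        if (max(dp) >= s1 / bipolar_ratio) {
          paste0(if (which.max(dp) == 1L) "apical" else "basal", "-lateral")
        } else "lateral"
      }
    } else "nonpolar"
  structure(list(class = cls, confidence = unname(confidence)),
            class = "polarity_call")
}

#' Classify every usable cell of a cell table
#'
#' Vectorized wrapper around [classify_cell_polarity()]; cells with missing
#' segment signals are excluded with a reason code.
#'
#' @param table A validated cell table.
#' @inheritParams classify_cell_polarity
#' @return Data.frame `cell_id`, `class` (factor), `confidence`; excluded
#'   cells are listed in attribute `"excluded"` with reasons.
#' @export
classify_polarity_table <- function(table, dominance_ratio = 1.5,
                                    bipolar_ratio = 1.5) {
  validate_cell_table(table)
  segs <- c("seg_distal", "seg_proximal", "seg_lat1", "seg_lat2")
  bad <- rowSums(is.na(table[segs])) > 0
  ok <- which(!bad)
  cls <- character(length(ok)); conf <- numeric(length(ok))
  for (k in seq_along(ok)) {
    i <- ok[k]
    pc <- classify_cell_polarity(table$seg_distal[i], table$seg_proximal[i],
                                 table$seg_lat1[i], table$seg_lat2[i],
                                 dominance_ratio, bipolar_ratio)
    cls[k] <- pc$class; conf[k] <- pc$confidence
  }
  out <- data.frame(cell_id = table$cell_id[ok],
                    class = factor(cls, levels = .polarity_levels),
                    confidence = conf)
  attr(out, "excluded") <- if (any(bad))
    data.frame(cell_id = table$cell_id[bad], reason = "missing segment signal")
  else data.frame(cell_id = character(0), reason = character(0))
  out
}

.polarity_levels <- c("apical", "apical-lateral", "basal", "basal-lateral",
                      "lateral", "bipolar", "nonpolar")

#' Estimate the polarity reversal position along the margin
#'
#' The reversal position is the mean distance-from-tip of the five cells
#' closest to the protrusion tip that show clear basal polarity (class
#' `basal` or `basal-lateral`). Ties at the fifth rank are broken by cell_id.
#' The estimate is invariant to record order and to the distances of
#' non-basal cells.
#'
#' @param table A validated cell table.
#' @param calls Optional polarity calls from [classify_polarity_table()]
#'   (computed with default thresholds when absent).
#' @param n_cells Number of closest basal cells averaged (default 5).
#' @return Reversal distance (micrometres).
#' @export
reversal_position <- function(table, calls = NULL, n_cells = 5) {
  validate_cell_table(table)
  if (is.null(calls)) calls <- classify_polarity_table(table)
  basal_ids <- calls$cell_id[calls$class %in% c("basal", "basal-lateral")]
  sel <- table$cell_id %in% basal_ids
  if (sum(sel) < n_cells)
    stop("insufficient basal cells: need ", n_cells, " with clear basal ",
         "polarity, found ", sum(sel))
  d <- table$dist_tip_um[sel]
  id <- table$cell_id[sel]
  o <- order(d, id)
  mean(d[o][seq_len(n_cells)])
}

#' Polarity frequency contingency table and chi-squared test
#'
#' Counts polarity calls per (group, class), drops classes with all-zero
#' totals (noted in the result), and runs a Pearson chi-squared test without
#' continuity correction.
#'
#' @param calls Data.frame with a `class` column (or factor vector of calls).
#' @param group Group label per call (e.g. control / clone / neighbor).
#' @return A `polarity_freq` list: `table` (group x class counts),
#'   `statistic`, `df`, `p.value`, `dropped_classes`.
#' @export
polarity_frequencies <- function(calls, group) {
  cls <- if (is.data.frame(calls)) calls$class else calls
  if (length(cls) != length(group))
    stop("calls and group must have the same length")
  tab <- table(group = group, class = cls)
  zero_cols <- colSums(tab) == 0
  dropped <- colnames(tab)[zero_cols]
  tab <- tab[, !zero_cols, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table: need >= 2 groups and >= 2 classes ",
         "with nonzero totals (got ", nrow(tab), " x ", ncol(tab), ")")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(table = tab,
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value,
                 dropped_classes = dropped),
            class = "polarity_freq")
}

#' @export
print.polarity_freq <- function(x, ...) {
  cat("Polarity frequency contingency analysis\n")
  print(x$table)
  cat(sprintf("  Pearson chi-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p.value))
  if (length(x$dropped_classes))
    cat("  dropped all-zero classes: ",
        paste(x$dropped_classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Point-biserial correlation
#'
#' r_pb = (M1 - M0) / s_n * sqrt(n1 n0 / n^2) with the population standard
#' deviation s_n; numerically identical to the Pearson correlation of `x`
#' with 0/1-coded `y`. A zero-variance `x` returns 0 with attribute
#' `zero_variance = TRUE` (documented convention). The significance test is
#' the usual t test on n - 2 degrees of freedom.
#'
#' @param x Continuous values.
#' @param y Binary labels (logical, 0/1, or two-level factor).
#' @return An object of class `htest` with `estimate` (r_pb), `statistic`
#'   (t), `parameter` (df) and `p.value`.
#' @examples
#' point_biserial(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
point_biserial <- function(x, y) {
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (length(y) != n) stop("x and y must have the same length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate grouping: both label classes must be present")
  s_n <- stats::sd(x) * sqrt((n - 1) / n)
  if (s_n == 0) {
    r <- 0
    zero_var <- TRUE
  } else {
    r <- (mean(x[y == 1]) - mean(x[y == 0])) / s_n * sqrt(n1 * n0 / n^2)
    zero_var <- FALSE
  }
  tstat <- if (abs(r) < 1) r * sqrt((n - 2) / (1 - r^2)) else sign(r) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- list(statistic = c(t = tstat), parameter = c(df = n - 2),
              p.value = p, estimate = c(r_pb = r),
              method = "Point-biserial correlation",
              data.name = paste(deparse(substitute(x)), "and",
                                deparse(substitute(y))))
  attr(out, "zero_variance") <- zero_var
  class(out) <- "htest"
  out
}

#' Ordinary least-squares expression regression
#'
#' Per-sample linear regression of one reporter channel on another (fit each
#' sample independently; do not pool).
#'
#' @param x Predictor channel (a.u.).
#' @param y Response channel (a.u.).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`, and
#'   the underlying `lm` fit.
#' @export
expression_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need n >= 3 (got ", length(x), ")")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (sm$sigma == 0) 0 else unname(stats::coef(sm)[2, 4])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = p,
       n = length(x), fit = fit)
}

#' Select a rows x cols region of interest from a cell table
#'
#' Selects the block of cells extending proximally (increasing grid row) and
#' inward (increasing grid column) from an origin cell — the presumptive CUC
#' domain ROI. The table must carry `grid_row` / `grid_col` coordinates.
#' Expected positions missing from the table are reported, never silently
#' skipped.
#'
#' @param table Cell table with `grid_row` and `grid_col` columns.
#' @param origin `cell_id` of the origin cell.
#' @param rows,cols Block extent (default 4 x 4).
#' @return List with `cells` (the subset of `table`) and `missing`
#'   (data.frame of expected grid positions absent from the table).
#' @export
select_roi_grid <- function(table, origin, rows = 4, cols = 4) {
  if (!all(c("grid_row", "grid_col") %in% names(table)))
    stop("table must carry grid_row and grid_col coordinates")
  i <- match(origin, table$cell_id)
  if (is.na(i)) stop("origin cell '", origin, "' not found in table")
  r0 <- table$grid_row[i]; c0 <- table$grid_col[i]
  want <- expand.grid(grid_row = r0 + seq_len(rows) - 1L,
                      grid_col = c0 + seq_len(cols) - 1L)
  key <- paste(table$grid_row, table$grid_col)
  sel <- table[key %in% paste(want$grid_row, want$grid_col), , drop = FALSE]
  have <- paste(sel$grid_row, sel$grid_col)
  missing <- want[!paste(want$grid_row, want$grid_col) %in% have, ,
                  drop = FALSE]
  rownames(missing) <- NULL
  list(cells = sel, missing = missing)
}
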