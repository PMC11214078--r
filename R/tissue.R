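# Tissue template construction: the modeled leaf margin is a flat rectangular
# strip of cells with 4-neighborhood adjacency. Row 1 is the distal (apical)
# end; rows increase proximally. The middle column is the margin proper, along
# which auxin profiles are read.

# Direction bookkeeping shared across the package. Columns of the neighbor
# matrix are, in order: up (distal, row - 1), down (proximal, row + 1),
# left (col - 1), right (col + 1).
.dir_names <- c("up", "down", "left", "right")
.dir_opposite <- c(2L, 1L, 4L, 3L)
# Unit vectors (x = column axis, y = distal axis pointing up): toward the
# neighbor in each direction.
.dir_ux <- c(0, 0, -1, 1)
.dir_uy <- c(1, -1, 0, 0)

#' Build a rectangular leaf-margin cell grid
#'
#' Constructs the static tissue geometry: `n_rows` x `n_cols` cells with
#' 4-neighborhood adjacency (no diagonals), identity and CUC fields
#' initialized to zero, and no auxin source. `n_cols` must be odd so that a
#' unique middle column (the margin proper) exists; row 1 is the distal end.
#'
#' @param n_rows Number of rows (>= 3); row index increases proximally.
#' @param n_cols Odd number of columns (>= 1).
#' @return A `margin_tissue` object: cell index vectors `row`/`col` (1-based,
#'   row-major order), neighbor index matrix `nb` (NA where the neighbor is
#'   missing; the tissue boundary is closed), fields `md`, `prox`, `cuc`,
#'   logical `is_source`, and `mid_col`.
#' @examples
#' tis <- build_grid(20, 5)
#' tis
#' @export
build_grid <- function(n_rows, n_cols) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 3)
    stop("n_rows must be a single number >= 3 (got ", n_rows, ")")
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 1 || n_cols %% 2 == 0)
    stop("n_cols must be a single odd number >= 1 (got ", n_cols, ")")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  i <- seq_len(n)
  nb <- matrix(NA_integer_, n, 4L, dimnames = list(NULL, .dir_names))
  nb[row > 1L, "up"] <- i[row > 1L] - n_cols
  nb[row < n_rows, "down"] <- i[row < n_rows] + n_cols
  nb[col > 1L, "left"] <- i[col > 1L] - 1L
  nb[col < n_cols, "right"] <- i[col < n_cols] + 1L
  structure(list(
    n_rows = n_rows, n_cols = n_cols, n_cells = n,
    row = row, col = col, nb = nb,
    mid_col = (n_cols + 1L) %/% 2L,
    md = numeric(n), prox = numeric(n), cuc = numeric(n),
    cuc_max = 0, fields_assigned = FALSE,
    is_source = logical(n)
  ), class = "margin_tissue")
}

#' @export
print.margin_tissue <- function(x, ...) {
  cat("Leaf-margin tissue: ", x$n_rows, " rows x ", x$n_cols,
      " cols (", x$n_cells, " cells, ", sum(!is.na(x$nb)),
      " directed edges)\n", sep = "")
  cat("  middle column: ", x$mid_col,
      "; source cells: ", sum(x$is_source), "\n", sep = "")
  if (x$fields_assigned)
    cat("  cuc_max: ", format(x$cuc_max), "; cells with cuc > 0: ",
        sum(x$cuc > 0), "\n", sep = "")
  invisible(x)
}

#' Number of directed adjacency edges in a tissue
#' @param tissue A `margin_tissue`.
#' @return Integer count of directed edges (each undirected neighbor pair
#'   contributes two).
#' @export
n_edges <- function(tissue) sum(!is.na(tissue$nb))

.cell_id <- function(tissue, row, col) {
  (as.integer(row) - 1L) * tissue$n_cols + as.integer(col)
}

#' Assign middle-domain and proximal-domain identity fields
#'
#' The middle domain (MD) is maximal on the middle column and decays linearly
#' with lateral distance; the proximal domain (PROX) is zero distal to a start
#' row and ramps linearly to 1 over `prox_ramp_rows` rows, staying at 1
#' proximally. Their product (scaled by `cuc_max`) later defines the CUC
#' expression domain.
#'
#' @param tissue A `margin_tissue`.
#' @param md_width Lateral width (in cells) of the MD ramp; md = max(0, 1 -
#'   lateral_distance / md_width).
#' @param prox_start_row Row at which the PROX ramp starts (prox = 0 there).
#' @param prox_ramp_rows Number of rows over which PROX ramps from 0 to 1.
#' @return The tissue with `md` and `prox` fields filled in.
#' @export
assign_identity_fields <- function(tissue, md_width, prox_start_row,
                                   prox_ramp_rows) {
  stopifnot(inherits(tissue, "margin_tissue"))
  if (md_width < 1) stop("md_width must be >= 1 (got ", md_width, ")")
  if (prox_start_row < 1 || prox_start_row > tissue$n_rows)
    stop("prox_start_row must be in [1, ", tissue$n_rows, "] (got ",
         prox_start_row, ")")
  if (prox_ramp_rows < 1)
    stop("prox_ramp_rows must be >= 1 (got ", prox_ramp_rows, ")")
  if (prox_start_row + prox_ramp_rows > tissue$n_rows)
    warning("PROX ramp extends past the grid (start ", prox_start_row,
            " + ramp ", prox_ramp_rows, " > ", tissue$n_rows,
            " rows); ramp clipped at the proximal boundary")
  lat <- abs(tissue$col - tissue$mid_col)
  tissue$md <- pmax(0, 1 - lat / md_width)
  tissue$prox <- pmin(1, pmax(0, (tissue$row - prox_start_row) / prox_ramp_rows))
  tissue$fields_assigned <- TRUE
  tissue$md_width <- md_width
  tissue$prox_start_row <- as.integer(prox_start_row)
  tissue$prox_ramp_rows <- as.integer(prox_ramp_rows)
  tissue
}

#' Set the CUC expression pattern from the identity fields
#'
#' CUC concentration is the product of the two identity fields scaled by
#' `cuc_max`: cuc(i) = cuc_max * md(i) * prox(i). `cuc_max = 0` yields the
#' cuc-mutant field (zero everywhere).
#'
#' @param tissue A `margin_tissue` with identity fields assigned.
#' @param cuc_max Maximum CUC concentration (a.u., >= 0).
#' @return The tissue with the `cuc` field filled in.
#' @export
set_cuc_pattern <- function(tissue, cuc_max) {
  stopifnot(inherits(tissue, "margin_tissue"))
  if (!isTRUE(tissue$fields_assigned))
    stop("identity fields must be assigned before setting the CUC pattern")
  if (cuc_max < 0) stop("cuc_max must be >= 0 (got ", cuc_max, ")")
  tissue$cuc <- cuc_max * tissue$md * tissue$prox
  tissue$cuc_max <- cuc_max
  tissue
}

#' Rows of the CUC band along the middle column
#'
#' The band is defined as the middle-column cells whose CUC concentration is
#' at least `threshold` times the tissue's `cuc_max` (default half-maximum).
#' Used to score "repolarization inside the CUC band".
#'
#' @param tissue A `margin_tissue` (wild-type pattern set).
#' @param threshold Fraction of `cuc_max` defining band membership.
#' @return Integer vector of row indices (possibly empty).
#' @export
cuc_band_rows <- function(tissue, threshold = 0.5) {
  stopifnot(inherits(tissue, "margin_tissue"))
  if (tissue$cuc_max <= 0) return(integer(0))
  sel <- tissue$col == tissue$mid_col &
    tissue$cuc >= threshold * tissue$cuc_max
  sort(tissue$row[sel])
}

#' Build a named scenario template
#'
#' Assembles a complete simulation scenario: tissue geometry, identity fields,
#' CUC pattern, the auxin source (the central cell of the second row, standing
#' for the distal auxin maximum of the leaf tip), uniform initial auxin, and
#' the initial PIN allocation rule.
#'
#' Scenarios: `"wt"` carries the patterned CUC field; `"cuc_mutant"` has
#' cuc = 0 everywhere; `"clone"` forces cuc = cuc_max on the listed clone
#' cells (by default with the background pattern suppressed, emulating an
#' ectopic clone in tissue without endogenous band CUC; set
#' `clone_background = "pattern"` to keep the wild-type pattern elsewhere).
#'
#' @param name One of `"wt"`, `"cuc_mutant"`, `"clone"`.
#' @param n_rows,n_cols Grid dimensions (defaults 20 x 5).
#' @param md_width,prox_start_row,prox_ramp_rows Identity-field geometry.
#' @param cuc_max Maximum CUC concentration (a.u.).
#' @param clone_cells For `"clone"`: a matrix or data.frame with columns
#'   (row, col), or a list of length-2 vectors.
#' @param clone_background `"none"` (default) or `"pattern"`.
#' @param init_auxin Uniform initial auxin concentration (a.u.).
#' @param init_pin Initial PIN allocation rule: `"uniform"` (equal share per
#'   existing membrane) or `"apical"` (all PIN on the distal membrane).
#' @return A `margin_template` object.
#' @examples
#' tpl <- make_template("wt")
#' tpl
#' @export
make_template <- function(name = c("wt", "cuc_mutant", "clone"),
                          n_rows = 20, n_cols = 5,
                          md_width = 2, prox_start_row = 4,
                          prox_ramp_rows = 2, cuc_max = 2,
                          clone_cells = NULL,
                          clone_background = c("none", "pattern"),
                          init_auxin = 0.1,
                          init_pin = c("apical", "uniform")) {
  name <- match.arg(name)
  init_pin <- match.arg(init_pin)
  clone_background <- match.arg(clone_background)
  tissue <- build_grid(n_rows, n_cols)
  tissue <- assign_identity_fields(tissue, md_width, prox_start_row,
                                   prox_ramp_rows)
  clone_ids <- integer(0)
  if (name == "clone") {
    if (is.null(clone_cells) || NROW(clone_cells) == 0)
      stop("clone scenario requires a non-empty clone_cells list")
    cc <- .as_cell_matrix(clone_cells)
    bad <- cc[, 1] < 1 | cc[, 1] > tissue$n_rows |
      cc[, 2] < 1 | cc[, 2] > tissue$n_cols
    if (any(bad))
      stop("clone cells outside the grid: ",
           paste(sprintf("(%d,%d)", cc[bad, 1], cc[bad, 2]), collapse = ", "))
    clone_ids <- .cell_id(tissue, cc[, 1], cc[, 2])
  } else if (!is.null(clone_cells) && NROW(clone_cells) > 0) {
    stop("clone_cells are only allowed for the clone scenario")
  }
  tissue <- switch(name,
    wt = set_cuc_pattern(tissue, cuc_max),
    cuc_mutant = set_cuc_pattern(tissue, 0),
    clone = {
      t2 <- if (clone_background == "pattern")
        set_cuc_pattern(tissue, cuc_max)
      else set_cuc_pattern(tissue, 0)
      t2$cuc[clone_ids] <- cuc_max
      t2$cuc_max <- cuc_max
      t2
    })
  src <- .cell_id(tissue, 2L, tissue$mid_col)
  tissue$is_source[src] <- TRUE
  structure(list(
    name = name,
    tissue = tissue,
    clone_cells = clone_ids,
    init_auxin = rep(init_auxin, tissue$n_cells),
    init_auxin_level = init_auxin,
    init_pin = init_pin,
    geometry = list(n_rows = n_rows, n_cols = n_cols, md_width = md_width,
                    prox_start_row = prox_start_row,
                    prox_ramp_rows = prox_ramp_rows, cuc_max = cuc_max,
                    clone_background = clone_background)
  ), class = "margin_template")
}

.as_cell_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (ncol(x) != 2) stop("clone_cells must have two columns (row, col)")
  x
}

#' @export
print.margin_template <- function(x, ...) {
  cat("Margin scenario template '", x$name, "'\n", sep = "")
  print(x$tissue)
  cat("  initial auxin: ", format(x$init_auxin_level),
      " (uniform); initial PIN: ", x$init_pin, "\n", sep = "")
  if (length(x$clone_cells))
    cat("  clone cells: ", length(x$clone_cells), "\n", sep = "")
  invisible(x)
}

#' Write / read a scenario template as a structured text config
#'
#' Templates serialize to a nested key-value (YAML) file with keys
#' `grid.rows`, `grid.cols`, `md.width`, `prox.start_row`, `prox.ramp_rows`,
#' `cuc.max`, `scenario.name`, `scenario.clone_cells`,
#' `scenario.clone_background`, `init.auxin`, `init.pin`. The round trip is
#' lossless: `read_template(write_template(tpl, f))` reconstructs a template
#' equal in all fields.
#'
#' @param template A `margin_template`.
#' @param path Output (input) file path.
#' @return `write_template` returns `path` invisibly; `read_template` returns
#'   a `margin_template`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "margin_template"))
  g <- template$geometry
  tis <- template$tissue
  clone <- if (length(template$clone_cells))
    lapply(template$clone_cells,
           function(i) c(tis$row[i], tis$col[i]))
  else list()
  cfg <- list(
    grid = list(rows = g$n_rows, cols = g$n_cols),
    md = list(width = g$md_width),
    prox = list(start_row = g$prox_start_row, ramp_rows = g$prox_ramp_rows),
    cuc = list(max = g$cuc_max),
    scenario = list(name = template$name,
                    clone_cells = clone,
                    clone_background = g$clone_background),
    init = list(auxin = template$init_auxin_level, pin = template$init_pin)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("grid", "md", "prox", "cuc", "scenario", "init")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("template config is missing sections: ", paste(miss, collapse = ", "))
  clone <- cfg$scenario$clone_cells
  make_template(
    name = cfg$scenario$name,
    n_rows = cfg$grid$rows, n_cols = cfg$grid$cols,
    md_width = cfg$md$width,
    prox_start_row = cfg$prox$start_row,
    prox_ramp_rows = cfg$prox$ramp_rows,
    cuc_max = cfg$cuc$max,
    clone_cells = if (length(clone)) clone else NULL,
    clone_background = if (is.null(cfg$scenario$clone_background)) "none"
                       else cfg$scenario$clone_background,
    init_auxin = cfg$init$auxin,
    init_pin = cfg$init$pin
  )
}

#' Export a tissue as a delimited per-cell table
#'
#' One row per cell with columns `row,col,md,prox,cuc,is_source` (1-based
#' indices), written as CSV.
#'
#' @param tissue A `margin_tissue`.
#' @param path Output file path.
#' @return The exported data.frame, invisibly.
#' @export
export_tissue <- function(tissue, path) {
  stopifnot(inherits(tissue, "margin_tissue"))
  df <- data.frame(row = tissue$row, col = tissue$col,
                   md = tissue$md, prox = tissue$prox, cuc = tissue$cuc,
                   is_source = as.integer(tissue$is_source))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
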