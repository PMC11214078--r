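# Leaf-silhouette morphometrics: perimeter, convex hull, and the Normalized
# Difference Margin Complexity
#   NDMC = (P_contour - P_hull) / (P_contour + P_hull),
# a dimensionless margin-complexity score that is 0 for convex silhouettes
# and invariant to rotation, translation and uniform scaling.

#' Construct a leaf silhouette polygon
#'
#' A closed simple polygon from an ordered vertex list. A duplicated closing
#' vertex is dropped; orientation is normalized to counterclockwise; strict
#' self-intersection validation can be overridden for dirty traces.
#'
#' @param x Two-column matrix/data.frame of vertices, or an x vector.
#' @param y Optional y vector when `x` is a vector.
#' @param name Optional label (e.g. genotype).
#' @param validate Check simplicity (no self-intersection)? Default TRUE.
#' @return A `leaf_silhouette`: numeric matrix of vertices (columns x, y)
#'   with attributes `name`.
#' @export
leaf_silhouette <- function(x, y = NULL, name = NULL, validate = TRUE) {
  v <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (ncol(v) != 2) stop("vertices must have two columns (x, y)")
  storage.mode(v) <- "double"
  if (nrow(v) >= 2 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3)
    stop("a silhouette needs >= 3 distinct vertices (got ", nrow(v), ")")
  if (anyNA(v) || any(!is.finite(v))) stop("vertices must be finite")
  if (validate && .self_intersects(v))
    stop("polygon is self-intersecting; pass validate = FALSE to override")
  if (.signed_area(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  colnames(v) <- c("x", "y")
  structure(v, class = "leaf_silhouette", name = name)
}

#' @export
print.leaf_silhouette <- function(x, ...) {
  nm <- attr(x, "name")
  cat("Leaf silhouette", if (!is.null(nm)) paste0(" '", nm, "'"), ": ",
      nrow(x), " vertices, perimeter ", format(perimeter(x), digits = 5),
      ", NDMC ", format(ndmc(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.leaf_silhouette <- function(x, hull = TRUE, ...) {
  graphics::plot(x[, 1], x[, 2], type = "n", asp = 1, xlab = "x (mm)",
                 ylab = "y (mm)", ...)
  graphics::polygon(x[, 1], x[, 2], border = "darkgreen", lwd = 2)
  if (hull) {
    h <- convex_hull(x)
    graphics::polygon(h[, 1], h[, 2], border = "grey50", lty = 2)
  }
  invisible(x)
}

.signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

# O(n^2) strict segment-intersection check over non-adjacent edges.
.self_intersects <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  for (a in seq_len(n - 2)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (sharing a vertex), incl. the (1, n) wrap pair
      if (b == a + 1 || (a == 1 && b == n)) next
      if (.segments_cross(v[a, ], v[j[a], ], v[b, ], v[j[b], ])) return(TRUE)
    }
  }
  FALSE
}

.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Perimeter of a closed polygon contour
#'
#' @param polygon A `leaf_silhouette` or two-column vertex matrix (>= 3
#'   vertices).
#' @return Total edge length of the closed contour.
#' @examples
#' sq <- leaf_silhouette(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' perimeter(sq)  # 4
#' @export
perimeter <- function(polygon) {
  v <- .as_vertices(polygon)
  j <- c(2:nrow(v), 1)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

.as_vertices <- function(polygon) {
  v <- unclass(polygon)
  v <- as.matrix(v)
  if (ncol(v) != 2 || nrow(v) < 3)
    stop("polygon must be a matrix of >= 3 (x, y) vertices")
  v
}

#' Convex hull of a polygon's vertex set
#'
#' Computed with [grDevices::chull()]; returned counterclockwise as a
#' `leaf_silhouette`. Collinear vertex sets (degenerate hulls with < 3
#' extreme points) are rejected. The hull perimeter never exceeds the
#' contour perimeter (asserted).
#'
#' @param polygon A `leaf_silhouette` or vertex matrix.
#' @return The hull as a `leaf_silhouette`.
#' @export
convex_hull <- function(polygon) {
  v <- .as_vertices(polygon)
  idx <- grDevices::chull(v[, 1], v[, 2])
  if (length(idx) < 3)
    stop("degenerate hull: vertices are collinear")
  h <- v[idx, , drop = FALSE]
  if (.signed_area(h) < 0) h <- h[nrow(h):1, , drop = FALSE]
  stopifnot(perimeter(h) <= perimeter(v) * (1 + 1e-12))
  leaf_silhouette(h, validate = FALSE, name = attr(polygon, "name"))
}

#' Normalized Difference Margin Complexity
#'
#' NDMC = (P_contour - P_hull) / (P_contour + P_hull), in \[0, 1). Exactly 0
#' when the silhouette is convex (the hull uses every vertex), and invariant
#' to rotation, translation and uniform scaling.
#'
#' @param polygon A `leaf_silhouette` or vertex matrix.
#' @return Dimensionless complexity score.
#' @examples
#' L <- leaf_silhouette(cbind(c(0, 2, 2, 1, 1, 0), c(0, 0, 1, 1, 2, 2)))
#' ndmc(L)  # (8 - (6 + sqrt(2))) / (8 + (6 + sqrt(2)))
#' @export
ndmc <- function(polygon) {
  v <- .as_vertices(polygon)
  idx <- grDevices::chull(v[, 1], v[, 2])
  if (length(idx) == nrow(v)) return(0)  # convex: hull == contour, exactly 0
  p_c <- perimeter(v)
  p_h <- perimeter(convex_hull(v))
  max(0, (p_c - p_h) / (p_c + p_h))
}

#' Read / write a silhouette
#'
#' Supported formats: two-column delimited vertex text (comma or whitespace
#' separated, `#` comments), or an SVG whose first `<path>` uses only
#' straight-line commands (M/m, L/l, H/h, V/v, Z/z); curved paths must be
#' flattened upstream.
#'
#' @param path File path; format detected from the `.svg` extension.
#' @param silhouette A `leaf_silhouette` (written as two-column CSV).
#' @param name,validate Passed to [leaf_silhouette()].
#' @return A `leaf_silhouette`.
#' @export
read_silhouette <- function(path, name = NULL, validate = TRUE) {
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    v <- .parse_svg_path(path)
  } else {
    first <- readLines(path, n = 1)
    sep <- if (grepl(",", first)) "," else ""
    df <- utils::read.table(path, sep = sep, comment.char = "#",
                            header = grepl("[A-Za-z]", first))
    v <- as.matrix(df[, 1:2])
  }
  leaf_silhouette(v, name = name, validate = validate)
}

#' @rdname read_silhouette
#' @export
write_silhouette <- function(silhouette, path) {
  v <- .as_vertices(silhouette)
  utils::write.csv(data.frame(x = v[, 1], y = v[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

.parse_svg_path <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//*[local-name() = 'path']")
  if (!length(nodes)) stop("no <path> element found in SVG")
  d <- xml2::xml_attr(nodes[[1]], "d")
  toks <- regmatches(d, gregexpr("[MmLlHhVvZzCcSsQqTtAa]|-?[0-9.eE+]+", d))[[1]]
  pts <- matrix(numeric(0), 0, 2)
  cur <- c(0, 0); cmd <- NULL; k <- 1
  while (k <= length(toks)) {
    t <- toks[k]
    if (grepl("^[A-Za-z]$", t)) {
      if (t %in% c("C", "c", "S", "s", "Q", "q", "T", "t", "A", "a"))
        stop("SVG path uses curve command '", t,
             "'; flatten curves to line segments first")
      cmd <- t; k <- k + 1
      if (cmd %in% c("Z", "z")) next
    } else {
      if (is.null(cmd)) stop("malformed SVG path data")
      if (cmd %in% c("M", "L", "m", "l")) {
        xy <- as.numeric(toks[k:(k + 1)]); k <- k + 2
        if (cmd %in% c("m", "l")) xy <- cur + xy
        # implicit lineto after moveto
        if (cmd == "M") cmd <- "L" else if (cmd == "m") cmd <- "l"
      } else if (cmd %in% c("H", "h")) {
        x <- as.numeric(toks[k]); k <- k + 1
        xy <- c(if (cmd == "h") cur[1] + x else x, cur[2])
      } else { # V, v
        yv <- as.numeric(toks[k]); k <- k + 1
        xy <- c(cur[1], if (cmd == "v") cur[2] + yv else yv)
      }
      cur <- xy
      pts <- rbind(pts, xy)
    }
  }
  pts
}
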