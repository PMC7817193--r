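#' Maze specification for the lattice spatial-learning task
#'
#' The task arena is a rectangular lattice of square cells (the "open field")
#' with a start box (S) below, a goal box (G) above, and a peripheral return
#' alleyway along the left side. Two lattice cells act as reward checkpoints:
#' C1 (default: fourth column from the left, second row from the bottom) and
#' C2 (default: second column from the left, fourth row from the bottom).
#' Animals run S-C1-G before reward relocation and S-C2-G after learning.
#'
#' Coordinates are in cm. The lattice spans `[0, cols*cell] x [0, rows*cell]`.
#' The start and goal anchors are placed slightly asymmetrically (12 cm below,
#' 18 cm above the lattice) so that the six canonical path templates have
#' pairwise-distinct lengths except for the physically identical G-C2/C2-G
#' corridor.
#'
#' @param lattice_cols,lattice_rows lattice size in cells (>= 4).
#' @param cell_size cell edge length in cm.
#' @param c1_cell,c2_cell checkpoint lattice indices `c(col, row)`, 1-based
#'   from left/bottom.
#' @return An object of class `maze_spec`: lattice geometry, region polygons
#'   (axis-aligned boxes), checkpoint centers, and the six path templates
#'   (piecewise-linear waypoint matrices with cumulative arc length).
#' @examples
#' mz <- make_maze()
#' names(mz$paths)
#' @export
make_maze <- function(lattice_cols = 5L, lattice_rows = 5L, cell_size = 20,
                      c1_cell = c(4L, 2L), c2_cell = c(2L, 4L)) {
  if (lattice_cols < 4L || lattice_rows < 4L)
    stop("lattice must be at least 4x4")
  if (cell_size <= 0) stop("cell_size must be positive")
  chk <- function(cc, nm) {
    if (length(cc) != 2L || any(cc < 1L) || cc[1] > lattice_cols || cc[2] > lattice_rows)
      stop(nm, " checkpoint cell outside lattice")
    as.integer(cc)
  }
  c1_cell <- chk(c1_cell, "C1"); c2_cell <- chk(c2_cell, "C2")
  if (identical(c1_cell, c2_cell)) stop("C1 and C2 must be distinct lattice cells")

  W <- lattice_cols * cell_size
  H <- lattice_rows * cell_size
  cell_center <- function(cc) c((cc[1] - 0.5) * cell_size, (cc[2] - 0.5) * cell_size)
  c1 <- cell_center(c1_cell); c2 <- cell_center(c2_cell)

  s_anchor <- c(W / 2, -0.6 * cell_size)
  g_anchor <- c(W / 2, H + 0.9 * cell_size)
  half <- 0.5 * cell_size
  start_box <- c(W / 2 - half, W / 2 + half, -1.2 * cell_size, 0)       # x0 x1 y0 y1
  goal_box  <- c(W / 2 - half, W / 2 + half, H, H + 1.2 * cell_size)
  alley_x <- -1.25 * cell_size

  wp <- function(...) {
    m <- do.call(rbind, list(...))
    colnames(m) <- c("x", "y")
    m
  }
  # Manhattan-style routes through cell centers; first/last waypoint inside
  # the stated start/end regions.
  row_y <- function(cc) (cc[2] - 0.5) * cell_size
  col_x <- function(cc) (cc[1] - 0.5) * cell_size
  paths <- list(
    "S-C1"  = wp(s_anchor, c(s_anchor[1], row_y(c1_cell)), c1),
    "C1-G"  = wp(c1, c(col_x(c1_cell), H - half), c(g_anchor[1], H - half), g_anchor),
    "G-C2"  = wp(g_anchor, c(g_anchor[1], H - half), c(col_x(c2_cell), H - half), c2),
    "S-C2"  = wp(s_anchor, c(s_anchor[1], half), c(col_x(c2_cell), half), c2),
    "C2-G"  = wp(c2, c(col_x(c2_cell), H - half), c(g_anchor[1], H - half), g_anchor),
    "return" = wp(g_anchor, c(alley_x, g_anchor[2]), c(alley_x, s_anchor[2]), s_anchor)
  )
  paths <- lapply(paths, function(m) {
    seg <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    list(waypoints = m, cum_len = c(0, cumsum(seg)), length = sum(seg))
  })

  structure(list(
    lattice_cols = lattice_cols, lattice_rows = lattice_rows,
    cell_size = cell_size, width = W, height = H,
    c1_cell = c1_cell, c2_cell = c2_cell, c1_xy = c1, c2_xy = c2,
    s_anchor = s_anchor, g_anchor = g_anchor,
    start_box = start_box, goal_box = goal_box,
    alley_box = c(alley_x - half, alley_x + half, -1.2 * cell_size, H + 1.2 * cell_size),
    paths = paths
  ), class = "maze_spec")
}

#' @export
print.maze_spec <- function(x, ...) {
  cat(sprintf("<maze_spec> %dx%d lattice, cell %.0f cm; C1=(%d,%d) C2=(%d,%d)\n",
              x$lattice_cols, x$lattice_rows, x$cell_size,
              x$c1_cell[1], x$c1_cell[2], x$c2_cell[1], x$c2_cell[2]))
  for (p in names(x$paths))
    cat(sprintf("  %-7s %6.1f cm\n", p, x$paths[[p]]$length))
  invisible(x)
}

#' Canonical path labels
#'
#' The five analyzed field paths plus the return alleyway.
#' @export
path_labels <- function() c("S-C1", "C1-G", "G-C2", "S-C2", "C2-G", "return")

#' Length of a path template in cm
#' @param maze a `maze_spec`.
#' @param path path label.
#' @export
path_length <- function(maze, path) maze$paths[[path]]$length

#' Interpolate a point at linearized position `s` (cm) along a path template
#' @inheritParams path_length
#' @param s arc-length positions in cm (clamped to `[0, L]`).
#' @return matrix with columns x, y.
#' @export
path_point <- function(maze, path, s) {
  tpl <- maze$paths[[path]]
  s <- pmin(pmax(s, 0), tpl$length)
  wp <- tpl$waypoints; cl <- tpl$cum_len
  seg <- pmin(findInterval(s, cl, rightmost.closed = TRUE), nrow(wp) - 1L)
  frac <- (s - cl[seg]) / pmax(cl[seg + 1L] - cl[seg], 1e-12)
  cbind(x = wp[seg, 1] + frac * (wp[seg + 1L, 1] - wp[seg, 1]),
        y = wp[seg, 2] + frac * (wp[seg + 1L, 2] - wp[seg, 2]))
}

#' Project 2D points onto a path template (linearization)
#'
#' Each path is its own 1D axis running from its start landmark to its
#' destination. Returns the arc-length coordinate of the nearest point on
#' the polyline and the orthogonal distance to it.
#'
#' @inheritParams path_length
#' @param x,y point coordinates in cm.
#' @return data.frame with `lin` (cm along path) and `dist` (cm off path).
#' @export
linearize_position <- function(maze, path, x, y) {
  tpl <- maze$paths[[path]]
  wp <- tpl$waypoints; cl <- tpl$cum_len
  n <- length(x)
  best_d2 <- rep(Inf, n); best_s <- numeric(n)
  for (k in seq_len(nrow(wp) - 1L)) {
    ax <- wp[k, 1]; ay <- wp[k, 2]
    bx <- wp[k + 1L, 1]; by <- wp[k + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(pmax(((x - ax) * vx + (y - ay) * vy) / L2, 0), 1) else 0
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- dx * dx + dy * dy
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_s[hit] <- cl[k] + t[hit] * sqrt(L2)
  }
  data.frame(lin = best_s, dist = sqrt(best_d2))
}

in_box <- function(x, y, b) x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]

lattice_cell_index <- function(maze, x, y) {
  # 1-based (col-1)*rows + row for points inside the lattice, NA outside
  inside <- x >= 0 & x < maze$width & y >= 0 & y < maze$height
  col <- pmin(pmax(floor(x / maze$cell_size) + 1L, 1L), maze$lattice_cols)
  row <- pmin(pmax(floor(y / maze$cell_size) + 1L, 1L), maze$lattice_rows)
  idx <- (col - 1L) * maze$lattice_rows + row
  idx[!inside] <- NA_integer_
  idx
}

#' Region label for arbitrary positions
#'
#' @inheritParams path_length
#' @param x,y coordinates in cm.
#' @return character vector in `{"start","goal","c1","c2","field","alleyway"}`.
#' @export
region_of <- function(maze, x, y) {
  out <- rep("alleyway", length(x))
  idx <- lattice_cell_index(maze, x, y)
  out[!is.na(idx)] <- "field"
  c1i <- (maze$c1_cell[1] - 1L) * maze$lattice_rows + maze$c1_cell[2]
  c2i <- (maze$c2_cell[1] - 1L) * maze$lattice_rows + maze$c2_cell[2]
  out[!is.na(idx) & idx == c1i] <- "c1"
  out[!is.na(idx) & idx == c2i] <- "c2"
  out[in_box(x, y, maze$start_box)] <- "start"
  out[in_box(x, y, maze$goal_box)] <- "goal"
  out
}

#' Analogous-path correspondence groups for context-dependent coding
#'
#' Paths whose final approach is behaviorally equivalent: approaching a
#' checkpoint (S-C1, S-C2, G-C2) and approaching the goal area (C1-G, C2-G).
#' Context-dependent fields sit at matching distances from the destination
#' on paths within a group.
#' @return named list of character vectors.
#' @export
path_correspondence <- function() {
  list(checkpoint = c("S-C1", "S-C2", "G-C2"),
       goal = c("C1-G", "C2-G"))
}
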