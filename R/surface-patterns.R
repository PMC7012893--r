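#' Construct a labeled two-dimensional point pattern
#'
#' Validates and tags a table of particle coordinates (nm) with species
#' labels inside a rectangular region, as digitized from micrographs of
#' nanoparticle or enzyme placements.
#'
#' @param data Data frame with columns `x_nm`, `y_nm`, `species`.
#' @param region Rectangle `c(x_min, y_min, x_max, y_max)` in nm; defaults
#'   to the bounding box of the points.
#'
#' @return A tibble of class `point_pattern` with a `region` attribute.
#' @examples
#' pts <- tibble::tibble(x_nm = c(0, 3), y_nm = c(0, 4), species = c("A", "B"))
#' point_pattern(pts, region = c(0, 0, 10, 10))
#' @export
point_pattern <- function(data, region = NULL) {
  data <- as_tibble(data)
  req <- c("x_nm", "y_nm", "species")
  if (!all(req %in% names(data))) {
    stop_bad_arg("`data` must have columns x_nm, y_nm, species.")
  }
  if (nrow(data) == 0L) stop_bad_arg("a point pattern needs at least one point.")
  if (is.null(region)) {
    region <- c(min(data$x_nm), min(data$y_nm), max(data$x_nm), max(data$y_nm))
  }
  if (length(region) != 4L || region[3] < region[1] || region[4] < region[2]) {
    stop_bad_arg("`region` must be c(x_min, y_min, x_max, y_max) with nonnegative extent.")
  }
  inside <- data$x_nm >= region[1] & data$x_nm <= region[3] &
    data$y_nm >= region[2] & data$y_nm <= region[4]
  if (!all(inside)) {
    stop_bad_arg(sprintf("%d point(s) fall outside the region.", sum(!inside)))
  }
  attr(data, "region") <- as.numeric(region)
  class(data) <- unique(c("point_pattern", class(data)))
  data
}

pattern_region <- function(pattern) {
  region <- attr(pattern, "region")
  if (is.null(region)) {
    region <- c(
      min(pattern$x_nm), min(pattern$y_nm),
      max(pattern$x_nm), max(pattern$y_nm)
    )
  }
  region
}

#' Heterotype nearest-neighbour distances
#'
#' For every point of species `from`, the Euclidean distance to the
#' nearest point of species `to` — the "hetero-pair" distance used to
#' quantify how closely two particle species are interleaved on a
#' surface. Rows follow the input order of the `from` points.
#'
#' The default is directional (each A to its nearest B, the B point may be
#' reused). `mode = "mutual"` instead retains only mutual nearest-neighbour
#' pairs (A's nearest B whose own nearest A is that A), a stricter
#' one-to-one pairing; the distances of those pairs are returned once each.
#'
#' @param pattern A `point_pattern` (or data frame with `x_nm`, `y_nm`,
#'   `species`).
#' @param from,to Species labels. Default: the first two distinct species
#'   in order of appearance.
#' @param mode `"nearest"` (default) or `"mutual"`.
#' @param guard_nm Optional guard zone: `from` points closer than this to
#'   the region boundary are dropped before measuring (reduces edge bias in
#'   property checks). Default 0, i.e. raw distances with no edge
#'   correction.
#'
#' @return Tibble with the anchor coordinates and `distance_nm`.
#' @examples
#' pts <- tibble::tibble(
#'   x_nm = c(0, 3), y_nm = c(0, 4),
#'   species = c("A", "B")
#' )
#' heterotype_nn_distances(point_pattern(pts))
#' @export
heterotype_nn_distances <- function(pattern, from = NULL, to = NULL,
                                    mode = c("nearest", "mutual"),
                                    guard_nm = 0) {
  mode <- match.arg(mode)
  pattern <- as_tibble(pattern)
  species <- unique(pattern$species)
  if (is.null(from)) from <- species[1]
  if (is.null(to)) to <- setdiff(species, from)[1]
  for (lab in c(from, to)) {
    if (is.na(lab) || !lab %in% species) {
      stop_bad_arg(sprintf("species '%s' is absent from the pattern.", lab))
    }
  }
  a <- pattern[pattern$species == from, , drop = FALSE]
  b <- pattern[pattern$species == to, , drop = FALSE]
  if (guard_nm > 0) {
    region <- pattern_region(pattern)
    keep <- a$x_nm >= region[1] + guard_nm & a$x_nm <= region[3] - guard_nm &
      a$y_nm >= region[2] + guard_nm & a$y_nm <= region[4] - guard_nm
    a <- a[keep, , drop = FALSE]
    if (nrow(a) == 0L) stop_bad_arg("guard zone removed every anchor point.")
  }
  d2 <- outer(a$x_nm, b$x_nm, "-")^2 + outer(a$y_nm, b$y_nm, "-")^2
  nn_idx <- max.col(-d2, ties.method = "first")
  out <- tibble(
    x_nm = a$x_nm, y_nm = a$y_nm, species = a$species,
    neighbor = nn_idx,
    distance_nm = sqrt(d2[cbind(seq_len(nrow(a)), nn_idx)])
  )
  if (mode == "mutual") {
    # keep (a, b) only when b's nearest 'from'-point is a
    back <- max.col(-t(d2), ties.method = "first")
    out <- out[back[out$neighbor] == seq_len(nrow(out)), , drop = FALSE]
  }
  out$neighbor <- NULL
  out
}

#' Grid heatmap of pair distances
#'
#' Partitions the pattern's region into a `grid_k` x `grid_k` matrix of
#' cells (e.g. 6 x 6 cells of 50 x 50 nm for a 300 x 300 nm field) and
#' summarizes the pair distances anchored in each cell. Each distance is
#' assigned to the cell containing its anchor point; cells are half-open
#' `[lo, hi)` with the last row/column closed, and indices are 0-based.
#' Empty cells carry `mean_nm = NA`, never zero.
#'
#' @param pattern The `point_pattern` the distances were measured on (its
#'   region defines the grid).
#' @param distances Tibble from [heterotype_nn_distances()] (anchor
#'   coordinates plus `distance_nm`).
#' @param grid_k Cells per side (default 6).
#'
#' @return Tibble of class `grid_summary` with `cell_row`, `cell_col`
#'   (0-based), `n`, `mean_nm`, and attribute `cell_size_nm`.
#' @export
grid_heatmap <- function(pattern, distances, grid_k = 6) {
  if (!is.numeric(grid_k) || length(grid_k) != 1L || grid_k < 1) {
    stop_bad_arg("`grid_k` must be a positive integer.")
  }
  grid_k <- as.integer(grid_k)
  region <- pattern_region(pattern)
  wx <- (region[3] - region[1]) / grid_k
  wy <- (region[4] - region[2]) / grid_k
  col_of <- pmin(floor((distances$x_nm - region[1]) / wx), grid_k - 1)
  row_of <- pmin(floor((distances$y_nm - region[2]) / wy), grid_k - 1)
  cells <- tidyr::expand_grid(
    cell_row = 0:(grid_k - 1),
    cell_col = 0:(grid_k - 1)
  )
  assigned <- tibble(
    cell_row = row_of, cell_col = col_of,
    distance_nm = distances$distance_nm
  ) |>
    dplyr::group_by(.data$cell_row, .data$cell_col) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_nm = mean(.data$distance_nm),
      .groups = "drop"
    )
  out <- dplyr::left_join(cells, assigned, by = c("cell_row", "cell_col")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  attr(out, "cell_size_nm") <- c(wx, wy)
  class(out) <- c("grid_summary", class(out))
  out
}

#' Boxplot-style summary of a distance sample
#'
#' Mean, sample standard deviation (n - 1 denominator), median, quartiles
#' (type-7 linear interpolation) and Tukey whiskers (the most extreme
#' observations within 1.5 x IQR of the box) for a set of distances — the
#' statistics drawn in inter-particle distance boxplots.
#'
#' @param distances Numeric vector of distances, or a tibble with a
#'   `distance_nm` column.
#'
#' @return One-row tibble: `n`, `mean_nm`, `sd_nm`, `median_nm`, `q1_nm`,
#'   `q3_nm`, `whisker_low_nm`, `whisker_high_nm`.
#' @examples
#' distance_summary(c(1, 2, 3, 4, 5))
#' @export
distance_summary <- function(distances) {
  if (is.data.frame(distances)) distances <- distances$distance_nm
  d <- as.numeric(distances)
  if (length(d) == 0L || anyNA(d)) {
    stop_bad_arg("`distances` must be a non-empty numeric vector without NA.")
  }
  q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  tibble(
    n = length(d),
    mean_nm = mean(d),
    sd_nm = if (length(d) > 1L) sd(d) else NA_real_,
    median_nm = q[2],
    q1_nm = q[1],
    q3_nm = q[3],
    whisker_low_nm = min(d[d >= lo_fence]),
    whisker_high_nm = max(d[d <= hi_fence])
  )
}

#' @describeIn grid_heatmap Tile heatmap of mean pair distance per cell.
#' @param object A `grid_summary`.
#' @param ... Unused.
#' @export
autoplot.grid_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_col, y = .data$cell_row, fill = .data$mean_nm)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "mean\ndistance (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row") +
    ggplot2::theme_minimal()
}

#' @describeIn point_pattern Scatter of the pattern colored by species.
#' @param object A `point_pattern`.
#' @param ... Unused.
#' @export
autoplot.point_pattern <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x_nm, y = .data$y_nm, color = .data$species)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
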