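# Topographic scalp maps: thin-plate-spline interpolation of per-electrode
# scalars over the unit-disc head projection, with untested regions masked.

tps_basis <- function(r) ifelse(r < 1e-12, 0, r^2 * log(r))

# exact thin-plate spline interpolant through (x, y, v); returns a
# function of (x, y) matrices/vectors
tps_fit <- function(x, y, v) {
  n <- length(x)
  D <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  K <- tps_basis(D)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(v, 0, 0, 0)
  coef <- solve(A, rhs)
  w <- coef[seq_len(n)]
  a <- coef[n + 1:3]
  function(px, py) {
    Dp <- sqrt(outer(px, x, "-")^2 + outer(py, y, "-")^2)
    as.vector(tps_basis(Dp) %*% w + a[1] + a[2] * px + a[3] * py)
  }
}

make_topomap <- function(values, montage, grid_n = 67) {
  present <- names(values)[!is.na(values)]
  idx <- match(present, montage$name)
  if (length(present) < 3) {
    stop("topographic interpolation needs >= 3 electrodes with values",
         call. = FALSE)
  }
  x <- montage$x[idx]; y <- montage$y[idx]
  if (abs(det(cov(cbind(x, y)))) < 1e-12) {
    stop("electrode positions are collinear; cannot interpolate",
         call. = FALSE)
  }
  fit <- tps_fit(x, y, values[present])
  gx <- seq(-1, 1, length.out = grid_n)
  gy <- seq(-1, 1, length.out = grid_n)
  pts <- expand.grid(x = gx, y = gy)
  inside <- pts$x^2 + pts$y^2 <= 1 + 1e-9
  z <- rep(NA_real_, nrow(pts))
  z[inside] <- fit(pts$x[inside], pts$y[inside])
  # blank the surface over untested electrodes: grid cells whose nearest
  # electrode carries no value are masked
  untested <- setdiff(montage$name, present)
  if (length(untested) > 0) {
    d2all <- vapply(seq_len(nrow(montage)), function(i) {
      (pts$x - montage$x[i])^2 + (pts$y - montage$y[i])^2
    }, numeric(nrow(pts)))
    nearest <- montage$name[max.col(-d2all)]
    z[nearest %in% untested] <- NA_real_
  }
  mask <- matrix(inside, grid_n, grid_n)
  structure(
    list(values = values, grid_x = gx, grid_y = gy,
         grid = matrix(z, grid_n, grid_n), mask = mask,
         untested = untested, montage = montage,
         interp = fit),
    class = "topomap"
  )
}

#' Topographic map of per-electrode group medians
#'
#' Computes the group median of `alpha_<electrode>` for every electrode
#' present in the metric table and interpolates it over the scalp disc
#' with an exact thin-plate spline (the surface passes through the
#' electrode values). Electrodes absent from the table are rendered
#' blank.
#'
#' @param metric_table data frame with `group` and `alpha_<electrode>`
#'   columns
#' @param group `"case"` or `"control"`
#' @param montage a [standard_montage()] table
#' @param electrodes electrodes to map (default: all with a column)
#' @return an object of class `topomap`
#' @export
median_topomap <- function(metric_table, group,
                           montage = standard_montage(),
                           electrodes = NULL) {
  if (is.null(electrodes)) {
    have <- sub("^alpha_", "", grep("^alpha_", names(metric_table),
                                    value = TRUE))
    electrodes <- intersect(montage$name, have)
  }
  rows <- metric_table$group == group
  if (!any(rows)) stop("no subjects in group '", group, "'", call. = FALSE)
  values <- rep(NA_real_, nrow(montage))
  names(values) <- montage$name
  for (el in electrodes) {
    values[el] <- stats::median(metric_table[[paste0("alpha_", el)]][rows])
  }
  make_topomap(values, montage)
}

#' Topographic map of uncorrected post-hoc p-values
#'
#' Maps the raw Mann-Whitney p-values of a [compare_groups()] result over
#' the tested (ROI) electrodes only; regions under untested electrodes
#' are blank. The conventional display anchors the color scale at the
#' significance level (see [plot.topomap()]).
#'
#' @param comparison a `group_comparison`
#' @param montage a [standard_montage()] table
#' @return an object of class `topomap`
#' @export
pvalue_topomap <- function(comparison, montage = standard_montage()) {
  values <- rep(NA_real_, nrow(montage))
  names(values) <- montage$name
  values[comparison$table$electrode] <- comparison$table$p_raw
  m <- make_topomap(values, montage)
  attr(m, "scale_anchor") <- comparison$alpha_level
  m
}

#' Evaluate a topomap's interpolant at arbitrary scalp positions
#'
#' @param topomap a `topomap`
#' @param x,y coordinates on the unit disc
#' @return interpolated values
#' @export
topomap_at <- function(topomap, x, y) topomap$interp(x, y)

#' @export
plot.topomap <- function(x, main = "", zlim = NULL, ...) {
  z <- x$grid
  if (is.null(zlim)) {
    zlim <- range(z, na.rm = TRUE)
    if (diff(zlim) == 0) zlim <- zlim + c(-1, 1) * max(1e-9, abs(zlim[1]) * 0.01)
  }
  cols <- grDevices::hcl.colors(64, "viridis")
  graphics::image(x$grid_x, x$grid_y, z, asp = 1, col = cols, zlim = zlim,
                  xlab = "", ylab = "", axes = FALSE, main = main)
  th <- seq(0, 2 * pi, length.out = 181)
  graphics::lines(cos(th), sin(th))
  have <- !is.na(x$values)
  graphics::points(x$montage$x[have], x$montage$y[have], pch = 20, cex = 0.6)
  if (any(!have)) {
    graphics::points(x$montage$x[!have], x$montage$y[!have], pch = 4,
                     cex = 0.6, col = "grey60")
  }
  invisible(x)
}

#' Strip plot of IAF distributions stratified by migraine
#'
#' Two panels (with / without comorbid migraine), one point per subject
#' at one electrode, group medians marked with horizontal bars. Empty
#' strata are annotated rather than an error.
#'
#' @param metric_table data frame with `group`, `migraine` and
#'   `iaf_<electrode>` columns
#' @param electrode electrode shown (default "O1")
#' @return invisibly, the list of per-panel data
#' @export
iaf_strata_plot <- function(metric_table, electrode = "O1") {
  col <- paste0("iaf_", electrode)
  if (!col %in% names(metric_table)) {
    stop("metric table lacks column ", col, call. = FALSE)
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  panels <- list(migraine = TRUE, no_migraine = FALSE)
  out <- list()
  for (nm in names(panels)) {
    sel <- metric_table$migraine == panels[[nm]]
    d <- metric_table[sel, , drop = FALSE]
    out[[nm]] <- d
    graphics::plot(NA, xlim = c(0.5, 2.5), ylim = c(7.5, 13.5),
                   xaxt = "n", xlab = "", ylab = "IAF [Hz]",
                   main = paste0(electrode, ", ", gsub("_", " ", nm)))
    graphics::axis(1, at = 1:2, labels = c("case", "control"))
    if (nrow(d) == 0) {
      graphics::text(1.5, 10.5, "empty stratum")
      next
    }
    for (gi in 1:2) {
      grp <- c("case", "control")[gi]
      v <- d[[col]][d$group == grp]
      if (length(v) == 0) {
        graphics::text(gi, 10.5, "empty")
        next
      }
      graphics::points(rep(gi, length(v)) + seq(-0.12, 0.12,
                                                length.out = length(v)),
                       v, pch = 19, col = grDevices::adjustcolor(gi + 1, 0.7))
      graphics::segments(gi - 0.2, stats::median(v), gi + 0.2,
                         stats::median(v), lwd = 3)
    }
  }
  invisible(out)
}
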