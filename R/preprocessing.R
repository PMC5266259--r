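#' arcsinh-transform selected channels
#'
#' Applies the inverse hyperbolic sine, `asinh(x) = ln(x + sqrt(x^2 + 1))`
#' (cofactor 1), to the named channels. The transform is near-linear around
#' zero and logarithmic for large intensities, the standard display/gating
#' scale for cytometry. Channels already transformed are refused, so the
#' transform cannot be applied twice by accident.
#'
#' @param events An `event_matrix`.
#' @param channels Channels to transform; defaults to all.
#' @return An `event_matrix` with the listed channels replaced by their
#'   arcsinh values and recorded in `$transformed`.
#' @export
transform_arcsinh <- function(events, channels = NULL) {
  stopifnot(inherits(events, "event_matrix"))
  all_ch <- colnames(events$values)
  if (is.null(channels)) channels <- all_ch
  missing_ch <- setdiff(channels, all_ch)
  if (length(missing_ch)) {
    stop("channel(s) not present: ", paste(missing_ch, collapse = ", "))
  }
  already <- intersect(channels, events$transformed)
  if (length(already)) {
    stop("channel(s) already arcsinh-transformed: ",
         paste(already, collapse = ", "))
  }
  vals <- events$values
  vals[, channels] <- asinh(vals[, channels])
  event_matrix(vals, all_ch, meta = events$meta,
               transformed = c(events$transformed, channels))
}

#' Define a polygon gate
#'
#' A gate is a simple polygon in a bivariate channel space, with vertices
#' given in transformed coordinates (arcsinh by default, matching how gates
#' are drawn on cytometry plots). Events on the polygon boundary count as
#' inside, a convention fixed for determinism.
#'
#' @param channel_x,channel_y Names of the two gating channels (must differ).
#' @param vertices Numeric matrix or data frame with two columns (x, y) and
#'   at least 3 rows, in order around the polygon.
#' @param transform `"arcsinh"` (vertices are in arcsinh space; event values
#'   are arcsinh-transformed before the point-in-polygon test) or
#'   `"identity"`.
#' @return An object of class `polygon_gate`.
#' @export
polygon_gate <- function(channel_x, channel_y, vertices,
                         transform = c("arcsinh", "identity")) {
  transform <- match.arg(transform)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stop("vertices must be an n x 2 matrix with n >= 3")
  }
  if (any(!is.finite(vertices))) stop("gate vertices must be finite")
  if (identical(channel_x, channel_y)) {
    stop("gating channels must differ")
  }
  if (abs(polygon_area(vertices)) < .Machine$double.eps) {
    stop("degenerate polygon: zero area")
  }
  if (!polygon_is_simple(vertices)) {
    stop("polygon is self-intersecting; gates must be simple polygons")
  }
  structure(list(channel_x = channel_x, channel_y = channel_y,
                 vertices = vertices, transform = transform),
            class = "polygon_gate")
}

#' @export
print.polygon_gate <- function(x, ...) {
  cat("polygon_gate: ", nrow(x$vertices), " vertices in ",
      if (x$transform == "arcsinh") "arcsinh(" else "(",
      x$channel_x, ") x ",
      if (x$transform == "arcsinh") "arcsinh(" else "(",
      x$channel_y, ")\n", sep = "")
  invisible(x)
}

#' Default denoising gate
#'
#' A rectangular gate in arcsinh(FL1-H) x arcsinh(FL3-H) keeping events with
#' both transformed green and red fluorescence above a floor, which removes
#' the low-fluorescence corner where (in)organic debris and instrument noise
#' accumulate in SYBR-Green-stained samples. Per-culture polygon gates should
#' be supplied where available; this rectangle is the configurable fallback.
#'
#' @param lo Lower bound in arcsinh space on both channels (default 1).
#' @param hi Upper bound (default 20, far beyond any stored intensity).
#' @param channel_x,channel_y Gating channels (defaults FL1-H, FL3-H).
#' @return A `polygon_gate`.
#' @export
default_gate <- function(lo = 1, hi = 20, channel_x = "FL1-H",
                         channel_y = "FL3-H") {
  polygon_gate(channel_x, channel_y,
               rbind(c(lo, lo), c(hi, lo), c(hi, hi), c(lo, hi)),
               transform = "arcsinh")
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  sum(v[j, 1L] * v[, 2L] - v[, 1L] * v[j, 2L]) / 2
}

# simple-polygon check: no two non-adjacent edges intersect
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- cross2(b[3:4] - b[1:2], a[1:2] - b[1:2])
    d2 <- cross2(b[3:4] - b[1:2], a[3:4] - b[1:2])
    d3 <- cross2(a[3:4] - a[1:2], b[1:2] - a[1:2])
    d4 <- cross2(a[3:4] - a[1:2], b[3:4] - a[1:2])
    (d1 * d2 < 0 && d3 * d4 < 0)
  }
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (inter(seg[i, ], seg[j, ])) return(FALSE)
    }
  }
  TRUE
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

# Ray-casting point-in-polygon with an explicit on-boundary test; points on
# an edge or vertex are inside. Vectorised over points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-12
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    # boundary: collinear and within the segment's bounding box
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    scale <- max(abs(c(xi, yi, xj, yj, 1)))
    on_seg <- abs(cr) <= eps * scale * scale &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Apply a polygon gate to events
#'
#' Partitions events into those inside and outside the gate. The gate's
#' transform is applied to the two gating channels before the
#' point-in-polygon test; the returned events keep their original stored
#' values. Every event lands in exactly one part and order is preserved, so
#' the inside/outside pair is an exact partition of the input.
#'
#' @param events An `event_matrix`.
#' @param gate A `polygon_gate`.
#' @return A list with `inside` and `outside` event matrices and the logical
#'   membership vector `keep`.
#' @export
apply_gate <- function(events, gate) {
  stopifnot(inherits(events, "event_matrix"), inherits(gate, "polygon_gate"))
  miss <- setdiff(c(gate$channel_x, gate$channel_y), channels(events))
  if (length(miss)) {
    stop("gating channel(s) not present: ", paste(miss, collapse = ", "))
  }
  x <- events$values[, gate$channel_x]
  y <- events$values[, gate$channel_y]
  if (gate$transform == "arcsinh") {
    # gate vertices live in arcsinh space; transform event coordinates
    # unless this channel already carries transformed values
    if (!gate$channel_x %in% events$transformed) x <- asinh(x)
    if (!gate$channel_y %in% events$transformed) y <- asinh(y)
  }
  keep <- points_in_polygon(x, y, gate$vertices)
  list(inside = subset_events(events, keep),
       outside = subset_events(events, !keep),
       keep = keep)
}

#' Pool gated replicates of one axenic culture
#'
#' Applies the same gate to every replicate of a taxon (one fixed gate per
#' culture) and concatenates the gated events into a single pooled event
#' matrix, recording per-replicate gated counts. Pooling precedes any
#' subsampling into in silico communities.
#'
#' @param replicates List of `event_matrix` objects sharing one panel.
#' @param gate A `polygon_gate`; defaults to [default_gate()].
#' @param taxon_id Taxon identifier attached to the sample.
#' @return An object of class `population_sample` with fields `taxon_id`,
#'   `replicates`, `gate`, `pooled` and per-replicate `counts`.
#' @export
pool_replicates <- function(replicates, gate = default_gate(),
                            taxon_id = "population") {
  stopifnot(is.list(replicates), length(replicates) >= 1L,
            all(vapply(replicates, inherits, TRUE, "event_matrix")))
  ref <- channels(replicates[[1L]])
  for (e in replicates[-1L]) {
    if (!identical(channels(e), ref)) {
      diff <- union(setdiff(channels(e), ref), setdiff(ref, channels(e)))
      stop("replicates of '", taxon_id, "' have mismatched panels: ",
           paste(diff, collapse = ", "))
    }
  }
  gated <- lapply(replicates, function(e) apply_gate(e, gate)$inside)
  counts <- vapply(gated, n_events, 0L)
  pooled <- bind_events(gated)
  pooled$meta$replicate_counts <- counts
  pooled$meta$taxon_id <- taxon_id
  structure(list(taxon_id = taxon_id, replicates = replicates, gate = gate,
                 pooled = pooled, counts = counts),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat("population_sample '", x$taxon_id, "': ", length(x$replicates),
      " replicate(s), gated counts ", paste(x$counts, collapse = " + "),
      " = ", cell_count(x), " pooled cells\n", sep = "")
  invisible(x)
}

#' Gated cell count of a population sample
#'
#' The number of events in the pooled, gated event pool. Conversion to a
#' cell density (count per volume) is the caller's arithmetic.
#'
#' @param sample A `population_sample`.
#' @return Integer count.
#' @export
cell_count <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  n_events(sample$pooled)
}

#' Read polygon gate definitions from a YAML config
#'
#' The config maps taxon ids to gate definitions:
#' ```yaml
#' Taxon_A:
#'   channel_x: FL1-H
#'   channel_y: FL3-H
#'   transform: arcsinh
#'   vertices: [[1, 1], [9, 1], [9, 9], [1, 9]]
#' ```
#'
#' @param path Path to the YAML file.
#' @return Named list of `polygon_gate` objects.
#' @export
read_gates_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(g) {
    polygon_gate(g$channel_x, g$channel_y,
                 do.call(rbind, lapply(g$vertices, as.numeric)),
                 transform = if (is.null(g$transform)) "arcsinh" else g$transform)
  })
}
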