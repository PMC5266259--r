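#' The canonical 12-parameter detector panel
#'
#' Channel names of the standard 4-fluorescence / 2-scatter panel, each
#' recorded as pulse area (-A) and height (-H), giving a twelve-variable
#' description of every cell.
#'
#' @return Character vector of the 12 canonical channel names.
#' @export
canonical_panel <- function() {
  c("FL1-A", "FL1-H", "FL2-A", "FL2-H", "FL3-A", "FL3-H",
    "FL4-A", "FL4-H", "FSC-A", "FSC-H", "SSC-A", "SSC-H")
}

#' Construct an event matrix
#'
#' An `event_matrix` is the atom of all processing in cytopop: an events x
#' channels table of raw (untransformed) intensities with named channels and
#' free-form acquisition metadata. Intensities must be finite; channel names
#' must be unique.
#'
#' @param values Numeric matrix (or object coercible to one), events in rows.
#' @param channels Character vector of channel names; defaults to
#'   `colnames(values)`.
#' @param meta Named list of free-form acquisition metadata.
#' @param transformed Character vector of channels already carrying
#'   arcsinh-transformed values (bookkeeping used by [transform_arcsinh()]
#'   to refuse double application).
#' @return An object of class `event_matrix`.
#' @seealso [read_events()], [transform_arcsinh()], [apply_gate()]
#' @export
event_matrix <- function(values, channels = colnames(values), meta = list(),
                         transformed = character()) {
  values <- as.matrix(values)
  if (nrow(values) > 0L || ncol(values) > 0L) storage.mode(values) <- "double"
  if (is.null(channels)) {
    stop("channel names are required (supply `channels` or name the columns)")
  }
  channels <- as.character(channels)
  if (length(channels) != ncol(values)) {
    stop("length(channels) must equal ncol(values)")
  }
  if (anyDuplicated(channels)) {
    stop("duplicate channel names: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  }
  if (length(values) && any(!is.finite(values))) {
    stop("event intensities must all be finite")
  }
  colnames(values) <- channels
  rownames(values) <- NULL
  structure(
    list(values = values, meta = meta,
         transformed = intersect(transformed, channels)),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat("event_matrix: ", n_events(x), " events x ", length(channels(x)),
      " channels\n", sep = "")
  cat("channels: ", paste(channels(x), collapse = ", "), "\n", sep = "")
  if (length(x$transformed)) {
    cat("arcsinh-transformed: ", paste(x$transformed, collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$meta)) {
    cat("meta: ", paste(names(x$meta), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of events in an event matrix
#' @param events An `event_matrix`.
#' @return Integer row count.
#' @export
n_events <- function(events) {
  stopifnot(inherits(events, "event_matrix"))
  nrow(events$values)
}

#' Channel names of an event matrix
#' @param events An `event_matrix`.
#' @return Character vector of channel names, in acquisition order.
#' @export
channels <- function(events) {
  stopifnot(inherits(events, "event_matrix"))
  colnames(events$values)
}

#' Subset events by row index
#'
#' Row-wise subsetting that preserves channel order, metadata and transform
#' bookkeeping. Events are never reordered implicitly; callers pass indices.
#'
#' @param events An `event_matrix`.
#' @param i Integer or logical row index.
#' @return An `event_matrix` with the selected events.
#' @export
subset_events <- function(events, i) {
  stopifnot(inherits(events, "event_matrix"))
  event_matrix(events$values[i, , drop = FALSE], channels(events),
               meta = events$meta, transformed = events$transformed)
}

#' Concatenate event matrices sharing one panel
#'
#' @param ... `event_matrix` objects, or a single list of them.
#' @return An `event_matrix` stacking all events in the order given.
#' @export
bind_events <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1L]], "event_matrix")) {
    args <- args[[1L]]
  }
  stopifnot(length(args) >= 1L, all(vapply(args, inherits, TRUE, "event_matrix")))
  ref <- channels(args[[1L]])
  for (e in args[-1L]) {
    if (!identical(channels(e), ref)) {
      diff <- union(setdiff(channels(e), ref), setdiff(ref, channels(e)))
      stop("panels differ across event matrices: ",
           paste(diff, collapse = ", "))
    }
  }
  event_matrix(do.call(rbind, lapply(args, function(e) e$values)), ref,
               meta = args[[1L]]$meta, transformed = args[[1L]]$transformed)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a task seed from a root seed
#'
#' Deterministic seed derivation used by the experiment runners so that each
#' (task, index) pair receives its own reproducible stream. The result is a
#' positive integer below 2^31.
#'
#' @param root Integer root seed.
#' @param task Character task name.
#' @param index Integer task index (default 0).
#' @return A positive integer seed.
#' @export
derive_seed <- function(root, task, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(task))
  h <- as.double(root) %% 2147483647
  for (ch in utf8ToInt(task)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + (as.double(index) %% 2147483647)) %% 2147483647
  as.integer(h + 1)
}
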