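# Internal helpers: identifiers, ISO-8601 timestamps, coordinate vectors.

new_id <- function(prj, kind) {
  n <- prj$counters[[kind]] %||% 0L
  prj$counters[[kind]] <- n + 1L
  sprintf("%s_%04d", kind, n + 1L)
}

# Timestamps are ISO-8601 UTC strings with millisecond precision; the fixed
# format makes ordering lexicographic and file exports byte-stable.
iso_now <- function(time = NULL) {
  if (is.null(time)) time <- Sys.time()
  if (inherits(time, "POSIXt")) {
    return(strftime(as.POSIXct(time), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
  }
  if (is.character(time) && length(time) == 1L) {
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}\\.\\d{3}Z$", time)) {
      parsed <- as.POSIXct(time, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%d %H:%M", "%Y-%m-%d"))
      if (is.na(parsed)) abort(sprintf("cannot parse timestamp '%s'", time))
      return(strftime(parsed, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"))
    }
    return(time)
  }
  abort("`time` must be NULL, POSIXt, or an ISO-8601 string")
}

iso_parse <- function(iso) {
  as.POSIXct(strptime(iso, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
}

# Strictly-later timestamp: an edit at (or apparently before) the creation
# instant still advances edited_at. The millisecond bump is done on the
# string (strftime("%OS3") truncates sub-ms float error and can repeat).
iso_after <- function(time, floor_iso) {
  t <- iso_now(time)
  if (t > floor_iso) return(t)
  base <- substr(floor_iso, 1, 19)
  ms <- as.integer(substr(floor_iso, 21, 23)) + 1L
  if (ms >= 1000L) {
    base <- strftime(iso_parse(paste0(base, ".000Z")) + 1, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    ms <- 0L
  }
  sprintf("%s.%03dZ", base, ms)
}

# --- coordinate vectors -----------------------------------------------------
# Internal canonical form: numeric matrix n x 2, columns x, y, 0-based pixels.
# Accepted input forms: such a matrix, a data.frame with x/y, a list of
# (x, y) pairs, or the flat JSON mapping {"x1":..,"y1":..,"x2":..,...}.

as_coord_matrix <- function(vector) {
  if (is.null(vector) || (is.list(vector) && length(vector) == 0L) ||
      (is.numeric(vector) && length(vector) == 0L)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  if (is.matrix(vector)) {
    if (ncol(vector) != 2L) abort("coordinate matrix must have 2 columns")
    m <- vector
  } else if (is.data.frame(vector)) {
    if (!all(c("x", "y") %in% names(vector))) abort("coordinate data frame needs x and y columns")
    m <- cbind(vector$x, vector$y)
  } else if (is.list(vector) && all(grepl("^[xy]\\d+$", names(vector)))) {
    idx <- sort(unique(as.integer(sub("^[xy]", "", names(vector)))))
    m <- cbind(
      vapply(idx, function(i) as.numeric(vector[[paste0("x", i)]]), numeric(1)),
      vapply(idx, function(i) as.numeric(vector[[paste0("y", i)]]), numeric(1))
    )
  } else if (is.list(vector)) {
    pts <- lapply(vector, function(p) {
      p <- unlist(p, use.names = FALSE)
      if (length(p) != 2L) abort("each point must be an (x, y) pair")
      as.numeric(p)
    })
    m <- do.call(rbind, pts)
  } else {
    abort("unsupported coordinate vector form")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) abort("coordinates must be finite numbers")
  colnames(m) <- c("x", "y")
  rownames(m) <- NULL
  m
}

# Flat mapping {"x1":..,"y1":..,...} with 1-based point indices; the stored
# JSON dialect (searchable coordinate fields).
coords_to_flat <- function(m) {
  if (nrow(m) == 0L) return(stats::setNames(list(), character(0)))
  out <- vector("list", 2L * nrow(m))
  nms <- character(2L * nrow(m))
  for (i in seq_len(nrow(m))) {
    out[[2L * i - 1L]] <- m[i, 1L]; nms[2L * i - 1L] <- paste0("x", i)
    out[[2L * i]] <- m[i, 2L];      nms[2L * i] <- paste0("y", i)
  }
  stats::setNames(out, nms)
}

bbox_of <- function(m, kind) {
  if (kind == "circle") {
    cx <- m[1, 1]; cy <- m[1, 2]
    r <- sqrt((m[2, 1] - cx)^2 + (m[2, 2] - cy)^2)
    c(x1 = cx - r, y1 = cy - r, x2 = cx + r, y2 = cy + r)
  } else {
    c(x1 = min(m[, 1]), y1 = min(m[, 2]), x2 = max(m[, 1]), y2 = max(m[, 2]))
  }
}

rect_intersect <- function(a, b) {
  r <- c(x1 = max(a[["x1"]], b[["x1"]]), y1 = max(a[["y1"]], b[["y1"]]),
         x2 = min(a[["x2"]], b[["x2"]]), y2 = min(a[["y2"]], b[["y2"]]))
  if (r[["x2"]] <= r[["x1"]] || r[["y2"]] <= r[["y1"]]) return(NULL)
  r
}

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a non-empty string", what))
  }
}
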