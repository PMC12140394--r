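# Containers and I/O for regularly sampled multivariate time series.
#
# A `ts_set` holds M series observed on the same channels at a common
# sampling interval dt. Time is carried as an integer sample index k (the
# absolute time of sample k is k * dt); absolute timestamps are never stored.

#' Create a time-series set
#'
#' @param x either a data frame in long-wide form with columns `series_id`,
#'   `time_index` and one numeric column per channel, or a (optionally named)
#'   list of numeric matrices, one per series, each `N_m x n` with the same
#'   column count.
#' @param dt sampling interval (time units between consecutive samples).
#' @param channel_names optional channel labels; defaults to the data frame's
#'   channel column names or the matrices' column names.
#' @return an object of class `ts_set` with fields `series` (named list of
#'   `N_m x n` matrices), `dt`, `channel_names`.
#' @examples
#' z <- tibble::tibble(series_id = "a", time_index = 0:4,
#'                     P = rnorm(5), S = rnorm(5))
#' ts <- ts_set(z, dt = 0.5)
#' tibble::as_tibble(ts)
#' @export
ts_set <- function(x, dt = 1, channel_names = NULL) {
  if (is.data.frame(x)) {
    req <- c("series_id", "time_index")
    if (!all(req %in% names(x)))
      stop("data frame input needs columns 'series_id' and 'time_index'",
           call. = FALSE)
    chan_cols <- setdiff(names(x), req)
    if (length(chan_cols) == 0L) stop("no channel columns found", call. = FALSE)
    if (!all(vapply(x[chan_cols], is.numeric, logical(1L))))
      stop("all channel columns must be numeric", call. = FALSE)
    bad <- which(!stats::complete.cases(x[chan_cols]))
    if (length(bad) > 0L)
      stop("missing channel value at row ", bad[1L],
           " (regular sampling with complete channels is required)",
           call. = FALSE)
    sids <- unique(as.character(x$series_id))
    series <- lapply(sids, function(s) {
      rows <- x[as.character(x$series_id) == s, , drop = FALSE]
      ti <- rows$time_index
      if (anyDuplicated(ti))
        stop("duplicate (series_id, time_index) in series '", s, "' at time_index ",
             ti[duplicated(ti)][1L], call. = FALSE)
      if (is.unsorted(ti, strictly = TRUE))
        stop("time_index not strictly increasing in series '", s, "'",
             call. = FALSE)
      m <- as.matrix(rows[chan_cols])
      rownames(m) <- NULL
      m
    })
    names(series) <- sids
    if (is.null(channel_names)) channel_names <- chan_cols
  } else if (is.list(x)) {
    if (length(x) == 0L) stop("no series found", call. = FALSE)
    if (!all(vapply(x, is.matrix, logical(1L))))
      stop("list input must contain numeric matrices", call. = FALSE)
    ncs <- vapply(x, ncol, integer(1L))
    if (length(unique(ncs)) != 1L)
      stop("all series must share the same channel count; got ",
           paste(unique(ncs), collapse = ", "), call. = FALSE)
    series <- lapply(x, function(m) { rownames(m) <- NULL; m })
    if (is.null(names(series)) || any(names(series) == ""))
      names(series) <- paste0("series_", seq_along(series))
    if (is.null(channel_names)) {
      channel_names <- colnames(series[[1L]])
      if (is.null(channel_names))
        channel_names <- paste0("ch", seq_len(ncs[1L]))
    }
  } else {
    stop("x must be a data frame or a list of matrices", call. = FALSE)
  }
  n <- ncol(series[[1L]])
  if (length(channel_names) != n)
    stop("channel_names has length ", length(channel_names),
         " but series have ", n, " channels", call. = FALSE)
  if (any(vapply(series, nrow, integer(1L)) < 1L))
    stop("each series needs at least one sample", call. = FALSE)
  series <- lapply(series, function(m) { colnames(m) <- channel_names; m })
  structure(list(series = series, dt = as.numeric(dt),
                 channel_names = channel_names),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  ns <- vapply(x$series, nrow, integer(1L))
  cat("<ts_set> ", length(x$series), " series, ",
      length(x$channel_names), " channels (",
      paste(x$channel_names, collapse = ", "), "), dt = ", x$dt, "\n",
      sep = "")
  cat("  samples per series: ", paste(utils::head(ns, 10L), collapse = ", "),
      if (length(ns) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @method as_tibble ts_set
#' @export
as_tibble.ts_set <- function(x, ...) {
  purrr::map2_dfr(names(x$series), x$series, function(sid, m) {
    out <- tibble::as_tibble(m, .name_repair = "minimal")
    names(out) <- x$channel_names
    dplyr::bind_cols(tibble::tibble(series_id = sid,
                                    time_index = seq_len(nrow(m)) - 1L), out)
  })
}

n_channels <- function(ts) length(ts$channel_names)

# All samples of all series stacked into one (sum N_m) x n matrix: the
# empirical marginal that surrogate tails are drawn from.
pooled_samples <- function(ts) do.call(rbind, ts$series)

#' Enumerate all full-history windows of a time-series set
#'
#' Slides a length-`T + 1` window over every series. Windows never cross a
#' series boundary and the first `T` samples of each series produce no window
#' (a full history is required), so the total count is
#' `sum(pmax(0, N_m - T))`.
#'
#' @param ts a [ts_set()].
#' @param T history length in samples (>= 1). The window holds `T` history
#'   samples plus the sample being predicted.
#' @return an object of class `window_ensemble`: a 3-d array `Z` of dimension
#'   `B x (T+1) x n`, parallel vectors `series_id` and `end_index` (0-based
#'   index of each window's final sample within its series), and `T`.
#' @examples
#' ts <- ts_set(list(matrix(rnorm(10), 5, 2)), dt = 1)
#' build_windows(ts, T = 2)$series_id
#' @export
build_windows <- function(ts, T) {
  stopifnot(inherits(ts, "ts_set"))
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1", call. = FALSE)
  ns <- vapply(ts$series, nrow, integer(1L))
  counts <- pmax(0L, ns - T)
  B <- sum(counts)
  if (B == 0L)
    stop("no usable windows: T = ", T, " but the longest series has only ",
         max(ns), " samples (need at least T + 1)", call. = FALSE)
  n <- n_channels(ts)
  Z <- array(NA_real_, dim = c(B, T + 1L, n))
  sid <- character(B)
  kend <- integer(B)
  pos <- 0L
  for (m in seq_along(ts$series)) {
    S <- ts$series[[m]]
    if (counts[m] == 0L) next
    for (k in (T + 1L):nrow(S)) {      # 1-based row of the window's end
      pos <- pos + 1L
      Z[pos, , ] <- S[(k - T):k, , drop = FALSE]
      sid[pos] <- names(ts$series)[m]
      kend[pos] <- k - 1L              # 0-based end index
    }
  }
  structure(list(Z = Z, series_id = sid, end_index = kend, T = T,
                 dt = ts$dt, channel_names = ts$channel_names),
            class = "window_ensemble")
}

#' @export
print.window_ensemble <- function(x, ...) {
  cat("<window_ensemble> ", dim(x$Z)[1L], " windows of length T+1 = ",
      x$T + 1L, ", ", dim(x$Z)[3L], " channels\n", sep = "")
  invisible(x)
}

# Flatten the window array to (B*(T+1)) x n for a batched pass through g.
# Row (t-1)*B + b is sample t of window b (column-major over the first two
# array dimensions, so plain dim<- is enough).
flatten_windows <- function(Z) {
  d <- dim(Z)
  dim(Z) <- c(d[1L] * d[2L], d[3L])
  Z
}

# ---- file I/O ------------------------------------------------------------

#' Read / write a time-series set
#'
#' Two formats are supported. `"csv"` is columnar text with a header row and
#' columns `series_id`, `time_index`, then one column per channel; values are
#' written with full round-trip precision. `"rds"` is a compressed container
#' holding one numeric matrix per series plus the metadata record
#' (`dt`, `channel_names`).
#'
#' @param path file path.
#' @param format `"csv"` or `"rds"`; default guessed from the extension.
#' @param dt sampling interval to attach when reading csv (csv carries no
#'   metadata record; default 1).
#' @return `read_timeseries` returns a [ts_set()]; `write_timeseries`
#'   invisibly returns `path`.
#' @export
read_timeseries <- function(path, format = NULL, dt = 1) {
  format <- format %||% guess_ts_format(path)
  if (format == "rds") {
    obj <- readRDS(path)
    if (!inherits(obj, "ts_set")) stop("not a ts_set container", call. = FALSE)
    return(obj)
  }
  if (format != "csv") stop("unknown format '", format, "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no series found in ", path, call. = FALSE)
  ts_set(df, dt = dt)
}

#' @rdname read_timeseries
#' @param ts a [ts_set()] to write.
#' @export
write_timeseries <- function(ts, path, format = NULL) {
  stopifnot(inherits(ts, "ts_set"))
  format <- format %||% guess_ts_format(path)
  if (format == "rds") {
    saveRDS(ts, path)
  } else if (format == "csv") {
    df <- as.data.frame(as_tibble.ts_set(ts))
    # 17 significant digits: shortest text guaranteed to round-trip doubles
    for (j in seq_along(df))
      if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unknown format '", format, "'", call. = FALSE)
  }
  invisible(path)
}

guess_ts_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("rds")) "rds" else "csv"
}
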