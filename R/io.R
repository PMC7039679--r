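#' Read a recording from disk
#'
#' The native interchange format is a plain-text file: a header of
#' `key: value` lines (temperature, solutions and per-sweep metadata — `dt`,
#' `clamp_mode`, `holding`, sample count and stimulus protocol, with
#' structured values encoded as JSON), a `data:` marker, then one
#' tab-separated column of samples per sweep (shorter sweeps padded with
#' `NA`). Numeric fields are serialized with 17 significant digits so a
#' write/read round trip is exact to full double precision. The format is
#' line-diffable on purpose: test fixtures and pipeline outputs can be
#' inspected and versioned as text.
#'
#' Import from Axon ABF or NWB containers is a documented extension point but
#' no reader for those containers is installed with this package; requesting
#' them raises an informative error.
#'
#' @param path Path to a file in the native format.
#' @param format One of `"native"`, `"abf"`, `"nwb"`.
#' @return A [cell_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("native", "abf", "nwb")) {
  format <- match.arg(format)
  if (format %in% c("abf", "nwb")) {
    stop(sprintf("no %s reader is available in this installation; convert to the native text format first",
                 toupper(format)), call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[[1]], "#patchkit")) {
    stop("not a patchkit native recording (missing '#patchkit' magic line)", call. = FALSE)
  }
  data_at <- which(lines == "data:")
  if (length(data_at) != 1L) stop("malformed file: expected exactly one 'data:' marker", call. = FALSE)

  hdr_lines <- lines[2:(data_at - 1L)]
  hdr_lines <- hdr_lines[nzchar(hdr_lines)]
  keys <- sub(":.*$", "", hdr_lines)
  vals <- sub("^[^:]*: ?", "", hdr_lines)
  hdr <- stats::setNames(as.list(vals), keys)

  need <- function(key, where = "header") {
    if (is.null(hdr[[key]])) {
      stop(sprintf("format error: required field '%s' missing from %s", key, where), call. = FALSE)
    }
    hdr[[key]]
  }
  n_sweeps <- as.integer(need("n_sweeps"))
  temperature <- as.numeric(need("temperature"))
  parse_json <- function(key) {
    if (is.null(hdr[[key]])) return(NULL)
    jsonlite::fromJSON(hdr[[key]], simplifyVector = TRUE)
  }
  internal <- unlist(parse_json("internal"))
  external <- unlist(parse_json("external"))
  metadata <- parse_json("metadata")
  if (is.null(metadata)) metadata <- list()

  as_num <- function(v) {
    v[v %in% c("NA", "nan")] <- NA_character_
    as.numeric(v)
  }
  body <- lines[(data_at + 1L):length(lines)]
  body <- body[nzchar(body)]
  mat <- NULL
  if (length(body) > 0L) {
    mat <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as_num))
  }

  sweeps <- vector("list", n_sweeps)
  for (i in seq_len(n_sweeps)) {
    pre <- sprintf("sweep.%d.", i)
    where <- sprintf("sweep %d", i)
    dt <- as_num(need(paste0(pre, "dt"), where))
    clamp_mode <- need(paste0(pre, "clamp_mode"), where)
    n <- as.integer(need(paste0(pre, "n"), where))
    holding <- as_num(need(paste0(pre, "holding"), where))
    id <- need(paste0(pre, "id"), where)
    stim <- NULL
    stim_json <- hdr[[paste0(pre, "stim")]]
    if (!is.null(stim_json)) {
      s <- jsonlite::fromJSON(stim_json, simplifyVector = TRUE)
      stim <- step_protocol(onset = s$onset, duration = s$duration,
                            amplitude = s$amplitude %||% NA_real_,
                            pulse_times = s$pulse_times,
                            pulse_rate = s$pulse_rate %||% NA_real_)
    }
    samples <- mat[seq_len(n), i]
    sweeps[[i]] <- sweep_trace(samples, dt = dt, clamp_mode = clamp_mode,
                               holding = holding, stim = stim, sweep_id = id)
  }
  cell_recording(sweeps, internal = internal, external = external,
                 temperature = temperature, metadata = metadata)
}

#' Write a recording to the native text format
#'
#' @param rec A [cell_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pk_recording"))
  if (length(rec$sweeps) == 0L) stop("nothing to write: recording has no sweeps", call. = FALSE)
  num <- function(x) sprintf("%.17g", x)
  to_json <- function(x) {
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }

  hdr <- c("#patchkit v1",
           paste0("temperature: ", num(rec$temperature)),
           paste0("n_sweeps: ", length(rec$sweeps)))
  if (!is.null(rec$internal)) hdr <- c(hdr, paste0("internal: ", to_json(as.list(rec$internal))))
  if (!is.null(rec$external)) hdr <- c(hdr, paste0("external: ", to_json(as.list(rec$external))))
  if (length(rec$metadata) > 0L) hdr <- c(hdr, paste0("metadata: ", to_json(rec$metadata)))

  for (i in seq_along(rec$sweeps)) {
    sw <- rec$sweeps[[i]]
    pre <- sprintf("sweep.%d.", i)
    hdr <- c(hdr,
             paste0(pre, "id: ", sw$sweep_id),
             paste0(pre, "dt: ", num(sw$dt)),
             paste0(pre, "clamp_mode: ", sw$clamp_mode),
             paste0(pre, "holding: ", num(sw$holding)),
             paste0(pre, "n: ", length(sw$samples)))
    if (!is.null(sw$stim)) {
      hdr <- c(hdr, paste0(pre, "stim: ", to_json(unclass(sw$stim))))
    }
  }

  n_max <- max(vapply(rec$sweeps, function(s) length(s$samples), integer(1)))
  cols <- lapply(rec$sweeps, function(s) {
    out <- rep("NA", n_max)
    out[seq_along(s$samples)] <- num(s$samples)
    out
  })
  body <- do.call(paste, c(cols, sep = "\t"))

  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, "data:", body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
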