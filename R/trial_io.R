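#' @title Trial trajectory files and cohort manifests
#' @description Trials are stored as long-form delimited text: a `#`-prefixed
#'   header block declaring units (mm, s), sampling rate, the height axis and
#'   the trial metadata, followed by one CSV row per sample per marker.
#'   Missing samples are written with empty coordinate fields (never zeros)
#'   and `missing=TRUE`, so dropout is explicit and round-trips losslessly.
#' @name trial_io
NULL

.trial_format_tag <- "wavetrial v1"

#' Write a trial to a plain-text trajectory file
#'
#' Serialization is lossless: coordinates are printed with 17 significant
#' digits so doubles round-trip exactly, and the missing mask is preserved.
#'
#' @param trial A `wave_trial`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_wave_trial(trial)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    paste("#", .trial_format_tag),
    sprintf("# participant_id: %s", trial$participant_id),
    sprintf("# block: %d", trial$block),
    sprintf("# focus: %s", trial$focus),
    sprintf("# direction: %s", trial$direction),
    sprintf("# trial_index: %d", trial$trial_index),
    sprintf("# sampling_rate: %.17g", trial$sampling_rate),
    "# units: mm,s",
    sprintf("# height_axis: %s", trial$height_axis),
    "marker_id,chain_index,t,x,y,z,missing"
  )
  writeLines(hdr, con)
  num <- function(v) sprintf("%.17g", v)
  for (j in seq_along(trial$marker_id)) {
    miss <- trial$missing[, j]
    xs <- ifelse(miss, "", num(trial$x[, j]))
    ys <- ifelse(miss, "", num(trial$y[, j]))
    zs <- ifelse(miss, "", num(trial$z[, j]))
    rows <- paste(
      trial$marker_id[j],
      ifelse(is.na(trial$chain_index[j]), "", trial$chain_index[j]),
      num(trial$t), xs, ys, zs, ifelse(miss, "TRUE", "FALSE"),
      sep = ","
    )
    writeLines(rows, con)
  }
  invisible(path)
}

parse_trial_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      kv[[key]] <- val
    }
  }
  kv
}

#' Read a trial from a plain-text trajectory file
#'
#' Validates the schema on the way in: the file must declare mm/s units,
#' cover chain indices 1..8 exactly once, share a strictly increasing common
#' time base across markers, and flag (rather than drop) missing samples.
#' Non-finite or empty coordinate fields become missing-mask entries.
#'
#' @param path File written by [write_trial()] (or any conforming file).
#' @param marker_map Optional named integer vector reassigning chain indices
#'   to marker ids, overriding the `chain_index` column.
#' @return A validated `wave_trial`.
#' @export
read_trial <- function(path, marker_map = NULL) {
  lines <- readLines(path)
  n_hdr <- match(FALSE, startsWith(lines, "#"), nomatch = 1L) - 1L
  if (n_hdr < 1L || !grepl(.trial_format_tag, lines[1L], fixed = TRUE)) {
    stop("not a ", .trial_format_tag, " file: ", path)
  }
  kv <- parse_trial_header(lines[seq_len(n_hdr)])
  if (!identical(kv$units, "mm,s")) {
    stop("unit mismatch: file declares units \"", kv$units,
         "\" but mm,s are required")
  }
  df <- read.csv(
    text = lines[-seq_len(n_hdr)],
    colClasses = c(
      marker_id = "character", chain_index = "integer", t = "numeric",
      x = "numeric", y = "numeric", z = "numeric", missing = "logical"
    )
  )
  marker_id <- unique(df$marker_id)
  m <- length(marker_id)
  t0 <- df$t[df$marker_id == marker_id[1L]]
  if (any(diff(t0) <= 0)) stop("non-monotone time base in ", path)
  n <- length(t0)

  x <- y <- z <- matrix(NA_real_, n, m, dimnames = list(NULL, marker_id))
  missing <- matrix(FALSE, n, m, dimnames = list(NULL, marker_id))
  chain_index <- integer(m)
  for (j in seq_len(m)) {
    sub <- df[df$marker_id == marker_id[j], ]
    if (nrow(sub) != n || !isTRUE(all.equal(sub$t, t0))) {
      stop("markers do not share a common time base in ", path)
    }
    x[, j] <- sub$x; y[, j] <- sub$y; z[, j] <- sub$z
    missing[, j] <- sub$missing | !is.finite(sub$x) |
      !is.finite(sub$y) | !is.finite(sub$z)
    ci <- unique(sub$chain_index)
    chain_index[j] <- if (length(ci) == 1L) ci else NA_integer_
  }
  if (!is.null(marker_map)) {
    chain_index <- rep(NA_integer_, m)
    hit <- match(marker_id, names(marker_map))
    chain_index[!is.na(hit)] <- as.integer(marker_map[hit[!is.na(hit)]])
  }
  x[missing] <- y[missing] <- z[missing] <- NA_real_

  new_wave_trial(
    participant_id = kv$participant_id %||% "unknown",
    block = as.integer(kv$block %||% 1L),
    focus = kv$focus %||% "external",
    direction = kv$direction %||% "left-to-right",
    trial_index = as.integer(kv$trial_index %||% 1L),
    t = t0, sampling_rate = as.numeric(kv$sampling_rate %||% 100),
    marker_id = marker_id, chain_index = chain_index,
    x = x, y = y, z = z, missing = missing,
    height_axis = kv$height_axis %||% "z"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort manifest
#'
#' A manifest maps trials to participant, block, attentional-focus condition
#' and wave direction (CSV columns `participant_id`, `block_index`, `focus`,
#' `direction`, `trial_index`, optionally `file` plus manual analysis-window
#' overrides `t_start`/`t_end`).
#'
#' @param path Manifest CSV path.
#' @return A validated tibble.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, colClasses = "character")
  required <- c("participant_id", "block_index", "focus",
                "direction", "trial_index")
  absent <- setdiff(required, names(df))
  if (length(absent)) {
    stop("manifest lacks required columns: ", paste(absent, collapse = ", "))
  }
  df$block_index <- as.integer(df$block_index)
  df$trial_index <- as.integer(df$trial_index)
  bad_focus <- setdiff(unique(df$focus), .focus_levels)
  if (length(bad_focus)) {
    stop("unknown focus label(s): ", paste(bad_focus, collapse = ", "))
  }
  bad_dir <- setdiff(unique(df$direction), .wave_directions)
  if (length(bad_dir)) {
    stop("unknown direction label(s): ", paste(bad_dir, collapse = ", "))
  }
  key <- paste(df$participant_id, df$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicate (participant_id, trial_index) keys in manifest")
  }
  for (col in c("t_start", "t_end")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  tibble::as_tibble(df)
}

#' Write a cohort manifest
#'
#' @param manifest Data frame with the manifest columns (see
#'   [read_manifest()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
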