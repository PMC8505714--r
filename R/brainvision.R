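# BrainVision (.vhdr/.vmrk/.eeg) dialect: INI-style header, marker file
# with "Mk<n>=<type>,<description>,<position>,<size>,<channel>" lines, and
# multiplexed little-endian binary data (IEEE float32, or int16 with a
# per-channel resolution). Marker positions are 1-based in the file and
# converted to the package's 0-based sample indexing on read.

# stimulus description <-> event kind mapping; condition markers carry
# their code directly as "S  <code>" (1..6)
.bv_kind_codes <- c(trial_start = 10L, cue = 11L, go = 12L)

#' Write a recording in BrainVision format
#'
#' Writes the .vhdr/.vmrk/.eeg triplet (multiplexed IEEE float32, little
#' endian). Condition markers are stored as \code{Stimulus,S  <code>};
#' trial start, cue and Go as stimulus codes 10/11/12; button releases as
#' \code{Response,R  1}.
#'
#' @param recording An \code{eeg_recording}.
#' @param events An \code{event_table} (or NULL).
#' @param basepath Path without extension; the three files get .vhdr,
#'   .vmrk, .eeg appended.
#' @return The .vhdr path, invisibly.
#' @export
write_brainvision <- function(recording, events = NULL, basepath) {
  hdr <- paste0(basepath, ".vhdr")
  mrk <- paste0(basepath, ".vmrk")
  dat <- paste0(basepath, ".eeg")
  base <- basename(basepath)
  nc <- n_channels(recording)

  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nc),
    paste0("SamplingInterval=", format(1e6 / recording$sampling_rate_hz,
                                       scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,%s,1,µV", seq_len(nc), recording$channel_labels,
            recording$reference_label))
  writeLines(lines, hdr, useBytes = TRUE)

  mlines <- c("Brain Vision Data Exchange Marker File, Version 1.0",
              "",
              "[Common Infos]",
              paste0("DataFile=", base, ".eeg"),
              "",
              "[Marker Infos]",
              "Mk1=New Segment,,1,1,0,0")
  if (!is.null(events) && nrow(events) > 0) {
    desc <- character(nrow(events))
    type <- character(nrow(events))
    for (i in seq_len(nrow(events))) {
      k <- events$kind[i]
      if (k == "condition_marker") {
        type[i] <- "Stimulus"; desc[i] <- sprintf("S  %d", events$code[i])
      } else if (k == "button_release") {
        type[i] <- "Response"; desc[i] <- "R  1"
      } else if (k %in% names(.bv_kind_codes)) {
        type[i] <- "Stimulus"; desc[i] <- sprintf("S %d", .bv_kind_codes[[k]])
      } else {
        type[i] <- "Comment"; desc[i] <- k
      }
    }
    mlines <- c(mlines,
                sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(events)) + 1L,
                        type, desc, events$sample + 1L))
  }
  writeLines(mlines, mrk, useBytes = TRUE)

  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$data), con, size = 4L, endian = "little")
  invisible(hdr)
}

# minimal INI parser: list of sections, each a named character vector plus
# the raw lines (for Mk entries whose values contain '=')
parse_ini <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "latin1")
  lines <- sub(";.*$", "", lines)
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- character(0)
      next
    }
    if (is.null(section) || !grepl("=", ln, fixed = TRUE)) next
    key <- sub("=.*$", "", ln)
    val <- sub("^[^=]*=", "", ln)
    out[[section]][trimws(key)] <- val
  }
  out
}

# safe lookup in a parsed INI section (named character vector)
ini_get <- function(section, key) {
  if (is.null(section) || !key %in% names(section)) NULL
  else section[[key]]
}

#' Read a BrainVision recording
#'
#' Reads the .vhdr header with its companion .vmrk/.eeg files. Supports
#' multiplexed binary data in IEEE float32 or int16 (scaled by the
#' per-channel resolution to microvolts). Stimulus markers \code{S <code>}
#' with codes 1..6 map to condition markers (internal whitespace in the
#' description is arbitrary); codes 10/11/12 map to trial start / cue / Go;
#' responses map to button releases; anything else is preserved with kind
#' \code{other}.
#'
#' @param header_path Path to the .vhdr file.
#' @return List with \code{recording} (an \code{eeg_recording}) and
#'   \code{events} (an \code{event_table}).
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) stop("header file not found: ", header_path)
  ini <- parse_ini(header_path)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stop("malformed BrainVision header: no [Common Infos]")
  if (!identical(toupper(ini_get(ci, "DataFormat")), "BINARY"))
    stop("unsupported BrainVision dialect: DataFormat ",
         ini_get(ci, "DataFormat"))
  if (!identical(toupper(ini_get(ci, "DataOrientation")), "MULTIPLEXED"))
    stop("unsupported BrainVision dialect: orientation ",
         ini_get(ci, "DataOrientation"))
  nc <- as.integer(ini_get(ci, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(ini_get(ci, "SamplingInterval"))
  fmt <- toupper(ini_get(bi, "BinaryFormat"))
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported BrainVision dialect: binary format ", fmt)

  chinf <- ini[["Channel Infos"]]
  labels <- character(nc); resol <- rep(1, nc)
  for (i in seq_len(nc)) {
    v <- ini_get(chinf, paste0("Ch", i))
    if (is.null(v)) stop("header lacks Ch", i, " in [Channel Infos]")
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resol[i] <- as.numeric(parts[3])
  }

  dir <- dirname(header_path)
  dat <- file.path(dir, ini_get(ci, "DataFile"))
  mrk <- if (!is.null(ini_get(ci, "MarkerFile")))
    file.path(dir, ini_get(ci, "MarkerFile"))
  if (!file.exists(dat)) stop("missing companion data file: ", dat)

  bytes <- file.info(dat)$size
  unit <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  if (bytes %% (unit * nc) != 0)
    stop("data file size inconsistent with ", nc,
         " declared channels (structural error)")
  nsamp <- bytes / (unit * nc)
  con <- file(dat, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = nc * nsamp, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = nc * nsamp, size = 2L, signed = TRUE,
            endian = "little")
  }
  data <- matrix(as.numeric(raw), nrow = nc)
  if (fmt == "INT_16") data <- data * resol

  events <- event_table(integer(0), character(0))
  if (!is.null(mrk) && file.exists(mrk)) {
    mini <- parse_ini(mrk)[["Marker Infos"]]
    if (!is.null(mini)) {
      sm <- integer(0); kd <- character(0); cd <- integer(0)
      for (v in mini) {
        parts <- strsplit(v, ",", fixed = TRUE)[[1]]
        if (length(parts) < 3) next
        type <- trimws(parts[1]); desc <- trimws(parts[2])
        pos <- suppressWarnings(as.integer(parts[3]))
        if (is.na(pos) || identical(type, "New Segment")) next
        kind <- "other"; code <- NA_integer_
        if (type == "Stimulus" && grepl("^S\\s*[0-9]+$", desc)) {
          scode <- as.integer(sub("^S\\s*", "", desc))
          if (scode %in% 1:6) { kind <- "condition_marker"; code <- scode }
          else if (scode %in% .bv_kind_codes)
            kind <- names(.bv_kind_codes)[match(scode, .bv_kind_codes)]
        } else if (type == "Response") {
          kind <- "button_release"
        }
        sm <- c(sm, pos - 1L); kd <- c(kd, kind); cd <- c(cd, code)
      }
      events <- event_table(sm, kd, cd)
    }
  }
  list(recording = eeg_recording(data, labels, fs), events = events)
}
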