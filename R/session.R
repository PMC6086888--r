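session_columns <- c(
  trial = "integer", trial_type = "character", block = "character",
  juice_a = "character", mag_a = "double", juice_b = "character",
  mag_b = "double", display_on = "double", display_duration = "double",
  iti_after = "double", aborted = "logical", choice = "character"
)

#' Validate a behavioral session table
#'
#' A session is a tibble with one row per trial, time-ordered, holding
#' two contiguous blocks (`narrow`, `wide`). Checks column presence and
#' types, positive magnitudes and durations, nonnegative ITIs,
#' non-overlapping trial timing, block contiguity, the constancy of the
#' test-trial reference option, and choice coding (`a`, `b`, or `none`;
#' aborted trials carry no choice). Errors name the offending trial.
#'
#' @param session A session tibble.
#' @return The validated session, invisibly usable in pipes.
#' @export
validate_session <- function(session) {
  if (!is.data.frame(session)) abort("`session` must be a data frame.")
  missing_cols <- setdiff(names(session_columns), names(session))
  if (length(missing_cols) > 0) {
    abort(paste0("Session is missing columns: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  meta <- attr(session, "normadapt_meta")
  session <- tibble::as_tibble(session)
  attr(session, "normadapt_meta") <- meta
  if (nrow(session) == 0) return(invisible(session))

  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(sprintf("Trial %d: %s.", session$trial[idx[1]], what))
    }
  }
  bad(!session$trial_type %in% c("test", "adapter"),
      "unknown trial_type (must be 'test' or 'adapter')")
  bad(!session$block %in% c("narrow", "wide"),
      "unknown block label (must be 'narrow' or 'wide')")
  bad(!session$choice %in% c("a", "b", "none"),
      "unknown choice (must be 'a', 'b' or 'none')")
  bad(!is.finite(session$mag_a) | session$mag_a <= 0 |
        !is.finite(session$mag_b) | session$mag_b <= 0,
      "reward magnitudes must be positive")
  bad(!is.finite(session$display_duration) | session$display_duration <= 0,
      "display_duration must be positive")
  bad(!is.finite(session$iti_after) | session$iti_after < 0,
      "iti_after must be nonnegative")
  bad(session$aborted & session$choice != "none",
      "aborted trials cannot carry a choice")

  n <- nrow(session)
  if (n > 1) {
    off <- session$display_on + session$display_duration +
      session$iti_after
    overlap <- session$display_on[-1] < off[-n] - 1e-9
    if (any(overlap)) {
      abort(sprintf(
        "Trial %d: overlaps the preceding trial in time.",
        session$trial[which(overlap)[1] + 1]
      ))
    }
  }

  blocks <- rle(session$block)$values
  if (length(unique(session$block)) != 2 || length(blocks) != 2) {
    abort(paste0(
      "Session must contain exactly two contiguous blocks, ",
      "one 'narrow' and one 'wide'."
    ))
  }

  tests <- session[session$trial_type == "test", ]
  if (nrow(tests) > 1) {
    if (length(unique(tests$juice_a)) > 1 ||
        length(unique(tests$mag_a)) > 1) {
      abort(paste0(
        "Test trials must share a fixed reference option ",
        "(constant juice_a and mag_a)."
      ))
    }
  }
  invisible(session)
}

session_meta <- function(session) {
  attr(session, "normadapt_meta") %||% list()
}

`session_meta<-` <- function(session, value) {
  attr(session, "normadapt_meta") <- value
  session
}

#' Write / read a session file
#'
#' Sessions are stored as plain text: CSV (one row per trial, metadata in
#' `#`-prefixed header lines) or JSON (`meta` + column-wise `trials`),
#' chosen by file extension. Both formats round-trip losslessly through
#' [read_session()], which validates the schema on the way in.
#'
#' @param session A validated session tibble.
#' @param path File path ending in `.csv` or `.json`.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session tibble with its metadata attribute restored.
#' @export
write_session <- function(session, path) {
  session <- validate_session(session)
  meta <- session_meta(session)
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "csv") {
    header <- c(
      "# normadapt_session v1",
      paste0("# meta ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                         digits = NA, null = "null"))
    )
    body <- readr::format_csv(session)
    writeLines(c(header, sub("\n$", "", body)), path)
  } else if (fmt == "json") {
    jsonlite::write_json(
      list(format = "normadapt_session", version = 1L, meta = meta,
           trials = as.list(session)),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  } else {
    abort("Unsupported session format; use a .csv or .json path.")
  }
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  fmt <- tolower(tools::file_ext(path))
  if (fmt == "csv") {
    lines <- readLines(path)
    if (length(lines) == 0 || !startsWith(lines[1], "# normadapt_session")) {
      abort(sprintf(
        "%s: not a session file (missing '# normadapt_session' header).",
        path
      ))
    }
    meta_line <- grep("^# meta ", lines, value = TRUE)
    meta <- if (length(meta_line) > 0) {
      jsonlite::fromJSON(sub("^# meta ", "", meta_line[1]),
                         simplifyVector = TRUE)
    } else {
      list()
    }
    trials <- readr::read_csv(
      I(paste(lines, collapse = "\n")), comment = "#",
      col_types = readr::cols(
        trial = "i", trial_type = "c", block = "c", juice_a = "c",
        mag_a = "d", juice_b = "c", mag_b = "d", display_on = "d",
        display_duration = "d", iti_after = "d", aborted = "l",
        choice = "c"
      ),
      progress = FALSE
    )
    probs <- readr::problems(trials)
    if (nrow(probs) > 0) {
      abort(sprintf(
        "%s: parse error at line %d (%s).",
        path, probs$row[1], probs$expected[1]
      ))
    }
  } else if (fmt == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (!identical(raw$format, "normadapt_session")) {
      abort(sprintf("%s: not a normadapt session JSON file.", path))
    }
    meta <- raw$meta
    trials <- tibble::as_tibble(raw$trials)
    trials$trial <- as.integer(trials$trial)
    trials$aborted <- as.logical(trials$aborted)
  } else {
    abort("Unsupported session format; use a .csv or .json path.")
  }
  session <- validate_session(trials)
  session_meta(session) <- meta
  session
}
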