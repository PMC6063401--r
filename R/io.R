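#' Read a trial table from CSV
#'
#' Reads trials in the package's delimited dialect: header row with
#' columns \code{task}, \code{s_vis}, \code{s_vest}, \code{coherence},
#' \code{response} (an optional leading \code{subject} column is kept).
#' Empty fields denote absent stimuli (e.g. \code{s_vis} on a
#' vestibular-only row). Malformed rows are rejected with their line
#' numbers.
#'
#' @param path File path.
#' @return Trial table data frame with columns \code{subject} (if
#'   present), \code{task}, \code{s_vis}, \code{s_vest}, \code{c_vis},
#'   \code{response}.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("task", "s_vis", "s_vest", "coherence", "response")
  if (!all(need %in% names(raw)))
    stop("missing column(s): ", paste(setdiff(need, names(raw)),
                                      collapse = ", "))
  df <- data.frame(task = as.character(raw$task),
                   s_vis = suppressWarnings(as.numeric(raw$s_vis)),
                   s_vest = suppressWarnings(as.numeric(raw$s_vest)),
                   c_vis = as.character(raw$coherence),
                   response = as.character(raw$response),
                   stringsAsFactors = FALSE)
  if ("subject" %in% names(raw))
    df <- cbind(subject = as.character(raw$subject), df,
                stringsAsFactors = FALSE)
  .validate_trials(df, line_offset = 1L)
  df
}

#' Write a trial table to CSV
#'
#' @param data Trial table data frame.
#' @param path Destination path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(data, path) {
  .validate_trials(data)
  out <- data
  names(out)[names(out) == "c_vis"] <- "coherence"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.validate_trials <- function(df, line_offset = 0L) {
  bad <- function(rows, why) {
    if (length(rows))
      stop("malformed trial row(s) at line(s) ",
           paste(utils::head(rows + line_offset, 10), collapse = ", "),
           ": ", why)
  }
  if (!nrow(df)) stop("trial table is empty")
  rows <- seq_len(nrow(df))
  bad(rows[!df$task %in% c("unisensory", "unity", "inertial")],
      "unknown task token")
  bad(rows[!df$response %in%
             c("right", "left", "unity", "separate", NA)],
      "unknown response token")
  bi <- df$task %in% c("unity", "inertial")
  bad(rows[bi & (is.na(df$s_vis) | is.na(df$s_vest) | is.na(df$c_vis))],
      "bisensory trial missing a heading or reliability")
  bad(rows[df$task == "unisensory" & !xor(is.na(df$s_vis),
                                          is.na(df$s_vest))],
      "unisensory trial must have exactly one heading")
  bad(rows[df$task == "unisensory" & !is.na(df$s_vis) & is.na(df$c_vis)],
      "visual unisensory trial missing reliability")
  bad(rows[!is.na(df$c_vis) & !df$c_vis %in% c("high", "med", "low")],
      "unknown reliability token")
  lr <- df$task %in% c("unisensory", "inertial") & !is.na(df$response)
  bad(rows[lr & !df$response %in% c("right", "left")],
      "discrimination trial needs a right/left response")
  un <- df$task == "unity" & !is.na(df$response)
  bad(rows[un & !df$response %in% c("unity", "separate")],
      "unity trial needs a unity/separate response")
  hd <- c(df$s_vis, df$s_vest)
  if (any(hd < -180 | hd >= 180, na.rm = TRUE))
    stop("headings outside [-180, 180)")
  invisible(TRUE)
}
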