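#' Canonical image-frame labels of the time course
#'
#' Sixteen frames: hourly images T0..T13 plus the post-medium-exchange
#' duplicates T5p and T10p taken immediately after the 5 h and 10 h medium
#' changes ("T5'" / "T10'" in figure legends; the prime is written \code{p} so
#' the labels are file-safe column names).
#'
#' @param n_timepoints number of hourly timepoints after T0 (default 13).
#' @param exchange_hours hours at which the medium is exchanged and a
#'   post-exchange duplicate frame is taken.
#' @return character vector of frame labels in chronological order.
#' @export
#' @examples
#' cid_frames()
cid_frames <- function(n_timepoints = 13L, exchange_hours = c(5L, 10L)) {
  hours <- 0:n_timepoints
  labs <- character(0)
  for (h in hours) {
    labs <- c(labs, paste0("T", h))
    if (h %in% exchange_hours && h < n_timepoints)
      labs <- c(labs, paste0("T", h, "p"))
  }
  labs
}

# numeric time of each frame; post-exchange duplicates sit just after the hour
frame_hours <- function(frames) {
  post <- grepl("p$", frames)
  h <- as.numeric(sub("^T([0-9]+)p?$", "\\1", frames))
  if (anyNA(h)) stop("unparseable frame label(s): ",
                     paste(frames[is.na(h)], collapse = ", "))
  h + ifelse(post, 0.5, 0)
}

#' Select the analysis timepoints from the available image frames
#'
#' The study images 16 frames but correlates expression against 13 hourly
#' timepoints.  The default policy uses T1..T13 with the pre-exchange frame at
#' the exchange hours (T5 and T10, not T5p/T10p).  Alternative policies swap in
#' the post-exchange frames or include T0.
#'
#' @param frames available frame labels (e.g. column names of a distance
#'   table).
#' @param policy one of \code{"pre-exchange"} (default; T1..T13 using T5/T10),
#'   \code{"post-exchange"} (T5p/T10p replace T5/T10) or \code{"all-hours"}
#'   (T0..T13, pre-exchange).
#' @param n_timepoints last hourly timepoint (default 13).
#' @return character vector of selected frame labels, in time order.
#' @export
#' @examples
#' timepoint_policy(cid_frames())                    # 13 labels, T5/T10
#' timepoint_policy(cid_frames(), "post-exchange")   # T5p/T10p instead
timepoint_policy <- function(frames,
                             policy = c("pre-exchange", "post-exchange",
                                        "all-hours"),
                             n_timepoints = 13L) {
  policy <- match.arg(policy)
  hours <- switch(policy,
                  "pre-exchange" = 1:n_timepoints,
                  "post-exchange" = 1:n_timepoints,
                  "all-hours" = 0:n_timepoints)
  wanted <- paste0("T", hours)
  if (policy == "post-exchange") {
    post <- paste0(wanted, "p")
    wanted <- ifelse(post %in% frames, post, wanted)
  }
  missing <- setdiff(wanted, frames)
  if (length(missing))
    stop("requested frame(s) absent: ", paste(missing, collapse = ", "),
         "; available: ", paste(frames, collapse = ", "))
  wanted
}
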