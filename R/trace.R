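# Gaze traces: uniformly sampled (t, x, y) gaze positions in degrees.

#' Construct a gaze trace
#'
#' @param t Sample times in seconds, a strictly increasing uniform grid.
#' @param x,y Horizontal and vertical gaze position in degrees.
#' @param sampling_rate Sampling rate in Hz.
#' @param stimulus_onset Stimulus-onset time in seconds (on the `t` axis).
#' @return A data.frame of class `gaze_trace` with attributes
#'   `sampling_rate` and `stimulus_onset`.
#' @export
gaze_trace <- function(t, x, y, sampling_rate, stimulus_onset) {
  if (length(t) < 2L) stop("gaze trace needs at least two samples")
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("t, x and y must have equal length")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("sample times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9) {
    stop("non-uniform sampling: time steps differ by more than 1e-9 s")
  }
  if (abs(mean(dt) - 1 / sampling_rate) > 1e-6 / sampling_rate) {
    stop("sample spacing does not match the declared sampling_rate")
  }
  structure(data.frame(t = t, x = x, y = y),
            sampling_rate = sampling_rate,
            stimulus_onset = stimulus_onset,
            class = c("gaze_trace", "data.frame"))
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "Gaze trace: %d samples at %g Hz (%.3f s), stimulus onset at %.3f s\n",
    nrow(x), attr(x, "sampling_rate"),
    nrow(x) / attr(x, "sampling_rate"), attr(x, "stimulus_onset")))
  invisible(x)
}

#' Read or write a gaze trace as tab-separated text
#'
#' The file holds three columns `t`, `x`, `y` preceded by metadata header
#' lines `# sampling_rate = <Hz>` and `# stimulus_onset = <s>`.
#'
#' @param trace A [gaze_trace()].
#' @param path File path.
#' @return `read_gaze_trace` returns a validated [gaze_trace()];
#'   `write_gaze_trace` returns `path` invisibly.
#' @export
write_gaze_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate = %.17g", attr(trace, "sampling_rate")),
               sprintf("# stimulus_onset = %.17g",
                       attr(trace, "stimulus_onset"))), con)
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_trace
#' @export
read_gaze_trace <- function(path) {
  header <- readLines(path, n = 10L)
  meta_lines <- grep("^#", header, value = TRUE)
  get_meta <- function(key) {
    line <- grep(paste0("^#\\s*", key, "\\s*="), meta_lines, value = TRUE)
    if (!length(line)) stop(sprintf("missing metadata: %s", key))
    as.numeric(sub(".*=\\s*", "", line[1L]))
  }
  sr <- get_meta("sampling_rate")
  onset <- get_meta("stimulus_onset")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("t", "x", "y") %in% names(df))) {
    stop("trace file must contain columns t, x, y")
  }
  gaze_trace(df$t, df$x, df$y, sampling_rate = sr, stimulus_onset = onset)
}
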