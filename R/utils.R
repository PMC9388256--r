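# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal-to-noise ratio in decibels
#'
#' Power ratio of a reference (clean) signal to the residual `x - clean`,
#' expressed in dB. Used throughout the synthetic-noise and denoising code.
#'
#' @param x Observed signal (numeric vector).
#' @param clean Reference clean signal of the same length.
#' @return A single number, `10 * log10(P_signal / P_noise)`.
#' @export
snr_db <- function(x, clean) {
  stopifnot(length(x) == length(clean))
  noise <- x - clean
  10 * log10(sum(clean^2) / sum(noise^2))
}

# Per-beat z-score; a constant beat maps to all zeros rather than NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Derive a reproducible per-stage seed from a global seed and a stage name.
# Plain arithmetic on UTF-8 code points keeps it dependency-free and stable
# across platforms; result stays inside the 32-bit integer range.
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 1000003L
  v <- (as.numeric(global_seed) %% 65521 + 1) * 1000003 + h
  as.integer(v %% 2147483647)
}

assert_finite <- function(x, what = "signal") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0(what, " must be numeric and finite"))
  }
  invisible(x)
}

# Structured one-line log record used by the pipeline stage runner.
log_line <- function(stage, event, ..., file = NULL) {
  kv <- list(...)
  extra <- if (length(kv)) {
    paste(names(kv), vapply(kv, function(v) paste(format(v), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  } else ""
  msg <- sprintf("%s [%s] %s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 stage, event, extra)
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}
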