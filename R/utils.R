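# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
# Quantize to the pump grid (0.05 U or 0.05 U/h). `floor` mode is used for
# boluses (never deliver more than asked), `round` for basal rates.
quantize_insulin <- function(x, step = 0.05, mode = c("round", "floor")) {
  mode <- match.arg(mode)
  # epsilon guards against 3.3/2 style binary-representation shortfalls
  k <- x / step + 1e-9
  k <- if (mode == "floor") floor(k) else round(x / step)
  k * step
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
# Linear-interpolation percentiles (R type 7), the convention used for all
# cohort interquartile ranges.
q25_75 <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)

# minutes -> "HH:MM" clock label within a day
clock_label <- function(t_min) {
  m <- t_min %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

# "HH:MM" -> minutes from midnight
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  stop_if(length(parts) != 2L, "clock time must be 'HH:MM', got '", x, "'")
  h <- suppressWarnings(as.numeric(parts[1]))
  m <- suppressWarnings(as.numeric(parts[2]))
  stop_if(!is.finite(h) || !is.finite(m) || h < 0 || h > 23 || m < 0 || m > 59,
          "invalid clock time '", x, "'")
  h * 60 + m
}
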