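#' Exponential insulin activity curve
#'
#' Bilinear-free exponential model of subcutaneous insulin action used for
#' all insulin-on-board accounting. With time constant
#' \eqn{\tau = peak (1 - peak/DIA) / (1 - 2 peak/DIA)}, \eqn{a = 2\tau/DIA}
#' and normalisation \eqn{S = 1 / (1 - a + (1 + a) e^{-DIA/\tau})}:
#' \deqn{activity(t) = (S/\tau^2)\, t\, (1 - t/DIA)\, e^{-t/\tau}}
#' \deqn{iob(t) = 1 - S (1 - a)\left[\left(\frac{t^2}{\tau DIA (1-a)} -
#'   \frac{t}{\tau} - 1\right) e^{-t/\tau} + 1\right]}
#' The activity fraction integrates to 1 over one DIA and the IOB fraction
#' decays from 1 at `t = 0` to 0 at `t = DIA`; both are 0 beyond DIA.
#'
#' @param t_since minutes since delivery (vectorized; values < 0 contribute
#'   nothing yet and return iob 1, activity 0... they are treated as t = 0).
#' @param dia duration of insulin activity, min.
#' @param peak time of peak activity, min; requires `2*peak < dia`.
#' @return A list with numeric vectors `iob_fraction` (0-1) and
#'   `activity_fraction` (1/min).
#' @examples
#' insulin_curve(75, dia = 300, peak = 75)
#' @export
insulin_curve <- function(t_since, dia = 300, peak = 75) {
  stop_if(!is_number(dia) || !is_number(peak) || peak <= 0 || dia <= 0,
          "dia and peak must be positive numbers")
  stop_if(2 * peak >= dia, "insulin curve requires peak < dia/2")
  t <- pmax(t_since, 0)
  tau <- peak * (1 - peak / dia) / (1 - 2 * peak / dia)
  a <- 2 * tau / dia
  S <- 1 / (1 - a + (1 + a) * exp(-dia / tau))
  act <- (S / tau^2) * t * (1 - t / dia) * exp(-t / tau)
  iob <- 1 - S * (1 - a) *
    ((t^2 / (tau * dia * (1 - a)) - t / tau - 1) * exp(-t / tau) + 1)
  ended <- t >= dia
  act[ended] <- 0
  iob[ended] <- 0
  list(iob_fraction = pmax(iob, 0), activity_fraction = pmax(act, 0))
}
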