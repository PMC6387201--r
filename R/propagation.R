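#' Log-distance radio propagation model
#'
#' Received power at distance d metres from a beacon follows the standard
#' log-distance path-loss law with additive effects:
#' \deqn{RSSI = P_0 - 10 n \log_{10}(d) - w \cdot \#walls - body(\theta)
#'       + I + N(0, \sigma^2)}
#' where \eqn{P_0} is the received power at the 1 m reference distance, n the
#' path-loss exponent, w the per-wall attenuation for every wall segment
#' crossed by the sight line, \eqn{body(\theta)} a heading-dependent
#' human-body attenuation, I an optional per-session interference offset and
#' the last term zero-mean Gaussian shadowing.
#'
#' The body term is a cosine ramp: zero when the beacon is straight ahead of
#' the walker and `body_loss_max` when it is directly behind (the walker's
#' torso blocks the line of sight), interpolating as
#' \eqn{body(\theta) = body\_loss\_max \cdot (1 - \cos\theta)/2}.
#'
#' @param n path-loss exponent (unitless, > 0). Indoor environments typically
#'   sit between 1.8 (open) and 4 (heavily obstructed).
#' @param wall_loss attenuation in dB per intersected wall segment.
#' @param shadow_sigma standard deviation in dB of Gaussian shadowing.
#' @param body_loss_max maximum body attenuation in dB (beacon directly behind).
#' @param interference logical; draw a per-session additive offset?
#' @param interference_range dB range the per-session offset is drawn from.
#' @return An object of class `propagation_model`.
#' @export
propagation_model <- function(n = 2.2, wall_loss = 3, shadow_sigma = 2,
                              body_loss_max = 6, interference = FALSE,
                              interference_range = c(1, 5)) {
  stopifnot(n > 0, wall_loss >= 0, shadow_sigma >= 0, body_loss_max >= 0,
            length(interference_range) == 2L,
            all(interference_range >= 0), diff(interference_range) >= 0)
  structure(list(n = n, wall_loss = wall_loss, shadow_sigma = shadow_sigma,
                 body_loss_max = body_loss_max, interference = interference,
                 interference_range = interference_range),
            class = "propagation_model")
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf(
    "propagation model: n = %.2f, wall %.1f dB, shadowing sd %.1f dB, body <= %.1f dB, interference %s\n",
    x$n, x$wall_loss, x$shadow_sigma, x$body_loss_max,
    if (x$interference) sprintf("[%g, %g] dB", x$interference_range[1],
                                x$interference_range[2]) else "off"))
  invisible(x)
}

#' Simulated RSSI at a position
#'
#' Vectorised over positions/headings for a single beacon. Shadowing uses the
#' current RNG stream; callers that need reproducibility seed it (the
#' `simulate_*` generators do so internally).
#'
#' @param x,y receiver position in metres.
#' @param heading walker heading in radians (direction faced; 0 = +x axis).
#' @param beacon one-row data.frame from [place_beacons()] (`beacon,x,y,p0`).
#' @param model a [propagation_model()].
#' @param plan optional [floorplan()] supplying wall segments; `NULL` means no
#'   wall attenuation.
#' @param interference_offset additive dB offset for this session (default 0).
#' @return Numeric vector of dBm values.
#' @export
rssi_at <- function(x, y, heading, beacon, model, plan = NULL,
                    interference_offset = 0) {
  stopifnot(inherits(model, "propagation_model"), nrow(beacon) == 1L)
  dx <- beacon$x - x
  dy <- beacon$y - y
  d <- pmax(sqrt(dx^2 + dy^2), 0.1)  # clamp: never evaluate inside 0.1 m
  det <- beacon$p0 - 10 * model$n * log10(d)
  if (!is.null(plan) && model$wall_loss > 0) {
    nw <- vapply(seq_along(x), function(i)
      walls_crossed(plan, x[i], y[i], beacon$x, beacon$y), integer(1))
    det <- det - model$wall_loss * nw
  }
  if (model$body_loss_max > 0) {
    theta <- atan2(dy, dx) - heading   # angle of beacon relative to heading
    det <- det - model$body_loss_max * (1 - cos(theta)) / 2
  }
  det <- det + interference_offset
  if (model$shadow_sigma > 0)
    det <- det + stats::rnorm(length(d), 0, model$shadow_sigma)
  det
}

# derive a per-stage sub-seed that stays inside the 32-bit integer range
derive_seed <- function(seed, i) {
  (as.numeric(seed) %% 100000) * 10000 + (as.numeric(i) %% 10000)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
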