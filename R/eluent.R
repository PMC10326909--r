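# Pure-component constants at 25 C used by the mixing rules:
# Snyder polarity index (dimensionless), dynamic viscosity (mPa s),
# surface tension (mN/m). CO2 values are nominal for the decompressed gas
# stream; by default descriptors are computed on the condensed components
# only, so they rarely enter.
.eluent_constants <- data.frame(
  component       = c("water", "methanol", "isopropanol", "acetonitrile", "co2"),
  polarity_index  = c(10.2,     5.1,        3.9,           5.8,            0.0),
  viscosity       = c(0.89,     0.544,      2.04,          0.369,          0.07),
  surface_tension = c(71.99,    22.07,      20.93,         28.66,          1.0),
  stringsAsFactors = FALSE
)

#' Define an SFC gradient program with makeup flow
#'
#' Describes a binary CO2 (A) / organic modifier (B) gradient plus the
#' post-column makeup flow added before the ESI source.
#'
#' @param segments data.frame with columns `t_start`, `t_end` (minutes),
#'   `pct_b_start`, `pct_b_end` (volume % of B). Segments must be contiguous
#'   and non-overlapping with %B in \[0, 100\].
#' @param column_flow Column flow rate, uL/min.
#' @param makeup_flow Makeup flow rate, uL/min.
#' @param makeup_composition Named numeric vector of volume fractions of the
#'   makeup liquid (must sum to 1).
#' @param modifier_additive Name of the additive in the modifier.
#' @param additive_mmol_L Additive concentration, mmol/L.
#' @param water_ph pH of the aqueous phase.
#' @return Object of class `gradient_program`.
#' @export
gradient_program <- function(segments, column_flow, makeup_flow,
                             makeup_composition,
                             modifier_additive = "ammonium acetate",
                             additive_mmol_L = 20,
                             water_ph = 7.0) {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "t_end", "pct_b_start", "pct_b_end") %in%
                  names(segments)))
  segments <- segments[order(segments$t_start), , drop = FALSE]
  if (any(segments$t_end <= segments$t_start)) {
    stop("each segment must have t_end > t_start")
  }
  if (nrow(segments) > 1L &&
      any(abs(segments$t_start[-1L] -
              segments$t_end[-nrow(segments)]) > 1e-9)) {
    stop("segments must be contiguous and non-overlapping")
  }
  if (any(segments$pct_b_start < 0 | segments$pct_b_start > 100 |
          segments$pct_b_end < 0 | segments$pct_b_end > 100)) {
    stop("%B must lie in [0, 100]")
  }
  if (column_flow <= 0 || makeup_flow < 0) stop("flows must be positive")
  if (abs(sum(makeup_composition) - 1) > 1e-9) {
    stop("makeup composition fractions must sum to 1")
  }
  structure(list(segments = segments, column_flow = column_flow,
                 makeup_flow = makeup_flow,
                 makeup_composition = makeup_composition,
                 modifier_additive = modifier_additive,
                 additive_mmol_L = additive_mmol_L,
                 water_ph = water_ph),
            class = "gradient_program")
}

#' The default SFC gradient used throughout the package
#'
#' CO2 (A) vs methanol + 20 mmol/L ammonium acetate (B): 2% B held for 1 min,
#' ramped to 60% B over 6 min, held at 60% for 4 min, returned to 2% within
#' 0.1 min. Column flow 1500 uL/min; makeup flow 200 uL/min of
#' water/isopropanol 90/10 (v/v); aqueous-phase pH 7.
#'
#' @return A [gradient_program()].
#' @export
default_gradient <- function() {
  gradient_program(
    segments = data.frame(
      t_start     = c(0, 1, 7, 11),
      t_end       = c(1, 7, 11, 11.1),
      pct_b_start = c(2, 2, 60, 60),
      pct_b_end   = c(2, 60, 60, 2)
    ),
    column_flow = 1500,
    makeup_flow = 200,
    makeup_composition = c(water = 0.9, isopropanol = 0.1),
    modifier_additive = "ammonium acetate",
    additive_mmol_L = 20,
    water_ph = 7.0
  )
}

#' Percentage of modifier (B) at a given time
#'
#' Piecewise-linear interpolation of the gradient program; times beyond the
#' program are clamped to the nearest segment boundary.
#'
#' @param program A [gradient_program()].
#' @param t Time, minutes (vectorized).
#' @return %B at `t`.
#' @export
percent_b_at <- function(program, t) {
  stopifnot(inherits(program, "gradient_program"))
  seg <- program$segments
  t <- pmin(pmax(t, min(seg$t_start)), max(seg$t_end))
  vapply(t, function(ti) {
    i <- which(ti >= seg$t_start & ti <= seg$t_end)[1L]
    s <- seg[i, ]
    s$pct_b_start + (s$pct_b_end - s$pct_b_start) *
      (ti - s$t_start) / (s$t_end - s$t_start)
  }, 0)
}

#' Mobile-phase component fractions at the ESI inlet
#'
#' Mixes the column flow (split into CO2 and methanol by %B at time `t`)
#' volumetrically with the makeup flow. With `include_co2 = FALSE` (the
#' default downstream) the fractions are renormalized over the condensed
#' components only, reflecting that CO2 decompresses before ionization.
#'
#' @param program A [gradient_program()].
#' @param t Elution time, minutes.
#' @param include_co2 Keep CO2 in the composition?
#' @return Named numeric vector of volume fractions summing to 1.
#' @export
inlet_fractions <- function(program, t, include_co2 = FALSE) {
  pct_b <- percent_b_at(program, t)
  flow_b <- program$column_flow * pct_b / 100
  flow_a <- program$column_flow - flow_b
  flows <- c(co2 = flow_a, methanol = flow_b,
             program$makeup_composition * program$makeup_flow)
  flows <- tapply(flows, names(flows), sum)  # merge duplicate components
  flows <- stats::setNames(as.numeric(flows), names(flows))
  if (!include_co2) flows <- flows[names(flows) != "co2"]
  flows <- flows[flows > 0]
  total <- sum(flows)
  if (total <= 0) stop("no condensed flow at this time point")
  flows / total
}

#' Eluent descriptors of a mobile-phase composition
#'
#' Computes the mobile-phase properties used as model features: Snyder
#' polarity index as the volume-fraction-weighted mean of pure-component
#' indices; viscosity by log-linear mixing, `exp(sum(phi_i * log(eta_i)))`;
#' surface tension as the volume-fraction-weighted mean. Constants are the
#' built-in 25 C table. The pH reported is the aqueous-phase pH of the
#' program, and `nh4_present` records whether the modifier additive is an
#' ammonium salt.
#'
#' @param fractions Named volume fractions summing to 1 (components from the
#'   built-in table: water, methanol, isopropanol, acetonitrile, co2).
#' @param program Optional [gradient_program()] supplying pH and additive;
#'   defaults to [default_gradient()].
#' @return Object of class `eluent_state`: list with `fractions`,
#'   `viscosity` (mPa s), `surface_tension` (mN/m), `polarity_index`, `ph`,
#'   `nh4_present`.
#' @export
eluent_descriptors <- function(fractions, program = default_gradient()) {
  if (abs(sum(fractions) - 1) > 1e-6 || any(fractions < 0)) {
    stop("fractions must be nonnegative and sum to 1")
  }
  unknown <- setdiff(names(fractions), .eluent_constants$component)
  if (length(unknown) > 0L) {
    stop("component(s) missing from the constants table: ",
         paste(unknown, collapse = ", "))
  }
  k <- .eluent_constants[match(names(fractions), .eluent_constants$component), ]
  structure(list(
    fractions = fractions,
    polarity_index = sum(fractions * k$polarity_index),
    viscosity = exp(sum(fractions * log(k$viscosity))),
    surface_tension = sum(fractions * k$surface_tension),
    ph = program$water_ph,
    nh4_present = grepl("ammonium", tolower(program$modifier_additive))
  ), class = "eluent_state")
}

#' @export
print.eluent_state <- function(x, ...) {
  cat(sprintf(
    "<eluent_state> P' = %.2f, viscosity = %.3f mPa s, surface tension = %.1f mN/m, pH = %.1f, NH4+ %s\n",
    x$polarity_index, x$viscosity, x$surface_tension, x$ph,
    if (x$nh4_present) "present" else "absent"))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Eluent descriptors at a retention time
#'
#' Convenience wrapper: composition at the ESI inlet at elution time `rt`,
#' then [eluent_descriptors()].
#'
#' @param program A [gradient_program()].
#' @param rt Retention time, minutes.
#' @param include_co2 Keep CO2 in the composition?
#' @return An `eluent_state`.
#' @export
eluent_at <- function(program, rt, include_co2 = FALSE) {
  eluent_descriptors(inlet_fractions(program, rt, include_co2), program)
}
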