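#' Michaelis-Menten dataset constructor
#'
#' @param substrate substrate concentrations, umol/L.
#' @param velocity initial velocities, umol/L/s.
#' @param e0 enzyme concentration, nmol/L.
#' @return An \linkS4class{MMDataset}.
#' @export
mmDataset <- function(substrate, velocity, e0) {
  new("MMDataset", substrate = as.numeric(substrate),
      velocity = as.numeric(velocity), e0 = e0)
}

#' MM parameters constructor
#'
#' \code{efficiency} is always derived as kcat/Km.
#'
#' @param km umol/L.
#' @param kcat 1/s.
#' @param details optional list of fit diagnostics.
#' @return An \linkS4class{MMParams}.
#' @examples
#' catalyticEfficiency(mmParams(km = 129.8, kcat = 489.0))  # ~3.77 L/umol/s
#' @export
mmParams <- function(km, kcat, details = list()) {
  new("MMParams", km = km, kcat = kcat, efficiency = kcat / km,
      details = details)
}

#' @rdname mmParams
#' @param p an \linkS4class{MMParams}.
#' @export
mmKm <- function(p) p@km

#' @rdname mmParams
#' @export
mmKcat <- function(p) p@kcat

#' @rdname mmParams
#' @export
catalyticEfficiency <- function(p) p@efficiency

setMethod("show", "MMParams", function(object) {
  cat(sprintf("MMParams: Km %.4g umol/L, kcat %.4g 1/s, kcat/Km %.4g L/umol/s\n",
              object@km, object@kcat, object@efficiency))
})

#' Fit Michaelis-Menten parameters
#'
#' Nonlinear least squares on \code{v = kcat * E0 * S / (Km + S)}, with the
#' start values taken from a Hanes-Woolf linearisation (\code{S/v} regressed
#' on \code{S}) and both parameters constrained positive. Requires at least
#' four distinct substrate levels so the curvature around Km is identifiable.
#'
#' @param d an \linkS4class{MMDataset}.
#' @return An \linkS4class{MMParams}; \code{details} carries the nls fit,
#'   Vmax, and residual summary.
#' @export
fitMM <- function(d) {
  S <- d@substrate; v <- d@velocity
  if (length(unique(S)) < 4L)
    stop("need >= 4 distinct substrate concentrations")
  if (all(v <= 0)) stop("no positive velocities")
  e0u <- d@e0 * 1e-3  # nmol/L -> umol/L
  ## Hanes-Woolf: S/v = S/Vmax + Km/Vmax
  keep <- v > 0
  hw <- stats::lm(I(S[keep] / v[keep]) ~ S[keep])
  vmax0 <- unname(1 / coef(hw)[2])
  km0 <- unname(coef(hw)[1]) * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(v)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  fit <- minpack.lm::nlsLM(
    v ~ vmax * S / (km + S),
    data = data.frame(S = S, v = v),
    start = list(vmax = vmax0, km = km0),
    lower = c(vmax = 1e-12, km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  mmParams(km = unname(est["km"]), kcat = unname(est["vmax"]) / e0u,
           details = list(vmax = unname(est["vmax"]),
                          residualSS = sum(stats::resid(fit)^2),
                          converged = fit$convInfo$isConv))
}

## ---- CSV interchange ----

#' Read/write time-course and velocity CSV files
#'
#' Time-course files have columns \code{time_min, value, unit} with unit
#' "U_per_mL" or "nmol_per_L" (constant per file); velocity files have
#' \code{substrate_umol_per_L, velocity_umol_per_L_s}.
#'
#' @param file path.
#' @return A \linkS4class{TimeCourse} / \linkS4class{MMDataset}.
#' @export
readTimeCourseCSV <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_min", "value", "unit")
  if (!all(need %in% names(d))) stop("expected columns: ",
                                     paste(need, collapse = ", "))
  u <- unique(d$unit)
  if (length(u) != 1L) stop("mixed units in time course file")
  timeCourse(d$time_min, d$value, u)
}

#' @rdname readTimeCourseCSV
#' @param tc a \linkS4class{TimeCourse}.
#' @export
writeTimeCourseCSV <- function(tc, file) {
  utils::write.csv(data.frame(time_min = tc@time, value = tc@value,
                              unit = tc@unit), file, row.names = FALSE)
  invisible(file)
}

#' @rdname readTimeCourseCSV
#' @param e0 enzyme concentration (nmol/L) to attach to the dataset.
#' @export
readMMCSV <- function(file, e0) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("substrate_umol_per_L", "velocity_umol_per_L_s")
  if (!all(need %in% names(d))) stop("expected columns: ",
                                     paste(need, collapse = ", "))
  mmDataset(d$substrate_umol_per_L, d$velocity_umol_per_L_s, e0)
}

#' @rdname readTimeCourseCSV
#' @param d an \linkS4class{MMDataset}.
#' @export
writeMMCSV <- function(d, file) {
  utils::write.csv(data.frame(substrate_umol_per_L = d@substrate,
                              velocity_umol_per_L_s = d@velocity),
                   file, row.names = FALSE)
  invisible(file)
}
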