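#' Bliss-independence expected effect of a drug combination
#'
#' Under Bliss independence two drugs act as independent "kill" events, so
#' the expected combined effect is `E_xy = E_x + E_y - E_x * E_y` —
#' algebraically identical to `1 - (1 - E_x)(1 - E_y)`. Effects are
#' fractions of the maximum effect, in \[0, 1\].
#'
#' @param ex,ey single-agent effects in \[0, 1\] (values within 1e-6 outside
#'   are clamped; anything further is an error). Vectorized.
#' @return expected combination effect, in `[max(ex, ey), 1]`.
#' @export
bliss_expected <- function(ex, ey) {
  clamp01 <- function(e, what) {
    if (any(e < -1e-6 | e > 1 + 1e-6)) stop(what, " must lie in [0, 1]")
    pmin(pmax(e, 0), 1)
  }
  ex <- clamp01(ex, "ex")
  ey <- clamp01(ey, "ey")
  ex + ey - ex * ey
}

#' Construct a dose-response matrix object
#'
#' Viability fractions on a dose grid whose first row and column are the
#' single agents (dose 0 of the partner); cell (0, 0) is the untreated well.
#' Viability is normalized to the untreated well, so `v[1, 1] == 1` after
#' construction. Replicate matrices are averaged before normalization.
#'
#' @param viability numeric matrix (doses of drug x in rows, drug y in
#'   columns), or a list of replicate matrices to average.
#' @param dose_x,dose_y strictly ascending dose vectors starting at 0.
#' @param normalize divide by the untreated well (default TRUE).
#' @return object of class `dose_response_matrix`.
#' @export
dose_response_matrix <- function(viability, dose_x, dose_y, normalize = TRUE) {
  if (is.list(viability)) {
    viability <- Reduce(`+`, viability) / length(viability)
  }
  viability <- as.matrix(viability)
  if (nrow(viability) < 2L || ncol(viability) < 2L) {
    stop("dose-response matrix needs a dose-0 row and column plus >= 1 dose each")
  }
  stopifnot(length(dose_x) == nrow(viability), length(dose_y) == ncol(viability))
  if (dose_x[1] != 0 || dose_y[1] != 0) {
    stop("first row/column must be dose 0 (single agents)")
  }
  if (any(diff(dose_x) <= 0) || any(diff(dose_y) <= 0)) {
    stop("doses must be strictly ascending")
  }
  if (normalize) {
    if (viability[1, 1] <= 0) stop("untreated well must be positive")
    viability <- viability / viability[1, 1]
  }
  structure(
    list(viability = viability, dose_x = dose_x, dose_y = dose_y),
    class = "dose_response_matrix"
  )
}

#' Deviation from Bliss additivity across a dose-response matrix
#'
#' Converts viabilities to effects `E = 1 - v` (clamped to \[0, 1\]; raw
#' values are kept in the `effect_raw` attribute), takes the single-agent
#' effects from the dose-0 row/column and computes, for every interior cell,
#' `d(i, j) = E_obs(i, j) - bliss_expected(E_x(i), E_y(j))`. Positive
#' deviation indicates synergy.
#'
#' @param drm a `dose_response_matrix`.
#' @return list of class `synergy_matrix` with `deviation` (interior cells
#'   only), `max_deviation`, `mean_deviation`.
#' @export
synergy_matrix <- function(drm) {
  stopifnot(inherits(drm, "dose_response_matrix"))
  v <- drm$viability
  e_raw <- 1 - v
  e <- pmin(pmax(e_raw, 0), 1)
  ex <- e[-1, 1]   # single-agent effects of drug x
  ey <- e[1, -1]
  expected <- outer(ex, ey, bliss_expected)
  d <- e[-1, -1, drop = FALSE] - expected
  rownames(d) <- drm$dose_x[-1]
  colnames(d) <- drm$dose_y[-1]
  attr(d, "effect_raw") <- e_raw
  structure(
    list(deviation = d,
         max_deviation = max(d),
         mean_deviation = mean(d)),
    class = "synergy_matrix"
  )
}

#' @export
print.synergy_matrix <- function(x, ...) {
  cat(sprintf("Bliss deviation over %d x %d combination doses\n",
              nrow(x$deviation), ncol(x$deviation)))
  cat(sprintf("  mean deviation: %+.4f   max deviation: %+.4f\n",
              x$mean_deviation, x$max_deviation))
  invisible(x)
}

#' Read a dose-response matrix CSV
#'
#' First row and first column hold dose labels; cell (0, 0) region holds the
#' untreated well at dose 0/0.
#'
#' @param path file path.
#' @param normalize passed to [dose_response_matrix()].
#' @export
read_dose_response <- function(path, normalize = TRUE) {
  raw <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  dose_response_matrix(raw, dose_x = as.numeric(rownames(raw)),
                       dose_y = as.numeric(colnames(raw)),
                       normalize = normalize)
}

#' Write a dose-response matrix CSV
#' @param drm a `dose_response_matrix`.
#' @param path output file path.
#' @export
write_dose_response <- function(drm, path) {
  m <- drm$viability
  rownames(m) <- drm$dose_x
  colnames(m) <- drm$dose_y
  write.csv(m, path, quote = FALSE)
  invisible(path)
}

#' Write a Bliss deviation matrix CSV
#' @param syn a `synergy_matrix`.
#' @param path output file path.
#' @export
write_synergy <- function(syn, path) {
  write.csv(syn$deviation, path, quote = FALSE)
  invisible(path)
}
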