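# HSQC titration analysis: peak matching, chemical-shift perturbation,
# urea-denaturation persistence per secondary-structure element, and
# relaxation curve fitting.

.unflagged <- function(peaks) {
  peaks[!nzchar(peaks$flags), , drop = FALSE]
}

#' Match peaks of two lists by residue and position
#'
#' A reference peak is matched when the same residue appears in `other`
#' with |dH| <= `tol_h` and |dN| <= `tol_n`; otherwise the residue is
#' missing. Peaks flagged overlapped/unresolved are excluded from both
#' sides before matching.
#'
#' @param reference,other [peak_list()]s.
#' @param tol_h,tol_n matching tolerances in ppm (defaults 0.04 / 0.4,
#'   typical HSQC linewidths).
#' @return list with `matched` (data.frame `residue`, `dh`, `dn`) and
#'   `missing` (residue numbers).
#' @export
match_peaks <- function(reference, other, tol_h = 0.04, tol_n = 0.4) {
  reference <- peak_list(reference)
  other <- peak_list(other)
  ref <- .unflagged(reference)
  oth <- .unflagged(other)
  i <- match(ref$residue, oth$residue)
  dh <- oth$h_ppm[i] - ref$h_ppm
  dn <- oth$n_ppm[i] - ref$n_ppm
  ok <- !is.na(i) & abs(dh) <= tol_h & abs(dn) <= tol_n
  list(matched = data.frame(residue = ref$residue[ok], dh = dh[ok],
                            dn = dn[ok]),
       missing = ref$residue[!ok])
}

#' Combined amide chemical-shift perturbation
#'
#' CSP = sqrt(dH^2 + (0.15 dN)^2), the standard 15N-downweighted combined
#' backbone NH shift change in ppm.
#'
#' @param dh,dn 1H and 15N shift changes in ppm (vectorised).
#' @return CSP in ppm.
#' @export
csp_delta <- function(dh, dn) sqrt(dh^2 + (0.15 * dn)^2)

#' CSP between two peaks of the same residue
#'
#' @param ref,moved single-row peak records (`residue`, `h_ppm`, `n_ppm`).
#' @return CSP in ppm.
#' @export
csp <- function(ref, moved) {
  if (ref$residue != moved$residue) stop("peaks belong to different residues")
  csp_delta(moved$h_ppm - ref$h_ppm, moved$n_ppm - ref$n_ppm)
}

#' Per-residue CSP profile and binding classification for a titration
#'
#' Computes the per-residue CSP between the reference (level 0) and the
#' final titration point (the maximum-shift convention for an endpoint in
#' excess titrant), classifies residues with CSP >= `threshold` as
#' perturbed, and calls "binds" iff at least one residue is perturbed.
#'
#' @param series a [titration_series()] with at least two points.
#' @param threshold classification cut-off in ppm (default 0.15).
#' @return list of class `"csp_result"`: `profile` (data.frame `residue`,
#'   `dh`, `dn`, `csp`), `threshold`, `perturbed` (residues), `binds`.
#' @export
csp_profile <- function(series, threshold = 0.15) {
  stopifnot(inherits(series, "titration_series"))
  if (length(series$levels) < 2) stop("need at least two titration points")
  ref <- .unflagged(series$peaklists[[1]])
  fin <- .unflagged(series$peaklists[[length(series$peaklists)]])
  i <- match(ref$residue, fin$residue)
  ok <- !is.na(i)
  if (!any(ok)) stop("no residues in common between reference and endpoint")
  dh <- fin$h_ppm[i[ok]] - ref$h_ppm[ok]
  dn <- fin$n_ppm[i[ok]] - ref$n_ppm[ok]
  prof <- data.frame(residue = ref$residue[ok], dh = dh, dn = dn,
                     csp = csp_delta(dh, dn))
  perturbed <- prof$residue[prof$csp >= threshold]
  structure(list(profile = prof, threshold = threshold,
                 perturbed = perturbed, binds = length(perturbed) > 0),
            class = "csp_result")
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf("CSP profile: %d residues, max %.4f ppm, threshold %.2f\n",
              nrow(x$profile), max(x$profile$csp), x$threshold))
  cat(sprintf("  perturbed: %d -> verdict: %s\n", length(x$perturbed),
              if (x$binds) "binds" else "no binding"))
  invisible(x)
}

#' Peak persistence per secondary-structure element along a denaturation
#'
#' For each titration level, the percentage of reference (level 0) peaks
#' still observed — matched within tolerance by [match_peaks()] — is
#' reported per SSE and overall. An SSE with no reference peaks is
#' reported as NA (undefined), not 0.
#'
#' @param series a [titration_series()] (e.g. a urea series).
#' @param sse an `"sse_map"` (see [read_sse_map()]).
#' @param tol_h,tol_n matching tolerances in ppm.
#' @return list of class `"persistence_result"`: `by_sse` (data.frame
#'   `level`, `sse`, `percent`, `n_ref`), `overall` (data.frame `level`,
#'   `percent`).
#' @export
persistence_profile <- function(series, sse, tol_h = 0.04, tol_n = 0.4) {
  stopifnot(inherits(series, "titration_series"))
  ref <- .unflagged(series$peaklists[[1]])
  assign_sse <- sse_assign(sse, ref$residue)
  sses <- unique(sse$name)
  rows <- list(); overall <- list()
  for (k in seq_along(series$levels)) {
    obs <- if (k == 1) ref$residue else
      match_peaks(series$peaklists[[1]], series$peaklists[[k]],
                  tol_h = tol_h, tol_n = tol_n)$matched$residue
    for (s in sses) {
      members <- ref$residue[!is.na(assign_sse) & assign_sse == s]
      pct <- if (length(members) == 0) NA_real_ else
        100 * sum(members %in% obs) / length(members)
      rows[[length(rows) + 1L]] <-
        data.frame(level = series$levels[k], sse = s, percent = pct,
                   n_ref = length(members), stringsAsFactors = FALSE)
    }
    overall[[k]] <- data.frame(level = series$levels[k],
                               percent = 100 * sum(ref$residue %in% obs) /
                                 nrow(ref))
  }
  structure(list(by_sse = do.call(rbind, rows),
                 overall = do.call(rbind, overall),
                 axis_label = series$axis_label),
            class = "persistence_result")
}

# ---- relaxation -----------------------------------------------------------

#' Fit a single-exponential relaxation decay
#'
#' Least-squares fit of I(t) = I0 exp(-t/T) to intensity-vs-delay data,
#' initialised from the log-linear fit. Suitable for T1/T2 series.
#'
#' @param delays relaxation delays in seconds (>= 3 distinct values).
#' @param intensities positive peak intensities, one per delay.
#' @return list with `T` (time constant, s), `I0`, `se` (standard errors),
#'   and the `fit` object.
#' @export
fit_exponential_decay <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  if (length(unique(delays)) < 3) stop("need at least 3 distinct delays")
  if (any(intensities <= 0)) stop("intensities must be positive")
  lf <- lm(log(intensities) ~ delays)
  slope <- coef(lf)[[2]]
  if (slope >= 0 || abs(slope) * diff(range(delays)) < 1e-8)
    stop("no decay detected (non-negative or negligible slope)")
  start <- list(I0 = exp(coef(lf)[[1]]), tau = -1 / slope)
  fit <- tryCatch(
    minpack.lm::nlsLM(intensities ~ I0 * exp(-delays / tau), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("relaxation fit did not converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, tau = NA_real_))
  if (est[["tau"]] <= 0) warning("non-positive time constant estimate")
  list(T = est[["tau"]], I0 = est[["I0"]],
       se = c(I0 = unname(se[["I0"]]), T = unname(se[["tau"]])), fit = fit)
}

#' Steady-state heteronuclear NOE ratios
#'
#' @param saturated,reference named (by residue) or plain intensity
#'   vectors over the same residue set.
#' @return per-residue ratio saturated / reference.
#' @export
hetnoe <- function(saturated, reference) {
  stopifnot(length(saturated) == length(reference))
  if (!is.null(names(saturated)) && !is.null(names(reference))) {
    if (!setequal(names(saturated), names(reference)))
      stop("residue sets differ")
    reference <- reference[names(saturated)]
  }
  if (any(reference == 0)) stop("zero reference intensity")
  saturated / reference
}
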