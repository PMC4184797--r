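make_peaks <- function(res = 1:10, h = NULL, n = NULL, inten = 100,
                       flags = "") {
  set.seed(99)
  if (is.null(h)) h <- runif(length(res), 7.5, 9.5)
  if (is.null(n)) n <- runif(length(res), 105, 130)
  peak_list(data.frame(residue = res, h_ppm = h, n_ppm = n,
                       intensity = rep_len(inten, length(res)),
                       flags = rep_len(flags, length(res)),
                       stringsAsFactors = FALSE))
}

test_that("peak matching identifies identical, missing and shifted peaks", {
  ref <- make_peaks()
  r <- match_peaks(ref, ref)
  expect_equal(nrow(r$matched), 10)
  expect_length(r$missing, 0)
  r2 <- match_peaks(ref, ref[ref$residue != 5, ])
  expect_identical(r2$missing, 5L)
  expect_error(match_peaks(ref, rbind(ref, ref[1, ])), "duplicate residue")
})

test_that("peak matching against exhaustive per-residue check", {
  set.seed(4)
  ref <- make_peaks(res = 1:10)
  oth <- ref
  moved <- c(2, 6, 9)
  oth$h_ppm[moved] <- oth$h_ppm[moved] + 0.2   # beyond tol_h = 0.04
  r <- match_peaks(ref, oth)
  # brute force: same residue, both windows
  brute <- vapply(ref$residue, function(rr) {
    j <- which(oth$residue == rr)
    length(j) == 1 && abs(oth$h_ppm[j] - ref$h_ppm[ref$residue == rr]) <=
      0.04 && abs(oth$n_ppm[j] - ref$n_ppm[ref$residue == rr]) <= 0.4
  }, logical(1))
  expect_setequal(r$missing, ref$residue[!brute])
  expect_setequal(r$matched$residue, ref$residue[brute])
  # infinite tolerances: missing reduces to residues absent from `other`
  r3 <- match_peaks(ref, oth[oth$residue != 7, ], tol_h = Inf, tol_n = Inf)
  expect_identical(r3$missing, 7L)
})

test_that("flagged peaks are excluded from both sides of the analysis", {
  ref <- make_peaks(flags = c(rep("", 8), "overlapped", "unresolved"))
  r <- match_peaks(ref, ref)
  expect_equal(nrow(r$matched), 8)
  expect_false(any(c(9, 10) %in% r$matched$residue))
  expect_length(r$missing, 0)
})

test_that("the combined CSP formula reproduces its worked values", {
  expect_equal(csp_delta(0.10, 0), 0.10)
  expect_equal(csp_delta(0, 1.00), 0.15)
  expect_equal(csp_delta(0.12, 0.80), sqrt(0.12^2 + 0.12^2))
  expect_equal(round(csp_delta(0.12, 0.80), 4), 0.1697)
  # symmetric in argument order and invariant to common axis offsets
  a <- list(residue = 1, h_ppm = 8.1, n_ppm = 119.2)
  b <- list(residue = 1, h_ppm = 8.3, n_ppm = 118.1)
  expect_equal(csp(a, b), csp(b, a))
  shift <- function(p, dh, dn)
    list(residue = 1, h_ppm = p$h_ppm + dh, n_ppm = p$n_ppm + dn)
  expect_equal(csp(shift(a, 1.3, -20), shift(b, 1.3, -20)), csp(a, b))
  expect_error(csp(a, list(residue = 2, h_ppm = 8, n_ppm = 119)),
               "different residues")
})

test_that("CSP profile classifies perturbed residues at the threshold", {
  # no change: all zero, verdict no binding
  flat <- make_titration_series(20, levels = c(0, 2, 5))
  r <- csp_profile(flat)
  expect_equal(max(r$profile$csp), 0)
  expect_false(r$binds)
  # exactly 5 residues engineered over the cut-off
  hit <- data.frame(residue = c(3, 7, 11, 15, 19), dh = 0.25, dn = 0)
  series <- make_titration_series(20, levels = c(0, 2, 5),
                                  csp_endpoints = hit)
  r2 <- csp_profile(series)
  expect_setequal(r2$perturbed, hit$residue)
  expect_true(r2$binds)
})

test_that("sub-threshold shifts give a no-binding verdict", {
  # strongest perturbation engineered at 0.12 ppm, below the 0.15 cut-off
  ends <- data.frame(residue = c(5, 9, 14), dh = c(0.12, 0.08, 0.05),
                     dn = c(0, 0.2, -0.2))
  series <- make_titration_series(30, levels = c(0, 1, 2, 5),
                                  csp_endpoints = ends)
  r <- csp_profile(series, threshold = 0.15)
  expect_equal(max(r$profile$csp), 0.12, tolerance = 1e-9)
  expect_false(r$binds)
  expect_length(r$perturbed, 0)
})

test_that("persistence is 100% at the reference and tracks deletions", {
  sse <- validate_sse_map(data.frame(name = c("b1", "L1"),
                                     start = c(1, 11), end = c(10, 15),
                                     kind = c("strand", "loop")))
  del <- data.frame(residue = 11:15, level = 4)
  series <- make_titration_series(15, levels = c(0, 2, 4, 6),
                                  disappearance = del)
  p <- persistence_profile(series, sse)
  at <- function(lv, el) p$by_sse$percent[p$by_sse$level == lv &
                                            p$by_sse$sse == el]
  expect_equal(at(0, "b1"), 100)
  expect_equal(at(0, "L1"), 100)
  expect_equal(at(2, "L1"), 100)
  expect_equal(at(4, "L1"), 0)
  expect_equal(at(6, "b1"), 100)
  expect_equal(p$overall$percent, c(100, 100, 200 / 3, 200 / 3))
})

test_that("an SSE with no reference peaks reports NA, not zero", {
  sse <- validate_sse_map(data.frame(name = c("b1", "b2"),
                                     start = c(1, 50), end = c(10, 60),
                                     kind = "strand"))
  series <- make_titration_series(10, levels = c(0, 1))
  p <- persistence_profile(series, sse)
  expect_true(all(is.na(p$by_sse$percent[p$by_sse$sse == "b2"])))
  expect_true(all(p$by_sse$percent[p$by_sse$sse == "b1"] == 100))
})

test_that("persistence is monotone under a monotone deletion schedule", {
  set.seed(2)
  sse <- validate_sse_map(data.frame(name = "all", start = 1, end = 60,
                                     kind = "strand"))
  del <- data.frame(residue = sample(1:60, 30),
                    level = sample(c(1, 2, 3, 4), 30, replace = TRUE))
  series <- make_titration_series(60, levels = 0:5, disappearance = del)
  p <- persistence_profile(series, sse)
  expect_true(all(diff(p$overall$percent) <= 0))
})

test_that("exponential decay fitting recovers T1-style time constants", {
  delays <- c(4, 10, 20, 40, 60, 80, 120, 160, 220, 280, 340) * 1e-3
  clean <- 100 * exp(-delays / 0.5)
  fit <- fit_exponential_decay(delays, clean)
  expect_equal(fit$T, 0.5, tolerance = 1e-6)
  expect_equal(fit$I0, 100, tolerance = 1e-6)
  expect_error(fit_exponential_decay(delays, rep(50, length(delays))),
               "no decay")
  expect_error(fit_exponential_decay(c(1, 1, 1) * 1e-3, c(3, 2, 1)),
               "3 distinct")
  set.seed(6)
  noisy <- clean + rnorm(length(delays), 0, 1)   # 1% of I0
  fit2 <- fit_exponential_decay(delays, noisy)
  expect_lt(abs(fit2$T / 0.5 - 1), 0.05)
})

test_that("heteronuclear NOE ratios recover per-residue factors", {
  ref <- c(r10 = 120, r11 = 80, r12 = 200)
  expect_equal(unname(hetnoe(ref, ref)), c(1, 1, 1))
  expect_equal(unname(hetnoe(0.8 * ref, ref)), rep(0.8, 3))
  set.seed(31)
  fac <- runif(3, 0.4, 1)
  expect_equal(unname(hetnoe(ref * fac, ref)), fac)
  expect_error(hetnoe(ref, c(r10 = 0, r11 = 1, r12 = 1)), "zero reference")
})
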