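#' Construct a FRAP trace
#'
#' Raw three-channel fluorescence-recovery-after-photobleaching time series:
#' the bleached region of interest (I), the whole nucleus (T) and an
#' extracellular background region (BG). `bleach_frame` indexes the first
#' post-bleach frame; the `n_prebleach` frames before it are the prescans.
#'
#' @param times acquisition times in seconds, strictly increasing
#' @param bleached_roi mean intensity of the bleached region per frame (AU)
#' @param whole_nucleus mean intensity of the whole nucleus per frame (AU)
#' @param background background intensity per frame (AU; a scalar is recycled)
#' @param bleach_frame index (1-based) of the first post-bleach frame
#' @param n_prebleach number of prebleach prescans (>= 2)
#' @param cell_id,treatment,concentration optional metadata
#' @return object of class `frap_trace`
#' @export
frap_trace <- function(times, bleached_roi, whole_nucleus, background,
                       bleach_frame = 6L, n_prebleach = 5L,
                       cell_id = "cell", treatment = NA_character_,
                       concentration = NA_real_) {
  nfr <- length(times)
  background <- rep(as.numeric(background), length.out = nfr)
  if (length(bleached_roi) != nfr || length(whole_nucleus) != nfr)
    abort_pt("frap trace: channel lengths must match times")
  if (any(diff(times) <= 0))
    abort_pt("frap trace: times must be strictly increasing")
  if (n_prebleach < 2) abort_pt("frap trace: need at least 2 prebleach frames")
  if (bleach_frame <= n_prebleach)
    abort_pt("frap trace: bleach_frame must follow the prebleach frames")
  structure(
    list(times = as.numeric(times), bleached_roi = as.numeric(bleached_roi),
         whole_nucleus = as.numeric(whole_nucleus), background = background,
         bleach_frame = as.integer(bleach_frame),
         n_prebleach = as.integer(n_prebleach),
         cell_id = cell_id, treatment = treatment,
         concentration = concentration),
    class = "frap_trace"
  )
}

#' Double-normalize a FRAP trace
#'
#' Relative fluorescence of the bleached region, corrected for background
#' and for whole-nucleus acquisition losses:
#' \deqn{rel(t) = \frac{(\bar T_{pre} - BG)(I_t - BG)}{(T_t - BG)(\bar I_{pre} - BG)}}
#' The prebleach averages are taken over the background-corrected ratio
#' \eqn{(I-BG)/(T-BG)}, which is identical to the product form when the
#' prebleach signals are steady and guarantees that the prebleach frames of
#' the output average to exactly 1. The result is invariant to a joint
#' multiplicative gain or acquisition-bleaching factor on I and T and to an
#' additive offset captured by BG.
#'
#' @param trace a [frap_trace()]
#' @return numeric vector of relative fluorescence per frame
#' @export
normalize_trace <- function(trace) {
  i_bg <- trace$bleached_roi - trace$background
  t_bg <- trace$whole_nucleus - trace$background
  bad <- which(t_bg == 0)
  if (length(bad))
    abort_pt("zero nucleus-minus-background denominator at frame ", bad[1])
  pre <- seq(trace$bleach_frame - trace$n_prebleach, trace$bleach_frame - 1)
  ratio <- i_bg / t_bg
  pre_mean <- mean(ratio[pre])
  if (pre_mean == 0)
    abort_pt("zero prebleach ROI-minus-background average")
  ratio / pre_mean
}

#' Rescale a normalized recovery curve to [0, 1]
#'
#' Affine rescaling of the double-normalized signal so that the first
#' post-bleach frame maps to 0 (baseline) and the prebleach mean maps to 1.
#' Curves already on that scale are unchanged; a full-depth bleach (first
#' post-bleach value 0) makes the rescaling the identity.
#'
#' @param rel relative fluorescence from [normalize_trace()]
#' @param bleach_frame index of the first post-bleach frame
#' @return rescaled curve, same length
#' @export
rescale_recovery <- function(rel, bleach_frame) {
  v0 <- rel[bleach_frame]
  if (v0 == 1)
    abort_pt("no bleach depth: first post-bleach value equals the prebleach level")
  (rel - v0) / (1 - v0)
}

#' Fit a single-exponential recovery and extract the half-time
#'
#' Fits \eqn{y(t) = A (1 - e^{-kt})} to the post-bleach frames of the
#' rescaled curve (t measured from the first post-bleach frame). The plateau
#' A is profiled linearly; k is found by golden-section/Brent search on the
#' log scale. `t_half = ln 2 / k`; the mobile fraction is reported as the
#' plateau of the rescaled curve. `method = "interpolation"` instead takes
#' the first linear-interpolated crossing of half the plateau.
#'
#' @param trace a [frap_trace()], or `NULL` if `curve`/`times` given directly
#' @param curve optional rescaled recovery curve (overrides `trace`)
#' @param times optional times matching `curve`
#' @param bleach_frame index of the first post-bleach frame (with `curve`)
#' @param method `"exponential"` (default) or `"interpolation"`
#' @return object of class `recovery_result`: `t_half` (s),
#'   `mobile_fraction`, `plateau`, `rate` (1/s), `fit_rmse`, `converged`,
#'   metadata
#' @export
fit_recovery <- function(trace = NULL, curve = NULL, times = NULL,
                         bleach_frame = NULL, method = c("exponential", "interpolation")) {
  method <- match.arg(method)
  meta <- list(cell_id = NA_character_, treatment = NA_character_,
               concentration = NA_real_)
  if (!is.null(trace)) {
    rel <- normalize_trace(trace)
    curve <- rescale_recovery(rel, trace$bleach_frame)
    times <- trace$times
    bleach_frame <- trace$bleach_frame
    meta <- trace[c("cell_id", "treatment", "concentration")]
  }
  if (is.null(curve) || is.null(times) || is.null(bleach_frame))
    abort_pt("supply either a frap_trace or curve + times + bleach_frame")
  post <- seq(bleach_frame, length(curve))
  if (length(post) < 8) abort_pt("need at least 8 post-bleach frames")
  t <- times[post] - times[bleach_frame]
  y <- curve[post]

  res <- structure(
    c(meta, list(t_half = NA_real_, mobile_fraction = NA_real_,
                 plateau = NA_real_, rate = NA_real_, fit_rmse = NA_real_,
                 converged = FALSE, method = method)),
    class = "recovery_result"
  )

  profile_A <- function(k) {
    g <- 1 - exp(-k * t)
    ss_g <- sum(g * g)
    if (ss_g == 0) return(list(A = 0, sse = sum(y^2)))
    A <- sum(y * g) / ss_g
    list(A = A, sse = sum((y - A * g)^2))
  }
  span <- diff(range(t[t > 0]))
  lo <- log(1e-4 / max(span, 1)); hi <- log(1e3)
  opt <- optimize(function(lk) profile_A(exp(lk))$sse, c(lo, hi), tol = 1e-12)
  # refine with a local parabolic pass around the optimum
  opt2 <- optimize(function(lk) profile_A(exp(lk))$sse,
                   opt$minimum + c(-0.05, 0.05), tol = 1e-14)
  if (opt2$objective < opt$objective) opt <- opt2
  k_hat <- exp(opt$minimum)
  pr <- profile_A(k_hat)
  if (!is.finite(pr$A) || pr$A <= 0 || k_hat <= 1.01e-4 / max(span, 1)) {
    return(res) # unconverged, excluded from group statistics
  }
  res$rate <- k_hat
  res$plateau <- pr$A
  res$mobile_fraction <- pr$A
  res$fit_rmse <- sqrt(pr$sse / length(y))
  res$converged <- TRUE
  if (method == "exponential") {
    res$t_half <- log(2) / k_hat
  } else {
    half <- pr$A / 2
    above <- which(y >= half)
    if (!length(above)) return(structure(modifyList(res, list(converged = FALSE)),
                                         class = "recovery_result"))
    i <- above[1]
    if (i == 1) {
      res$t_half <- t[1]
    } else {
      res$t_half <- t[i - 1] + (half - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
    }
  }
  res
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result> %s: t1/2 = %.3f s  mobile = %.3f  k = %.4f /s (%s)\n",
              x$cell_id, x$t_half, x$mobile_fraction, x$rate, x$method))
  invisible(x)
}

#' Compare recovery half-times between two treatment groups
#'
#' Two-tailed t-test on per-cell half-times, paired or unpaired. Identical
#' zero-variance groups (difference exactly 0 everywhere) return t = 0,
#' p = 1 rather than the 0/0 indeterminate.
#'
#' @param treated,control lists of `recovery_result` (or numeric vectors of
#'   half-times); unconverged results are dropped
#' @param paired logical; paired test requires equal n
#' @return tibble: `mean_diff` (treated - control), `t`, `df`, `p_value`,
#'   `n_treated`, `n_control`, `paired`
#' @export
compare_groups <- function(treated, control, paired = FALSE) {
  pull_th <- function(x) {
    if (is.numeric(x)) return(x)
    x <- Filter(function(r) isTRUE(r$converged), x)
    vapply(x, `[[`, numeric(1), "t_half")
  }
  a <- pull_th(treated); b <- pull_th(control)
  if (length(a) < 2 || length(b) < 2)
    abort_pt("need at least 2 usable results per group")
  if (paired && length(a) != length(b))
    abort_pt("paired comparison requires equal group sizes")
  diffs_zero <- if (paired) all(a - b == 0) else
    (mean(a) == mean(b) && sd(a) == 0 && sd(b) == 0)
  if (diffs_zero || (paired && sd(a - b) == 0 && mean(a - b) == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(a) - 1),
               p.value = 1)
  } else {
    tt <- tryCatch(
      t.test(a, b, paired = paired, alternative = "two.sided"),
      error = function(e) {
        # zero-variance but nonzero shift: infinitely significant
        list(statistic = c(t = sign(mean(a) - mean(b)) * Inf),
             parameter = c(df = length(a) - 1), p.value = 0)
      }
    )
  }
  tibble::tibble(
    mean_diff = mean(a) - mean(b),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_treated = length(a),
    n_control = length(b),
    paired = paired
  )
}

#' Per-group summary of recovery half-times
#'
#' Mean, SEM and n of the half-times of converged fits, by group label.
#'
#' @param results list of `recovery_result`
#' @param group character vector of group labels, same length
#' @return tibble `group`, `t_half_mean`, `t_half_sem`, `n`
#' @export
summarize_recovery <- function(results, group) {
  keep <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  th <- vapply(results[keep], `[[`, numeric(1), "t_half")
  g <- group[keep]
  out <- lapply(split(th, g), function(v) {
    tibble::tibble(t_half_mean = mean(v),
                   t_half_sem = sd(v) / sqrt(length(v)), n = length(v))
  })
  dplyr::bind_rows(out, .id = "group")
}
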