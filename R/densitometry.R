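#' Construct a gel-lane intensity profile
#'
#' A lane profile is the 1-D record of a densitometric scan along one gel
#' lane: monotone pixel positions and non-negative intensities in arbitrary
#' units. All quantification operates on this representation.
#'
#' @param position Monotone increasing numeric vector (pixels).
#' @param intensity Finite, non-negative numeric vector of equal length.
#' @param lane_id Label for the lane.
#' @return A tibble of class `lane_profile` with columns `position` and
#'   `intensity` and a `lane_id` attribute.
#' @export
lane_profile <- function(position, intensity, lane_id = "lane") {
  stopifnot(length(position) == length(intensity))
  if (length(position) < 32L) {
    stop("a lane profile needs at least 32 samples", call. = FALSE)
  }
  if (any(diff(position) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  out <- tibble::tibble(position = as.numeric(position),
                        intensity = as.numeric(intensity))
  class(out) <- c("lane_profile", class(out))
  attr(out, "lane_id") <- lane_id
  out
}

#' Read a lane profile from CSV
#'
#' Expects a two-column CSV `position,intensity` with a header.
#'
#' @param path CSV path.
#' @param lane_id Label (defaults to the file name).
#' @return A `lane_profile`.
#' @export
read_lane_profile <- function(path, lane_id = basename(path)) {
  d <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!all(c("position", "intensity") %in% names(d))) {
    stop("lane CSV must have columns 'position' and 'intensity'",
         call. = FALSE)
  }
  lane_profile(d$position, d$intensity, lane_id = lane_id)
}

# centered running mean with truncated windows at the edges
smooth_mean <- function(x, window) {
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centered running min/max in O(n) (van Herk block decomposition);
# edge windows are truncated to the available data
roll_extreme <- function(x, window, fun) {
  minimum <- identical(fun, min)
  cmb <- if (minimum) pmin else pmax
  pad <- if (minimum) Inf else -Inf
  n <- length(x)
  half <- window %/% 2L
  w <- 2L * half + 1L
  y <- c(rep(pad, half), x, rep(pad, half))
  k <- ceiling(length(y) / w) * w
  y <- c(y, rep(pad, k - length(y)))
  m <- matrix(y, nrow = w)
  L <- m
  for (i in 2:w) L[i, ] <- cmb(L[i - 1L, ], m[i, ])
  R <- m
  for (i in (w - 1L):1L) R[i, ] <- cmb(R[i + 1L, ], m[i, ])
  Lv <- as.vector(L)
  Rv <- as.vector(R)
  starts <- seq_len(n)               # window over y[start .. start + w - 1]
  cmb(Rv[starts], Lv[starts + w - 1L])
}

#' Remove the lane baseline by morphological opening
#'
#' Estimates the baseline as a rolling-minimum followed by a rolling-maximum
#' (a 1-D morphological opening) with the given window, and subtracts it.
#' Bands (and clusters of adjacent bands) narrower than the window are preserved, so the window should exceed the widest band cluster; any slowly varying offset
#' or ramp is removed. Output intensities are clamped at zero.
#'
#' @param profile A `lane_profile`.
#' @param window Structuring-element width in samples; must be at least 3,
#'   smaller than the profile, and comfortably wider than the widest band
#'   cluster (default 201).
#' @return A background-subtracted `lane_profile`.
#' @export
subtract_background <- function(profile, window = 201L) {
  if (window < 3L || window >= nrow(profile)) {
    stop("background window must be in [3, profile length)", call. = FALSE)
  }
  # estimate the baseline on a lightly smoothed copy so the rolling minimum
  # tracks the background trend rather than the noise minimum envelope
  sm <- smooth_mean(profile$intensity, 15L)
  # extend by linear extrapolation so the opening has full support at the
  # edges (a truncated opening under-reaches a ramp by slope * window / 2)
  n <- length(sm)
  half <- window %/% 2L
  fit_line <- function(idx) {
    cf <- stats::coef(stats::lm.fit(cbind(1, idx), sm[idx]))
    function(i) cf[1] + cf[2] * i
  }
  left <- fit_line(seq_len(min(window, n)))
  right <- fit_line(seq.int(max(1L, n - min(window, n) + 1L), n))
  ext <- c(left(seq.int(1L - half, 0L)), sm, right(seq.int(n + 1L, n + half)))
  eroded <- roll_extreme(ext, window, min)
  baseline <- roll_extreme(eroded, window, max)[half + seq_len(n)]
  res <- profile$intensity - baseline
  res[abs(res) < 1e-8 * max(abs(baseline), 1)] <- 0
  out <- profile
  out$intensity <- pmax(res, 0)
  out
}

# local maxima with topographic prominence
find_peaks <- function(y) {
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(cand) == 0L) return(tibble::tibble(index = integer(),
                                                prominence = numeric()))
  prom <- vapply(cand, function(i) {
    # walk left/right until terrain rises above the peak; track valley depth
    left <- i; lv <- y[i]
    while (left > 1L && y[left - 1L] <= y[i]) {
      left <- left - 1L
      lv <- min(lv, y[left])
    }
    if (left == 1L) lv <- min(lv, y[1L])
    right <- i; rv <- y[i]
    while (right < n && y[right + 1L] <= y[i]) {
      right <- right + 1L
      rv <- min(rv, y[right])
    }
    if (right == n) rv <- min(rv, y[n])
    y[i] - max(lv, rv)
  }, numeric(1))
  tibble::tibble(index = cand, prominence = prom)
}

trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}

#' Detect bands and integrate their areas
#'
#' Smooths the background-subtracted profile lightly (running mean,
#' `smooth_window` samples), keeps local maxima whose topographic prominence
#' is at least `min_prominence` of the profile maximum, integrates each band
#' between its flanking valleys (trapezoidal rule on the unsmoothed
#' profile), and expresses areas as percentages of the lane total.
#'
#' @param profile A background-subtracted `lane_profile`.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   profile maximum (default 0.05).
#' @param smooth_window Running-mean window for peak finding (default 9;
#'   set to 1 to disable).
#' @return A tibble of band calls: `center` (pixel), `left`, `right`
#'   (integration bounds), `area`, `fraction` (percent of lane total).
#'   Empty when no band is found.
#' @export
detect_bands <- function(profile, min_prominence = 0.05, smooth_window = 9L) {
  y <- profile$intensity
  x <- profile$position
  ys <- if (smooth_window > 1L) smooth_mean(y, smooth_window) else y
  pk <- find_peaks(ys)
  # residual noise floor after background subtraction; most of a lane is
  # band-free, so the median tracks the floor and the MAD its spread
  floor_lvl <- stats::median(ys) + 2 * stats::mad(ys)
  # noise-adaptive detection: a band must beat both the relative prominence
  # threshold and the noise fluctuation scale, and rise clearly above floor
  thr <- max(min_prominence * max(ys), 6 * stats::mad(ys))
  pk <- pk[pk$prominence >= thr & ys[pk$index] >= floor_lvl + thr, ,
           drop = FALSE]
  if (nrow(pk) == 0L) {
    return(tibble::tibble(center = numeric(), left = numeric(),
                          right = numeric(), area = numeric(),
                          fraction = numeric()))
  }
  pk <- pk[order(pk$index), , drop = FALSE]
  n <- length(ys)
  bounds <- vapply(seq_len(nrow(pk)), function(k) {
    i <- pk$index[k]
    vlo <- if (k == 1L) 1L else {
      seg <- pk$index[k - 1L]:i
      seg[which.min(ys[seg])]
    }
    vhi <- if (k == nrow(pk)) n else {
      seg <- i:pk$index[k + 1L]
      seg[which.min(ys[seg])]
    }
    # band support: walk outward from the peak while the signal stays above
    # the noise floor, clipped at the valleys shared with neighbours
    lo <- i
    while (lo > vlo && ys[lo - 1L] > floor_lvl) lo <- lo - 1L
    hi <- i
    while (hi < vhi && ys[hi + 1L] > floor_lvl) hi <- hi + 1L
    c(max(1L, lo - 1L), min(n, hi + 1L))
  }, numeric(2))
  # flat pedestal at the median of the (band-sparse) profile: removes the
  # clamped-noise floor without touching band area in the clean case
  pedestal <- stats::median(ys)
  area <- vapply(seq_len(nrow(pk)), function(k) {
    idx <- bounds[1, k]:bounds[2, k]
    trapezoid(x[idx], pmax(y[idx] - pedestal, 0))
  }, numeric(1))
  total <- sum(area)
  tibble::tibble(center = x[pk$index],
                 left = x[bounds[1, ]], right = x[bounds[2, ]],
                 area = area,
                 fraction = if (total > 0) area / total * 100 else area)
}

#' Calibrate band sizes against a ladder
#'
#' Fits migration position against log10(fragment size) by least squares
#' over the ladder rungs (the classical semi-log gel calibration) and
#' assigns each band an estimated size from the fit.
#'
#' @param bands Band tibble from [detect_bands()].
#' @param ladder Data frame with columns `position` and `size_bp`; at least
#'   3 rungs; size must decrease strictly with migration distance.
#' @return `bands` with a `size_bp` column; the fitted model's R^2 and
#'   coefficients are attached as attribute `"calibration"`.
#' @export
calibrate_sizes <- function(bands, ladder) {
  ladder <- dplyr::arrange(tibble::as_tibble(ladder), .data$position)
  if (nrow(ladder) < 3L) {
    stop("ladder needs at least 3 rungs", call. = FALSE)
  }
  if (any(diff(ladder$size_bp) >= 0)) {
    stop("ladder sizes must strictly decrease with migration distance",
         call. = FALSE)
  }
  fit <- stats::lm(log10(size_bp) ~ position, data = ladder)
  out <- bands
  out$size_bp <- unname(10^stats::predict(
    fit, newdata = data.frame(position = bands$center)))
  ss_tot <- sum((log10(ladder$size_bp) - mean(log10(ladder$size_bp)))^2)
  attr(out, "calibration") <- list(
    r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot,
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]))
  out
}

#' Predict the RT-PCR fragment size of a splice product
#'
#' The amplified fragment spans both reporter flanks plus all exonic (and
#' aberrantly included intronic) sequence of the construct after applying
#' the splice events.
#'
#' @param construct A [minigene_construct()].
#' @param events Event tibble (zero rows = the wild-type product).
#' @param model A `transcript_model`.
#' @return Fragment size in bp.
#' @export
predict_fragment_size <- function(construct, events, model) {
  ex <- model$exons
  span <- construct$first_exon:construct$last_exon
  base <- construct$flank_5_len + construct$flank_3_len +
    sum(ex$c_end[ex$exon %in% span] - ex$c_start[ex$exon %in% span] + 1L)
  if (nrow(events) > 0L) {
    touched <- unlist(events$exons[events$kind == "exon_skip"])
    if (length(touched) && !all(touched %in% span)) {
      stop("event references exon(s) outside construct ", construct$name,
           call. = FALSE)
    }
    base <- base + delta_length(events, model)
  }
  as.integer(base)
}

#' Assign band identities by nearest predicted fragment size
#'
#' Bands are matched greedily in order of decreasing area: each takes the
#' unused candidate with the nearest predicted size, provided the gap is
#' within `tolerance_bp`; bands with no candidate in reach are flagged
#' `"unidentified"`.
#'
#' @param bands Calibrated band tibble (with `size_bp`).
#' @param candidates Data frame with columns `label` and `size_bp`.
#' @param tolerance_bp Maximum |observed - predicted| size gap (default 30).
#' @return `bands` with an `identity` column.
#' @export
match_transcripts <- function(bands, candidates, tolerance_bp = 30) {
  candidates <- tibble::as_tibble(candidates)
  stopifnot(nrow(candidates) > 0L,
            all(c("label", "size_bp") %in% names(candidates)))
  identity <- rep(NA_character_, nrow(bands))
  used <- rep(FALSE, nrow(candidates))
  for (k in order(bands$area, decreasing = TRUE)) {
    gaps <- abs(candidates$size_bp - bands$size_bp[k])
    gaps[used] <- Inf
    j <- which.min(gaps)
    if (length(j) == 1L && gaps[j] <= tolerance_bp) {
      identity[k] <- candidates$label[j]
      used[j] <- TRUE
    } else {
      identity[k] <- "unidentified"
    }
  }
  dplyr::mutate(bands, identity = identity)
}

#' Enumerate candidate splice products for a construct
#'
#' Builds the candidate table used for band identification: the wild-type
#' product, every single-exon skip, every adjacent double skip, the
#' construct's baseline species, and any extra event sets supplied.
#'
#' @param construct A [minigene_construct()].
#' @param model A `transcript_model`.
#' @param extra Optional named list of additional event tibbles.
#' @return A tibble: `label`, `size_bp`, `events` (list-column).
#' @export
candidate_transcripts <- function(construct, model, extra = list()) {
  span <- construct$first_exon:construct$last_exon
  cand <- list(WT = splice_events())
  for (e in span) cand[[paste0("skip_", e)]] <- exon_skip(e)
  if (length(span) > 1L) {
    for (i in seq_len(length(span) - 1L)) {
      cand[[paste0("skip_", span[i], "_", span[i + 1L])]] <-
        exon_skip(c(span[i], span[i + 1L]))
    }
  }
  for (b in construct$baseline) {
    lbl <- paste0("baseline_", rna_notation(b$events, model))
    if (!any(vapply(cand, identical, TRUE, y = b$events))) cand[[lbl]] <- b$events
  }
  for (nm in names(extra)) cand[[nm]] <- extra[[nm]]
  sizes <- vapply(cand, predict_fragment_size, integer(1),
                  construct = construct, model = model)
  out <- tibble::tibble(label = names(cand), size_bp = sizes,
                        events = unname(cand))
  dplyr::distinct(out, .data$size_bp, .keep_all = TRUE)
}

#' Quantify one lane end to end
#'
#' Convenience composition: background subtraction, band detection and
#' integration, ladder calibration, and identity assignment against the
#' construct's candidate products.
#'
#' @param profile A raw `lane_profile`.
#' @param ladder Ladder data frame (`position`, `size_bp`).
#' @param construct A [minigene_construct()].
#' @param model A `transcript_model`.
#' @param candidates Optional candidate table; defaults to
#'   [candidate_transcripts()].
#' @param window,min_prominence,tolerance_bp Tuning parameters passed
#'   through.
#' @return Calibrated, identity-assigned band tibble.
#' @export
quantify_lane <- function(profile, ladder, construct, model,
                          candidates = NULL, window = 201L,
                          min_prominence = 0.05, tolerance_bp = 30) {
  if (is.null(candidates)) {
    candidates <- candidate_transcripts(construct, model)
  }
  profile |>
    subtract_background(window = window) |>
    detect_bands(min_prominence = min_prominence) |>
    calibrate_sizes(ladder) |>
    match_transcripts(candidates, tolerance_bp = tolerance_bp)
}
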