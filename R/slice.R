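## Peak extraction from the pattern-wavelength channel and per-slice pose.

#' Construct a two-channel slice
#'
#' @param patternChannel,targetChannel numeric matrices (rows axial depth,
#'   columns lateral); must have identical dimensions.
#' @param pixelSpacing numeric length 2: lateral and axial pixel size (mm).
#' @param index acquisition-order index.
#' @return a [PASlice-class].
#' @export
paSlice <- function(patternChannel, targetChannel = patternChannel * 0,
                    pixelSpacing = c(lateral = 0.1, axial = 0.1),
                    index = 1L) {
  pixelSpacing <- stats::setNames(as.numeric(pixelSpacing),
                                  c("lateral", "axial"))
  new("PASlice", patternChannel = patternChannel,
      targetChannel = targetChannel, pixelSpacing = pixelSpacing,
      index = as.integer(index))
}

#' Collapse the pattern channel to a lateral intensity profile
#'
#' Reduces the 2D pattern channel to 1D by taking, for every lateral column,
#' the maximum intensity inside an axial depth band, together with the depth
#' at which that maximum occurs.  The pattern sits at the skin surface, so a
#' near-surface band can be used to exclude deep structures; the default is
#' the full image depth.
#'
#' @param slice a [PASlice-class].
#' @param depthBand numeric length 2, `c(min, max)` axial depth in mm, or
#'   `NULL` for the full depth.
#' @return list with `lateral` (mm positions of the columns), `profile`
#'   (per-column band maximum) and `depth` (mm depth of each column's
#'   maximum).
#' @export
depthProfile <- function(slice, depthBand = NULL) {
  stopifnot(is(slice, "PASlice"))
  img <- slice@patternChannel
  dy <- slice@pixelSpacing[["axial"]]
  dx <- slice@pixelSpacing[["lateral"]]
  rows <- seq_len(nrow(img))
  if (!is.null(depthBand)) {
    y <- (rows - 1) * dy
    rows <- rows[y >= depthBand[1] & y <= depthBand[2]]
    if (length(rows) == 0L)
      t3dError("depth band contains no image rows", "domainError")
  }
  band <- img[rows, , drop = FALSE]
  amax <- max.col(t(band), ties.method = "first")
  list(lateral = (seq_len(ncol(img)) - 1) * dx,
       profile = band[cbind(amax, seq_len(ncol(band)))],
       depth = (rows[amax] - 1) * dy)
}

## prominence of each local maximum: height minus the higher of the two
## valley floors separating it from higher terrain (array edges count as
## terrain ends), as in the standard 1D topographic definition.
peakProminence <- function(v, idx) {
  vapply(idx, function(i) {
    h <- v[i]
    lmin <- h
    j <- i
    while (j > 1L && v[j - 1L] <= h) { j <- j - 1L; lmin <- min(lmin, v[j]) }
    if (j == 1L && v[1L] <= h) lmin <- min(lmin, v[1L])
    left <- if (j == 1L) min(v[1:i]) else lmin
    rmin <- h
    j <- i
    n <- length(v)
    while (j < n && v[j + 1L] <= h) { j <- j + 1L; rmin <- min(rmin, v[j]) }
    right <- if (j == n) min(v[i:n]) else rmin
    h - max(left, right)
  }, numeric(1))
}

#' Detect candidate peaks in a 1D lateral profile
#'
#' Finds local maxima exceeding a prominence floor, enforces a minimum
#' lateral separation (keeping the more prominent peak), and refines each
#' position to sub-pixel accuracy by three-point parabolic interpolation.
#'
#' @param profile list as returned by [depthProfile()], or a numeric vector
#'   (in which case `spacing` gives the sample distance in mm).
#' @param minProminence absolute prominence threshold; default
#'   `0.2 * (max(profile) - median(profile))`.
#' @param minSeparation minimum distance between retained peaks (mm).
#' @param spacing sample spacing when `profile` is a bare vector (mm).
#' @return data.frame with columns `lateral` (mm, sub-pixel), `depth` (mm;
#'   `NA` for bare vectors), `prominence`, sorted by lateral position.
#' @export
detectPeaks <- function(profile, minProminence = NULL, minSeparation = 1.0,
                        spacing = 1.0) {
  if (is.numeric(profile))
    profile <- list(lateral = (seq_along(profile) - 1) * spacing,
                    profile = profile,
                    depth = rep(NA_real_, length(profile)))
  v <- profile$profile
  x <- profile$lateral
  n <- length(v)
  if (n < 3L) t3dError("profile must have at least 3 samples", "domainError")
  if (is.null(minProminence))
    minProminence <- 0.2 * (max(v) - stats::median(v))
  # plateau-aware local maxima: runs of equal values strictly above both
  # neighbours are peaks located at the plateau midpoint
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  isPeak <- vapply(seq_len(nr), function(k) {
    if (starts[k] == 1L || ends[k] == n) return(FALSE)
    r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L]
  }, logical(1))
  idx <- as.integer(floor((starts[isPeak] + ends[isPeak]) / 2))
  plateau <- r$lengths[isPeak] > 1L
  # continuous midpoint of the plateau (half-sample accurate for ties)
  plateauMid <- (x[starts[isPeak]] + x[ends[isPeak]]) / 2
  empty <- data.frame(lateral = numeric(), depth = numeric(),
                      prominence = numeric())
  if (length(idx) == 0L) return(empty)
  prom <- peakProminence(v, idx)
  keep <- prom >= minProminence & prom > 0
  idx <- idx[keep]; prom <- prom[keep]; plateau <- plateau[keep]
  plateauMid <- plateauMid[keep]
  if (length(idx) == 0L) return(empty)
  # greedy separation filter, most prominent first
  ord <- order(prom, decreasing = TRUE)
  sel <- integer()
  for (k in ord) {
    if (all(abs(x[idx[k]] - x[idx[sel]]) >= minSeparation)) sel <- c(sel, k)
  }
  idx <- idx[sel]; prom <- prom[sel]; plateau <- plateau[sel]
  plateauMid <- plateauMid[sel]
  # sub-pixel refinement by 3-point parabola; applied to log-intensity
  # when the neighbourhood is positive (exact for Gaussian peaks).
  # Plateaus keep their midpoint.
  lat <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    if (plateau[k]) return(plateauMid[k])
    if (i <= 1L || i >= n) return(x[i])
    tri <- v[(i - 1L):(i + 1L)]
    if (all(tri > 0)) tri <- log(tri)
    denom <- tri[1] - 2 * tri[2] + tri[3]
    off <- if (denom == 0) 0 else 0.5 * (tri[1] - tri[3]) / denom
    x[i] + max(-0.5, min(0.5, off)) * (x[2] - x[1])
  }, numeric(1))
  out <- data.frame(lateral = lat, depth = profile$depth[idx],
                    prominence = prom)
  out[order(out$lateral), , drop = FALSE]
}

#' Select the pattern peak triplet among candidates
#'
#' Enumerates all triplets among the top `K` candidates by prominence,
#' orders each by lateral position into (l, c, r), and keeps the triplets
#' whose decoded pose passes the physical gates: `a0` in
#' `(0, a0Max * (1 + margin)]`, `dl + dr <= dMax * (1 + margin)`, and
#' `|alpha| <= maxAlphaDeg` (a freehand sweep does not plausibly tilt the
#' probe beyond that).  Among admissible triplets the one with the
#' greatest total prominence wins.  Rejection is a value, not an error.
#'
#' @param candidates data.frame from [detectPeaks()].
#' @param pattern a [PatternSpec-class].
#' @param topK number of most prominent candidates to enumerate over.
#' @param maxAlphaDeg tilt-plausibility gate in degrees.
#' @return list with either `triplet` (3-row data.frame l, c, r), `dl`,
#'   `dr`, `pose` ([ProbePose-class]) and `rejection = NA`, or
#'   `rejection` one of `"too-few-peaks"`, `"no-valid-triplet"`,
#'   `"gate-failed"`.
#' @export
selectTriplet <- function(candidates, pattern, topK = 6L,
                          maxAlphaDeg = 45) {
  stopifnot(is(pattern, "PatternSpec"))
  if (nrow(candidates) < 3L)
    return(list(rejection = "too-few-peaks"))
  cand <- candidates[order(candidates$prominence, decreasing = TRUE), ]
  cand <- cand[seq_len(min(topK, nrow(cand))), ]
  combos <- utils::combn(nrow(cand), 3L)
  margin <- pattern@a0GateMargin
  best <- NULL
  bestProm <- -Inf
  anyPose <- FALSE
  for (j in seq_len(ncol(combos))) {
    tri <- cand[combos[, j], ]
    tri <- tri[order(tri$lateral), ]
    dvec <- function(a, b) {
      dy <- if (anyNA(tri$depth)) 0 else tri$depth[a] - tri$depth[b]
      sqrt((tri$lateral[a] - tri$lateral[b])^2 + dy^2)
    }
    dl <- dvec(1L, 2L)
    dr <- dvec(3L, 2L)
    if (dl + dr <= 0) next
    pose <- tryCatch(
      estimatePose(dl, dr, pattern, xc = tri$lateral[2L],
                   yc = if (is.na(tri$depth[2L])) 0 else tri$depth[2L]),
      gateError = function(e) { anyPose <<- TRUE; NULL },
      degenerateInputError = function(e) NULL)
    if (is.null(pose)) next
    if (dl + dr > pattern@dMax * (1 + margin)) { anyPose <- TRUE; next }
    if (abs(pose@alpha) > maxAlphaDeg * pi / 180) { anyPose <- TRUE; next }
    tot <- sum(tri$prominence)
    if (tot > bestProm) {
      bestProm <- tot
      best <- list(triplet = tri, dl = dl, dr = dr, pose = pose,
                   rejection = NA_character_)
    }
  }
  if (!is.null(best)) return(best)
  list(rejection = if (anyPose) "gate-failed" else "no-valid-triplet")
}

#' Estimate the pose of a single slice
#'
#' End-to-end per-slice pose decoding: [depthProfile()] →
#' [detectPeaks()] → [selectTriplet()] → [estimatePose()], with the central
#' peak supplying `(xc, yc)`.
#'
#' @param slice a [PASlice-class].
#' @param pattern a [PatternSpec-class].
#' @param depthBand optional axial band (mm) passed to [depthProfile()].
#' @param minProminence,minSeparation peak-detection parameters, see
#'   [detectPeaks()].
#' @param topK triplet enumeration breadth, see [selectTriplet()].
#' @return list with `accepted` (logical), `pose` ([ProbePose-class] or
#'   `NULL`), `triplet`, `dl`, `dr`, and `rejection` (reason string or `NA`).
#' @export
slicePose <- function(slice, pattern, depthBand = NULL,
                      minProminence = NULL, minSeparation = 1.0, topK = 6L,
                      maxAlphaDeg = 45) {
  prof <- depthProfile(slice, depthBand)
  if (all(prof$profile == prof$profile[1]))   # flat channel: nothing to find
    return(list(accepted = FALSE, pose = NULL, triplet = NULL,
                dl = NA_real_, dr = NA_real_, rejection = "too-few-peaks"))
  cands <- detectPeaks(prof, minProminence, minSeparation)
  sel <- selectTriplet(cands, pattern, topK, maxAlphaDeg)
  if (!is.na(sel$rejection))
    return(list(accepted = FALSE, pose = NULL, triplet = NULL,
                dl = NA_real_, dr = NA_real_, rejection = sel$rejection))
  list(accepted = TRUE, pose = sel$pose, triplet = sel$triplet,
       dl = sel$dl, dr = sel$dr, rejection = NA_character_)
}

#' Decode poses for a whole stack of slices
#'
#' @param slices list of [PASlice-class] objects.
#' @param pattern a [PatternSpec-class].
#' @param ... passed to [slicePose()].
#' @return data.frame with one row per slice: `index`, `accepted`,
#'   `alpha_deg`, `a0_mm`, `x_c_mm`, `y_c_mm`, `rejection_reason`.
#' @export
stackPoses <- function(slices, pattern, ...) {
  rows <- lapply(slices, function(s) {
    r <- slicePose(s, pattern, ...)
    if (r$accepted)
      data.frame(index = s@index, accepted = TRUE,
                 alpha_deg = r$pose@alpha * 180 / pi, a0_mm = r$pose@a0,
                 x_c_mm = r$pose@xc, y_c_mm = r$pose@yc,
                 rejection_reason = NA_character_)
    else
      data.frame(index = s@index, accepted = FALSE, alpha_deg = NA_real_,
                 a0_mm = NA_real_, x_c_mm = NA_real_, y_c_mm = NA_real_,
                 rejection_reason = r$rejection)
  })
  do.call(rbind, rows)
}
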