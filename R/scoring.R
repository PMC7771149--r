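#' Weights for the Tollrian neckteeth-induction score
#'
#' The classical induction index combines the ordinal pedestal class and the
#' neckteeth count into a single 0--100% score: a fixed percentage per
#' pedestal class plus a fixed percentage per tooth, capped. The canonical
#' weights (Tollrian 1993) are 0/30/50% for pedestal classes A/B/C plus 10%
#' per necktooth, capped at 100%; they are configuration, not constants.
#'
#' @param per_tooth_percent Percent contributed by each necktooth.
#' @param pedestal_percent Named numeric vector with entries `A`, `B`, `C`.
#' @param cap Maximum score, in percent.
#' @return An object of class `induction_weights`.
#' @export
induction_weights <- function(per_tooth_percent = 10,
                              pedestal_percent = c(A = 0, B = 30, C = 50),
                              cap = 100) {
  if (!all(c("A", "B", "C") %in% names(pedestal_percent))) {
    stop("pedestal_percent must have entries named A, B and C", call. = FALSE)
  }
  pedestal_percent <- pedestal_percent[c("A", "B", "C")]
  if (per_tooth_percent < 0 || any(pedestal_percent < 0) || cap < 0) {
    stop("induction-score weights must be non-negative", call. = FALSE)
  }
  if (cap < max(pedestal_percent) || cap < NECKTEETH_TRIALS * per_tooth_percent) {
    stop("cap must be at least the largest single component", call. = FALSE)
  }
  structure(list(per_tooth_percent = per_tooth_percent,
                 pedestal_percent = pedestal_percent, cap = cap),
            class = "induction_weights")
}

#' Tollrian neckteeth-induction score
#'
#' `score = min(cap, pedestal_percent[pedestal] + per_tooth_percent * neckteeth)`.
#' With the default weights the score lies in 0--100% and is monotone in both
#' trait components. The score is descriptive only; modelling treats the two
#' traits as a bivariate response instead, because the index is interval-
#' censored and frequently zero-inflated.
#'
#' @param neckteeth Integer counts in 0..5 (vectorized).
#' @param pedestal Pedestal classes, `"A"`/`"B"`/`"C"` (character or factor).
#' @param weights An [induction_weights] object.
#' @return Numeric vector of scores in percent.
#' @examples
#' tollrian_induction_score(3, "B")  # 60
#' @export
tollrian_induction_score <- function(neckteeth, pedestal,
                                     weights = induction_weights()) {
  if (!inherits(weights, "induction_weights")) {
    weights <- do.call(induction_weights, as.list(weights))
  }
  neckteeth <- as.integer(neckteeth)
  if (any(is.na(neckteeth)) || any(neckteeth < 0L) ||
      any(neckteeth > NECKTEETH_TRIALS)) {
    stop("neckteeth must be integers in 0..", NECKTEETH_TRIALS, call. = FALSE)
  }
  pedestal <- as.character(pedestal)
  if (any(!pedestal %in% PEDESTAL_LEVELS)) {
    stop("pedestal must be one of A, B, C", call. = FALSE)
  }
  raw <- weights$pedestal_percent[pedestal] +
    weights$per_tooth_percent * neckteeth
  unname(pmin(weights$cap, raw))
}

LANDMARK_NAMES <- c("head_top", "spina_base", "spina_tip", "ventral_mid",
                    "dorsal_mid")

#' A labelled set of morphometric landmarks
#'
#' Five 2-D landmarks, already calibrated to mm, digitized from a lateral
#' photograph: top of the head, base and tip of the tail spine (spina), and
#' the ventral and dorsal midpoints of the carapace.
#'
#' @param head_top,spina_base,spina_tip,ventral_mid,dorsal_mid Numeric
#'   length-2 vectors `c(x, y)` in mm.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(head_top, spina_base, spina_tip, ventral_mid,
                         dorsal_mid) {
  pts <- list(head_top = head_top, spina_base = spina_base,
              spina_tip = spina_tip, ventral_mid = ventral_mid,
              dorsal_mid = dorsal_mid)
  for (nm in LANDMARK_NAMES) {
    p <- pts[[nm]]
    if (is.null(p) || length(p) != 2 || !all(is.finite(p))) {
      stop("landmark '", nm, "' must be a finite (x, y) pair", call. = FALSE)
    }
    pts[[nm]] <- as.numeric(p)
  }
  structure(pts, class = "landmark_set")
}

#' Body measurements from a landmark set
#'
#' Body length is the distance from the top of the head to the base of the
#' tail spine; body width the distance between the ventral and dorsal
#' midpoints; spina length the distance from the base to the tip of the tail
#' spine. All three are plain Euclidean distances, hence invariant under
#' translation and rotation of the digitized image.
#'
#' @param landmarks A [landmark_set].
#' @return Named numeric vector `c(body_length_mm, body_width_mm,
#'   spina_length_mm)`.
#' @export
landmark_lengths <- function(landmarks) {
  if (!inherits(landmarks, "landmark_set")) {
    landmarks <- do.call(landmark_set, as.list(landmarks))
  }
  dist2 <- function(a, b) sqrt(sum((a - b)^2))
  c(body_length_mm = dist2(landmarks$head_top, landmarks$spina_base),
    body_width_mm = dist2(landmarks$ventral_mid, landmarks$dorsal_mid),
    spina_length_mm = dist2(landmarks$spina_base, landmarks$spina_tip))
}

#' Read a landmark table and compute measurements
#'
#' The CSV has one row per juvenile with two columns per landmark,
#' `<name>_x` and `<name>_y` (e.g. `head_top_x,head_top_y,...`), plus any
#' identifier columns, which are carried through.
#'
#' @param path Path to a landmarks CSV file.
#' @return The input table with `body_length_mm`, `body_width_mm` and
#'   `spina_length_mm` columns appended.
#' @export
read_landmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- as.vector(t(outer(LANDMARK_NAMES, c("_x", "_y"), paste0)))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("landmark table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  lengths <- t(apply(df[, needed], 1, function(r) {
    lm <- landmark_set(head_top = r[c("head_top_x", "head_top_y")],
                       spina_base = r[c("spina_base_x", "spina_base_y")],
                       spina_tip = r[c("spina_tip_x", "spina_tip_y")],
                       ventral_mid = r[c("ventral_mid_x", "ventral_mid_y")],
                       dorsal_mid = r[c("dorsal_mid_x", "dorsal_mid_y")])
    landmark_lengths(lm)
  }))
  cbind(df, as.data.frame(lengths))
}
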