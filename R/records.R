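PEDESTAL_LEVELS <- c("A", "B", "C")
NECKTEETH_TRIALS <- 5L

JUVENILE_COLUMNS <- c(
  "clone", "kairomone", "uvr", "instar", "mother_uid", "neckteeth", "pedestal",
  "body_length_mm", "body_width_mm", "spina_length_mm", "survived_to_instar2"
)

EFFECTIVITY_COLUMNS <- c(
  "treatment", "exposure_hours", "mother_uid", "neckteeth", "pedestal"
)

EXPOSURE_HOURS <- c(2L, 4L, 6L, 8L)
EFFECTIVITY_TREATMENTS <- c("control", "PAR", "UVR")

#' Construct a unique mother identifier
#'
#' Mothers are numbered consecutively within each clone-by-treatment cell, so a
#' globally unique identifier must encode the clone, both treatment flags and
#' the within-cell index. The format is `"CLONE.K{0/1}.U{0/1}.{index}"`, e.g.
#' `"UNI.K1.U0.3"` for the third mother of clone UNI under kairomone without
#' UVR. Any injective scheme would do; this one is fixed for reproducibility.
#'
#' @param clone Clone label (e.g. `"UNI"`, `"P5"`).
#' @param kairomone Logical; kairomone exposure.
#' @param uvr Logical; UVR exposure.
#' @param mother_index Integer >= 1, the within-cell mother number.
#' @return Character vector of identifiers.
#' @examples
#' make_mother_uid("UNI", TRUE, FALSE, 3)
#' @export
make_mother_uid <- function(clone, kairomone, uvr, mother_index) {
  mother_index <- as.integer(mother_index)
  if (any(is.na(mother_index)) || any(mother_index < 1L)) {
    stop("mother_index must be an integer >= 1", call. = FALSE)
  }
  sprintf("%s.K%d.U%d.%d", as.character(clone),
          as.integer(as.logical(kairomone)), as.integer(as.logical(uvr)),
          mother_index)
}

#' Unique mother identifier for the kairomone-effectivity trial
#'
#' Mothers in the effectivity trial are nested in treatment-by-duration cells
#' rather than clone-by-treatment cells; the identifier encodes both.
#'
#' @param treatment One of `"control"`, `"PAR"`, `"UVR"`.
#' @param exposure_hours Exposure duration of the kairomone suspension (2/4/6/8).
#' @param mother_index Integer >= 1.
#' @return Character vector of identifiers.
#' @export
make_effectivity_mother_uid <- function(treatment, exposure_hours, mother_index) {
  mother_index <- as.integer(mother_index)
  if (any(is.na(mother_index)) || any(mother_index < 1L)) {
    stop("mother_index must be an integer >= 1", call. = FALSE)
  }
  sprintf("%s.T%d.%d", as.character(treatment), as.integer(exposure_hours),
          mother_index)
}

#' Validate a table of juvenile trait records
#'
#' Checks the invariants of the per-juvenile record: neckteeth counts in
#' 0..5, pedestal class in A/B/C, positive (or missing) lengths, instar in
#' {1, 2}, and that instar-2 rows only occur for juveniles flagged as having
#' survived to instar 2. Errors name the first offending row.
#'
#' @param df A data frame with the `juveniles.csv` columns.
#' @return The validated data frame (invisibly the same object), with
#'   `pedestal` as an ordered factor A < B < C and flags as logicals.
#' @export
validate_juvenile_table <- function(df) {
  missing_cols <- setdiff(JUVENILE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("juvenile table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, JUVENILE_COLUMNS]
  df$clone <- as.character(df$clone)
  df$mother_uid <- as.character(df$mother_uid)
  df$kairomone <- as_flag(df$kairomone, "kairomone")
  df$uvr <- as_flag(df$uvr, "uvr")
  df$survived_to_instar2 <- as_flag(df$survived_to_instar2, "survived_to_instar2")
  df$instar <- as.integer(df$instar)
  df$neckteeth <- as.integer(df$neckteeth)

  bad <- which(!df$instar %in% c(1L, 2L))
  if (length(bad)) stop("invalid instar (must be 1 or 2) on row ", bad[1], call. = FALSE)
  bad <- which(is.na(df$neckteeth) | df$neckteeth < 0L | df$neckteeth > NECKTEETH_TRIALS)
  if (length(bad)) stop("neckteeth outside 0-5 on row ", bad[1], call. = FALSE)
  bad <- which(!as.character(df$pedestal) %in% PEDESTAL_LEVELS)
  if (length(bad)) stop("pedestal value outside {A,B,C} on row ", bad[1], call. = FALSE)
  df$pedestal <- factor(as.character(df$pedestal), levels = PEDESTAL_LEVELS,
                        ordered = TRUE)
  for (col in c("body_length_mm", "body_width_mm", "spina_length_mm")) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    # spina length zero is legal only as a degenerate measured value
    if (col == "spina_length_mm") bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) stop(col, " must be positive on row ", bad[1], call. = FALSE)
  }
  bad <- which(df$instar == 2L & !df$survived_to_instar2)
  if (length(bad)) {
    stop("instar-2 record without survived_to_instar2 on row ", bad[1], call. = FALSE)
  }
  df
}

as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1))) stop(name, " must be 0/1 or logical", call. = FALSE)
    return(x == 1)
  }
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "T", "YES")] <- TRUE
  out[x %in% c("0", "FALSE", "F", "NO")] <- FALSE
  if (any(is.na(out))) stop(name, " must be 0/1 or logical", call. = FALSE)
  out
}

#' Read / write the tidy per-juvenile trait table
#'
#' `juveniles.csv` has one row per juvenile per instar with the header
#' `clone,kairomone,uvr,instar,mother_uid,neckteeth,pedestal,body_length_mm,
#' body_width_mm,spina_length_mm,survived_to_instar2`. Logical flags are
#' stored as 0/1 and missing morphometric measurements as empty cells
#' (measurements can be lost to image-file corruption; they are preserved as
#' missing, never coerced to zero).
#'
#' @param path Path to a CSV file.
#' @return `read_juvenile_table` returns a validated data frame;
#'   `write_juvenile_table` invisibly returns `path`.
#' @export
read_juvenile_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pedestal = "character"))
  validate_juvenile_table(df)
}

#' @rdname read_juvenile_table
#' @param df A data frame of juvenile records (validated before writing).
#' @export
write_juvenile_table <- function(df, path) {
  df <- validate_juvenile_table(df)
  out <- df
  out$kairomone <- as.integer(out$kairomone)
  out$uvr <- as.integer(out$uvr)
  out$survived_to_instar2 <- as.integer(out$survived_to_instar2)
  out$pedestal <- as.character(out$pedestal)
  # lengths serialized at full double precision so a write/read round trip
  # reproduces the numbers bit-exactly
  for (col in c("body_length_mm", "body_width_mm", "spina_length_mm")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.17g", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a table of kairomone-effectivity records
#'
#' One row per juvenile of the effectivity trial: a 3-level treatment
#' (`control`, `PAR`, `UVR`, labelling what the kairomone suspension was
#' exposed to), the suspension exposure duration in hours (2/4/6/8), the
#' mother identifier and the two scored defense traits.
#'
#' @param df Data frame with the `effectivity.csv` columns.
#' @return The validated data frame with `pedestal` as ordered factor and
#'   `treatment` as factor with `control` as reference level.
#' @export
validate_effectivity_table <- function(df) {
  missing_cols <- setdiff(EFFECTIVITY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("effectivity table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, EFFECTIVITY_COLUMNS]
  df$mother_uid <- as.character(df$mother_uid)
  bad <- which(!as.character(df$treatment) %in% EFFECTIVITY_TREATMENTS)
  if (length(bad)) stop("unknown treatment on row ", bad[1], call. = FALSE)
  df$treatment <- factor(as.character(df$treatment), levels = EFFECTIVITY_TREATMENTS)
  df$exposure_hours <- as.integer(df$exposure_hours)
  bad <- which(!df$exposure_hours %in% EXPOSURE_HOURS)
  if (length(bad)) stop("exposure_hours must be one of 2/4/6/8 on row ", bad[1],
                        call. = FALSE)
  df$neckteeth <- as.integer(df$neckteeth)
  bad <- which(is.na(df$neckteeth) | df$neckteeth < 0L | df$neckteeth > NECKTEETH_TRIALS)
  if (length(bad)) stop("neckteeth outside 0-5 on row ", bad[1], call. = FALSE)
  bad <- which(!as.character(df$pedestal) %in% PEDESTAL_LEVELS)
  if (length(bad)) stop("pedestal value outside {A,B,C} on row ", bad[1], call. = FALSE)
  df$pedestal <- factor(as.character(df$pedestal), levels = PEDESTAL_LEVELS,
                        ordered = TRUE)
  df
}

#' @rdname validate_effectivity_table
#' @param path Path to a CSV file.
#' @export
read_effectivity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pedestal = "character"))
  validate_effectivity_table(df)
}

#' @rdname validate_effectivity_table
#' @export
write_effectivity_table <- function(df, path) {
  df <- validate_effectivity_table(df)
  out <- df
  out$treatment <- as.character(out$treatment)
  out$pedestal <- as.character(out$pedestal)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
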