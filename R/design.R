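#' Specification of a fixed-effect design
#'
#' Factors are given as a named list of level vectors; the first level of
#' each factor is the reference level (indicator/treatment coding). When a
#' factor's levels are not supplied explicitly they default to the sorted
#' unique values found in the data, so the alphabetically first level is the
#' reference. `max_interaction_order` bounds the interaction depth: the
#' model-reduction workflow drops the highest-order interaction whenever the
#' full model is unidentifiable (split-Rhat > 1.05), so the final
#' morphometric model uses order 3 of 4 factors and the final defense models
#' order 2 of 3.
#'
#' @param factors Named list; each element a character vector of levels,
#'   reference level first. Logical data columns map to levels `c("0", "1")`.
#' @param max_interaction_order Integer >= 1, at most the number of factors.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(factors, max_interaction_order = length(factors)) {
  if (!is.list(factors) || is.null(names(factors)) ||
      any(!nzchar(names(factors)))) {
    stop("factors must be a named list of level vectors", call. = FALSE)
  }
  max_interaction_order <- as.integer(max_interaction_order)
  if (max_interaction_order < 1L || max_interaction_order > length(factors)) {
    stop("max_interaction_order must be in 1..number of factors", call. = FALSE)
  }
  factors <- lapply(factors, as.character)
  structure(list(factors = factors,
                 max_interaction_order = max_interaction_order),
            class = "design_spec")
}

#' Default design for the per-instar defense models
#'
#' Clone, kairomone and UVR main effects plus all two-way interactions; the
#' three-way interaction is excluded (the full model is unidentifiable at
#' this design size).
#' @export
defense_design_spec <- function() {
  design_spec(list(clone = c("P5", "UNI"), kairomone = c("0", "1"),
                   uvr = c("0", "1")), max_interaction_order = 2L)
}

#' Default design for the morphometric model
#'
#' Clone, instar, kairomone and UVR up to three-way interactions; the
#' four-way interaction is excluded.
#' @export
morpho_design_spec <- function() {
  design_spec(list(clone = c("P5", "UNI"), instar = c("1", "2"),
                   kairomone = c("0", "1"), uvr = c("0", "1")),
              max_interaction_order = 3L)
}

#' Default design for the pooled kairomone-effectivity model
#'
#' A single 3-level treatment factor with `control` as reference; exposure
#' duration is deliberately not a predictor (all time points are pooled).
#' @export
effectivity_design_spec <- function() {
  design_spec(list(treatment = c("control", "PAR", "UVR")),
              max_interaction_order = 1L)
}

design_column_value <- function(x) {
  if (is.logical(x)) as.character(as.integer(x)) else as.character(x)
}

#' Build a fixed-effects design matrix
#'
#' Intercept plus indicator-coded main effects plus all interaction products
#' up to `max_interaction_order`, in the deterministic order produced by
#' `model.matrix` on `~ (f1 + f2 + ...)^k`: intercept, main effects in the
#' order the factors were declared, then interactions by ascending order.
#' Column names concatenate factor name and non-reference level (e.g.
#' `cloneUNI`, `kairomone1`, `cloneUNI:uvr1`).
#'
#' @param records Data frame containing one column per declared factor.
#'   Logical columns are coded as levels `"0"`/`"1"`.
#' @param spec A [design_spec].
#' @return Numeric matrix with one row per record and named columns.
#' @export
build_design_matrix <- function(records, spec) {
  stopifnot(inherits(spec, "design_spec"))
  fnames <- names(spec$factors)
  missing_cols <- setdiff(fnames, names(records))
  if (length(missing_cols) > 0) {
    stop("records lack factor column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  fd <- list()
  for (nm in fnames) {
    vals <- design_column_value(records[[nm]])
    unknown <- setdiff(unique(vals), spec$factors[[nm]])
    if (length(unknown) > 0) {
      stop("unknown level '", unknown[1], "' for factor '", nm, "'",
           call. = FALSE)
    }
    fd[[nm]] <- factor(vals, levels = spec$factors[[nm]])
  }
  fd <- as.data.frame(fd, optional = TRUE)
  rhs <- paste(fnames, collapse = " + ")
  if (spec$max_interaction_order > 1L) {
    rhs <- paste0("(", rhs, ")^", spec$max_interaction_order)
  }
  form <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(form, data = fd)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}
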