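#' Fixed clinical normalization bounds
#'
#' Per-channel affine maps to \[0, 1\] used for all model inputs. Bounds are
#' fixed clinical ranges rather than data minima/maxima so the map is stable
#' across cross-validation folds and cannot leak validation statistics into
#' training: sensitivities -1 to 40 dB, RNFL thickness 0 to 250 um, age 0 to
#' 110 years. Out-of-range values clip after normalization.
#'
#' @param dls,rnfl,age Numeric length-2 `c(min, max)` per channel.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(dls = c(-1, 40), rnfl = c(0, 250),
                               age = c(0, 110)) {
  for (ch in list(dls, rnfl, age)) {
    stopifnot(length(ch) == 2, all(is.finite(ch)))
    if (ch[2] <= ch[1]) stop("degenerate-channel: max must exceed min")
  }
  structure(list(dls = as.numeric(dls), rnfl = as.numeric(rnfl),
                 age = as.numeric(age)),
            class = "normalization_spec")
}

#' Assemble the model input vector from one paired visit
#'
#' Concatenation order is fixed and stable: the 52 sensitivities in grid
#' order, then the 256 RNFL samples in angular order, then age. With both
#' optional blocks the input dimension is 309; dropping age gives 308,
#' dropping the RNFL block gives 53, dropping both leaves the bare 52-point
#' field.
#'
#' @param visit A [paired_visit()] object.
#' @param include_rnfl,include_age Input-ablation flags.
#' @return Numeric vector with attribute `layout` describing the blocks.
#' @export
assemble_fusion_vector <- function(visit, include_rnfl = TRUE,
                                   include_age = TRUE) {
  stopifnot(inherits(visit, "paired_visit"))
  x <- visit$vf$dls
  layout <- c(dls = 52L)
  if (include_rnfl) {
    x <- c(x, visit$oct$rnfl_profile)
    layout <- c(layout, rnfl = 256L)
  }
  if (include_age) {
    x <- c(x, visit$age)
    layout <- c(layout, age = 1L)
  }
  attr(x, "layout") <- layout
  x
}

#' @rdname assemble_fusion_vector
#' @param x A vector produced by `assemble_fusion_vector()`.
#' @return `disassemble_fusion_vector`: a list with `dls` and, when present,
#'   `rnfl` and `age`.
#' @export
disassemble_fusion_vector <- function(x) {
  layout <- attr(x, "layout")
  stopifnot(!is.null(layout), sum(layout) == length(x))
  out <- list()
  pos <- 0L
  for (nm in names(layout)) {
    out[[nm]] <- as.numeric(x[pos + seq_len(layout[[nm]])])
    pos <- pos + layout[[nm]]
  }
  out
}

# layout for a cohort-level design matrix under the ablation flags
fusion_layout <- function(include_rnfl = TRUE, include_age = TRUE) {
  layout <- c(dls = 52L)
  if (include_rnfl) layout <- c(layout, rnfl = 256L)
  if (include_age) layout <- c(layout, age = 1L)
  layout
}

# per-column channel bounds for a layout
layout_bounds <- function(layout, spec) {
  lo <- numeric(0); hi <- numeric(0)
  for (nm in names(layout)) {
    ch <- spec[[nm]]
    lo <- c(lo, rep(ch[1], layout[[nm]]))
    hi <- c(hi, rep(ch[2], layout[[nm]]))
  }
  list(lo = lo, hi = hi)
}

#' Normalize / denormalize fusion vectors
#'
#' Maps each channel by `(x - min) / (max - min)` with the channel bounds of
#' a [normalization_spec()]; values outside the bounds clip to \[0, 1\].
#' `denormalize_fusion` is the exact inverse for in-range values.
#'
#' @param x Numeric vector or matrix (rows = samples) whose columns follow
#'   `layout`.
#' @param spec A [normalization_spec()].
#' @param layout Named integer block layout, e.g. from a fusion vector's
#'   `layout` attribute or [assemble_fusion_vector()] defaults.
#' @param clip Clip out-of-range values after normalization (default TRUE).
#' @return Same shape as `x`.
#' @export
normalize_fusion <- function(x, spec, layout = attr(x, "layout"), clip = TRUE) {
  b <- check_layout(x, layout, spec)
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, b$lo, "-"), 2, b$hi - b$lo, "/")
  } else {
    out <- (as.numeric(x) - b$lo) / (b$hi - b$lo)
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  restore_layout(out, x, layout)
}

#' @rdname normalize_fusion
#' @export
denormalize_fusion <- function(x, spec, layout = attr(x, "layout")) {
  b <- check_layout(x, layout, spec)
  if (is.matrix(x)) {
    out <- sweep(sweep(x, 2, b$hi - b$lo, "*"), 2, b$lo, "+")
  } else {
    out <- as.numeric(x) * (b$hi - b$lo) + b$lo
  }
  restore_layout(out, x, layout)
}

check_layout <- function(x, layout, spec) {
  stopifnot(inherits(spec, "normalization_spec"), !is.null(layout))
  d <- if (is.matrix(x)) ncol(x) else length(x)
  if (sum(layout) != d) stop("layout does not cover the vector channels")
  layout_bounds(layout, spec)
}

restore_layout <- function(out, x, layout) {
  if (!is.matrix(out)) attr(out, "layout") <- layout
  out
}

#' Design matrix of normalized fusion vectors for a cohort
#'
#' @param cohort Cohort data.frame.
#' @param spec A [normalization_spec()].
#' @param include_rnfl,include_age Input-ablation flags.
#' @return List with `x` (n x d matrix, normalized), `v` (n x 52 matrix, the
#'   normalized measured fields), `layout`, and the row-aligned `eye_id`.
#' @export
cohort_design <- function(cohort, spec = normalization_spec(),
                          include_rnfl = TRUE, include_age = TRUE) {
  layout <- fusion_layout(include_rnfl, include_age)
  x <- as.matrix(cohort[dls_cols()])
  if (include_rnfl) x <- cbind(x, as.matrix(cohort[rnfl_cols()]))
  if (include_age) x <- cbind(x, cohort$age)
  colnames(x) <- NULL
  xn <- normalize_fusion(x, spec, layout)
  list(x = xn, v = xn[, 1:52, drop = FALSE], layout = layout,
       eye_id = as.character(cohort$eye_id))
}
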