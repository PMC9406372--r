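#' Bethesda system class labels
#'
#' The four diagnostic categories used throughout the package, in severity
#' order: NILM (negative for intraepithelial malignancy), LSIL (low-grade
#' squamous intraepithelial lesion), HSIL (high-grade lesion) and SCC
#' (squamous cell carcinoma).
#'
#' @return Character vector of the four class labels in severity order.
#' @export
bethesda_classes <- function() c("NILM", "LSIL", "HSIL", "SCC")

#' Coerce labels to a Bethesda factor
#'
#' @param x character, factor or integer (0-based or 1-based index) labels.
#' @return factor with levels `bethesda_classes()` in severity order.
#' @export
bethesda_factor <- function(x) {
  lv <- bethesda_classes()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (all(x %in% 0:3)) x <- lv[x + 1L]
    else if (all(x %in% 1:4)) x <- lv[x]
    else stop("integer labels must index the four Bethesda classes")
  }
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0) {
    stop(sprintf("unknown Bethesda label(s): %s", paste(bad, collapse = ", ")))
  }
  factor(x, levels = lv)
}

#' Collapse Bethesda labels to the binary screening scheme
#'
#' Groups NILM and LSIL as "negative" and HSIL and SCC as "positive", the
#' standard low-grade/high-grade dichotomy used when assessing binary
#' cross-preparation performance.
#'
#' @param labels labels coercible via [bethesda_factor()].
#' @return factor with levels `c("negative", "positive")`.
#' @export
binarize_labels <- function(labels) {
  if (length(labels) == 0) {
    return(factor(character(0), levels = c("negative", "positive")))
  }
  f <- bethesda_factor(labels)
  factor(ifelse(as.integer(f) <= 2L, "negative", "positive"),
         levels = c("negative", "positive"))
}
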