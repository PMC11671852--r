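# UN-LCCS (CCI-LC style) class codes -> aggregated vegetation categories.
# BL broad-leaved, NL needle-leaved, MF mixed forest, Shb shrubland,
# TW transitional woodland, Gs grassland, Cp cropland, Oth other surfaces.

landcover_category_levels <- function() {
  c("BL", "NL", "MF", "Shb", "TW", "Gs", "Cp", "Oth")
}

lcc_code_table <- function() {
  rbind(
    data.frame(code = c(50L, 60L),        category = "BL"),
    data.frame(code = c(70L, 80L),        category = "NL"),
    data.frame(code = 90L,                category = "MF"),
    data.frame(code = c(40L, 110L, 120L), category = "Shb"),
    data.frame(code = 100L,               category = "TW"),
    data.frame(code = 130L,               category = "Gs"),
    data.frame(code = c(10L, 20L, 30L),   category = "Cp"),
    data.frame(code = seq(150L, 220L, by = 10L), category = "Oth")
  )
}

#' Aggregate 37-class land-cover codes into vegetation categories
#'
#' Maps UN-LCCS class codes to the eight aggregated categories used throughout
#' the analysis: broad-leaved forest `BL` (codes 50, 60), needle-leaved forest
#' `NL` (70, 80), mixed forest `MF` (90), shrubland `Shb` (40, 110, 120),
#' transitional woodland `TW` (100), grassland `Gs` (130), cropland `Cp`
#' (10, 20, 30) and `Oth` for the non-vegetated codes 150-220.
#'
#' @param codes integer vector or matrix of land-cover class codes.
#' @return a factor (same shape as `codes` when a matrix, via attribute
#'   preservation in `dim`) with levels `BL, NL, MF, Shb, TW, Gs, Cp, Oth`.
#' @export
aggregate_landcover <- function(codes) {
  tab <- lcc_code_table()
  idx <- match(as.integer(codes), tab$code)
  # codes 150-220 include intermediate values in some products; accept any
  # code in that range
  oth <- is.na(idx) & !is.na(codes) & codes >= 150 & codes <= 220
  bad <- is.na(idx) & !oth & !is.na(codes)
  if (any(bad)) {
    stop("unmapped land-cover code(s): ",
         paste(sort(unique(as.integer(codes)[bad])), collapse = ", "))
  }
  out <- tab$category[idx]
  out[oth] <- "Oth"
  f <- factor(out, levels = landcover_category_levels())
  dim(f) <- dim(codes)
  f
}
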