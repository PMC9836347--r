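#' Vegetation-index registry
#'
#' Registry of vegetation-index (VI) formulas over reflectance bands
#' \code{R, G, B, RE, NIR} (floating point, scale 0--1). Each entry records the
#' bands it requires, the formula as a function of those bands, and the
#' mathematically attainable output range for band values in \[0, 1\] (used by
#' property tests; \code{Inf} bounds mark ratio indices that are unbounded).
#'
#' RGB-only entries include the chromatic coordinates (RCC, GCC, BCC),
#' normalized differences (NGRDI, NGBDI, MGRVI, GLI, VARI, RGBVI), the excess
#' colour family on chromatic coordinates (ExG, ExR, ExB, ExGR, CIVE, MExG)
#' and ratio/triangular indices (VEG, GRRI, RGRI, BGI, TGI, WI). Entries using
#' red-edge/near-infrared include NDVI, GNDVI, NDRE, the soil-adjusted family
#' (SAVI, OSAVI, MSAVI), nonlinear indices (NLI, MNLI), EVI2, RDVI, simple and
#' modified ratios (SR, MSR, SRRE, CIG, CIRE), differences (DVI, GDVI),
#' WDRVI, IPVI and TVI.
#'
#' @param platform one of \code{"all"}, \code{"rgb"} (indices computable from
#'   R,G,B alone) or \code{"multi"} (indices requiring RE and/or NIR).
#' @return a named list of entries, each with elements \code{bands},
#'   \code{fn} and \code{range}; class \code{"vi_registry"}.
#' @examples
#' names(vi_registry("rgb"))
#' @export
vi_registry <- function(platform = c("all", "rgb", "multi")) {
  platform <- match.arg(platform)
  reg <- .vi_registry_all()
  if (platform == "rgb") {
    reg <- reg[vapply(reg, function(e) all(e$bands %in% c("R", "G", "B")), logical(1))]
  } else if (platform == "multi") {
    reg <- reg[vapply(reg, function(e) any(e$bands %in% c("RE", "NIR")), logical(1))]
  }
  structure(reg, class = "vi_registry")
}

# chromatic coordinates; division by zero handled by caller's NA masking
.chrom <- function(b) {
  s <- b$R + b$G + b$B
  list(r = b$R / s, g = b$G / s, b = b$B / s)
}

.vi_registry_all <- function() {
  e <- function(bands, fn, range) list(bands = bands, fn = fn, range = range)
  rgb <- c("R", "G", "B")
  list(
    # ---- RGB-only -------------------------------------------------------
    RCC   = e(rgb, function(b) b$R / (b$R + b$G + b$B), c(0, 1)),
    GCC   = e(rgb, function(b) b$G / (b$R + b$G + b$B), c(0, 1)),
    BCC   = e(rgb, function(b) b$B / (b$R + b$G + b$B), c(0, 1)),
    NGRDI = e(c("R", "G"), function(b) (b$G - b$R) / (b$G + b$R), c(-1, 1)),
    NGBDI = e(c("G", "B"), function(b) (b$G - b$B) / (b$G + b$B), c(-1, 1)),
    IKAW  = e(c("R", "B"), function(b) (b$R - b$B) / (b$R + b$B), c(-1, 1)),
    MGRVI = e(c("R", "G"), function(b) (b$G^2 - b$R^2) / (b$G^2 + b$R^2), c(-1, 1)),
    GLI   = e(rgb, function(b) (2 * b$G - b$R - b$B) / (2 * b$G + b$R + b$B), c(-1, 1)),
    VARI  = e(rgb, function(b) (b$G - b$R) / (b$G + b$R - b$B), c(-Inf, Inf)),
    ExG   = e(rgb, function(b) { cc <- .chrom(b); 2 * cc$g - cc$r - cc$b }, c(-1, 2)),
    ExR   = e(rgb, function(b) { cc <- .chrom(b); 1.4 * cc$r - cc$g }, c(-1, 1.4)),
    ExB   = e(rgb, function(b) { cc <- .chrom(b); 1.4 * cc$b - cc$g }, c(-1, 1.4)),
    ExGR  = e(rgb, function(b) { cc <- .chrom(b); (2 * cc$g - cc$r - cc$b) - (1.4 * cc$r - cc$g) }, c(-2.4, 3)),
    CIVE  = e(rgb, function(b) { cc <- .chrom(b); 0.441 * cc$r - 0.811 * cc$g + 0.385 * cc$b + 18.78745 }, c(17.97645, 19.22845)),
    MExG  = e(rgb, function(b) 1.262 * b$G - 0.884 * b$R - 0.311 * b$B, c(-1.195, 1.262)),
    RGBVI = e(rgb, function(b) (b$G^2 - b$R * b$B) / (b$G^2 + b$R * b$B), c(-1, 1)),
    TGI   = e(rgb, function(b) b$G - 0.39 * b$R - 0.61 * b$B, c(-1, 1)),
    VEG   = e(rgb, function(b) b$G / (b$R^0.667 * b$B^0.333), c(0, Inf)),
    GRRI  = e(c("R", "G"), function(b) b$G / b$R, c(0, Inf)),
    RGRI  = e(c("R", "G"), function(b) b$R / b$G, c(0, Inf)),
    BGI   = e(c("G", "B"), function(b) b$B / b$G, c(0, Inf)),
    WI    = e(rgb, function(b) (b$G - b$B) / (b$R - b$G), c(-Inf, Inf)),
    # ---- red-edge / NIR -------------------------------------------------
    NDVI  = e(c("R", "NIR"), function(b) (b$NIR - b$R) / (b$NIR + b$R), c(-1, 1)),
    GNDVI = e(c("G", "NIR"), function(b) (b$NIR - b$G) / (b$NIR + b$G), c(-1, 1)),
    NDRE  = e(c("RE", "NIR"), function(b) (b$NIR - b$RE) / (b$NIR + b$RE), c(-1, 1)),
    SAVI  = e(c("R", "NIR"), function(b) 1.5 * (b$NIR - b$R) / (b$NIR + b$R + 0.5), c(-3, 3)),
    OSAVI = e(c("R", "NIR"), function(b) 1.16 * (b$NIR - b$R) / (b$NIR + b$R + 0.16), c(-7.25, 7.25)),
    NLI   = e(c("R", "NIR"), function(b) (b$NIR^2 - b$R) / (b$NIR^2 + b$R), c(-1, 1)),
    MNLI  = e(c("R", "NIR"), function(b) 1.5 * (b$NIR^2 - b$R) / (b$NIR^2 + b$R + 0.5), c(-3, 3)),
    EVI2  = e(c("R", "NIR"), function(b) 2.5 * (b$NIR - b$R) / (b$NIR + 2.4 * b$R + 1), c(-2.5, 2.5)),
    MSAVI = e(c("R", "NIR"), function(b) (2 * b$NIR + 1 - sqrt((2 * b$NIR + 1)^2 - 8 * (b$NIR - b$R))) / 2, c(-1, 1)),
    RDVI  = e(c("R", "NIR"), function(b) (b$NIR - b$R) / sqrt(b$NIR + b$R), c(-1, 1)),
    SR    = e(c("R", "NIR"), function(b) b$NIR / b$R, c(0, Inf)),
    MSR   = e(c("R", "NIR"), function(b) (b$NIR / b$R - 1) / sqrt(b$NIR / b$R + 1), c(-1, Inf)),
    CIG   = e(c("G", "NIR"), function(b) b$NIR / b$G - 1, c(-1, Inf)),
    CIRE  = e(c("RE", "NIR"), function(b) b$NIR / b$RE - 1, c(-1, Inf)),
    SRRE  = e(c("RE", "NIR"), function(b) b$NIR / b$RE, c(0, Inf)),
    DVI   = e(c("R", "NIR"), function(b) b$NIR - b$R, c(-1, 1)),
    GDVI  = e(c("G", "NIR"), function(b) b$NIR - b$G, c(-1, 1)),
    WDRVI = e(c("R", "NIR"), function(b) (0.12 * b$NIR - b$R) / (0.12 * b$NIR + b$R), c(-1, 1)),
    IPVI  = e(c("R", "NIR"), function(b) b$NIR / (b$NIR + b$R), c(0, 1)),
    NGRVI = e(c("G", "NIR"), function(b) b$NIR / b$G, c(0, Inf)),
    TVI   = e(c("G", "R", "NIR"), function(b) 0.5 * (120 * (b$NIR - b$G) - 200 * (b$R - b$G)), c(-160, 160))
  )
}

#' @exportS3Method base::print
print.vi_registry <- function(x, ...) {
  rgb_n <- sum(vapply(x, function(e) all(e$bands %in% c("R", "G", "B")), logical(1)))
  cat(sprintf("<vi_registry> %d indices (%d RGB-only, %d using RE/NIR)\n",
              length(x), rgb_n, length(x) - rgb_n))
  invisible(x)
}
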