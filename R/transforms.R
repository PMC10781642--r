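#' Trait transforms used throughout the package
#'
#' Proportions at birth (neonatal / adult size, as fractions in \[0, 1\]) are
#' arcsine-square-root transformed; absolute sizes and gestation lengths are
#' natural-log transformed. `transform_trait()` applies one of these by tag.
#'
#' @param values numeric vector (optionally named by species).
#' @param kind one of `"log"`, `"arcsine_sqrt"`, `"identity"`.
#' @return numeric vector of the same length and names, with attribute
#'   `transform` recording the tag.
#' @examples
#' transform_trait(c(0, 0.25, 1), "arcsine_sqrt")  # 0, pi/6, pi/2
#' transform_trait(275, "log")                     # log(275)
#' @export
transform_trait <- function(values, kind = c("log", "arcsine_sqrt", "identity")) {
  kind <- match.arg(kind)
  out <- switch(kind,
    log = {
      if (any(values <= 0, na.rm = TRUE)) {
        abort("log transform requires strictly positive values")
      }
      log(values)
    },
    arcsine_sqrt = {
      if (any(values < 0 | values > 1, na.rm = TRUE)) {
        abort("arcsine_sqrt transform requires fractions in [0, 1]")
      }
      asin(sqrt(values))
    },
    identity = values
  )
  attr(out, "transform") <- kind
  out
}

## normalized species names: case-insensitive, underscores and spaces
## interchangeable, surrounding whitespace ignored. No fuzzy matching.
normalize_name <- function(x) {
  x <- gsub("_", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}
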