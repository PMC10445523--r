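#' Binned droplet size distribution
#'
#' Container for a laser-diffraction style droplet size distribution: strictly
#' increasing bin diameters with non-negative weights that are normalized to
#' sum to one.  Weights may be number-based or volume-based; moment means
#' convert internally.
#'
#' @param diameters numeric vector of bin diameters in micrometres, strictly
#'   increasing and positive.
#' @param weights numeric vector of bin weights (any non-negative scale;
#'   normalized on construction).
#' @param weighting `"number"` or `"volume"`: what the weights count.
#' @return An object of class `size_distribution` with elements `diameters`,
#'   `weights` and `weighting`.
#' @examples
#' sd <- size_distribution(c(1, 2), c(0.5, 0.5), "number")
#' mean_diameter(sd, 4, 3)
#' @export
size_distribution <- function(diameters, weights,
                              weighting = c("number", "volume")) {
  weighting <- match.arg(weighting)
  if (length(diameters) == 0L) stop("empty size distribution")
  if (length(diameters) != length(weights)) {
    stop("diameters and weights must have equal length")
  }
  if (!all(is.finite(diameters)) || any(diameters <= 0)) {
    stop("all bin diameters must be positive and finite")
  }
  if (length(diameters) > 1L && any(diff(diameters) <= 0)) {
    stop("bin diameters must be strictly increasing")
  }
  if (!all(is.finite(weights)) || any(weights < 0)) {
    stop("all weights must be non-negative and finite")
  }
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  structure(list(diameters = as.numeric(diameters),
                 weights = as.numeric(weights) / s,
                 weighting = weighting),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("size_distribution: %d bins, %.3g-%.3g um, %s-weighted\n",
              length(x$diameters), min(x$diameters), max(x$diameters),
              x$weighting))
  cat(sprintf("  d4,3 = %.4g um, d3,2 = %.4g um\n", d43(x), d32(x)))
  invisible(x)
}

#' Convert between number and volume weighting
#'
#' Number weights are proportional to volume weights divided by the cubed bin
#' diameter (and vice versa), renormalized.  Converting one way and back
#' reproduces the original weights to numerical precision.
#'
#' @param dist a [size_distribution()].
#' @return A `size_distribution` in the requested weighting.
#' @export
as_number_weights <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (dist$weighting == "number") return(dist)
  size_distribution(dist$diameters, dist$weights / dist$diameters^3, "number")
}

#' @rdname as_number_weights
#' @export
as_volume_weights <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  if (dist$weighting == "volume") return(dist)
  size_distribution(dist$diameters, dist$weights * dist$diameters^3, "volume")
}

#' Moment mean diameter d(p,q)
#'
#' Computes the generalized moment mean
#' `(sum(n_i d_i^p) / sum(n_i d_i^q))^(1/(p-q))` over the number-weighted
#' distribution, the standard family containing the volume mean diameter
#' d4,3 (`p = 4, q = 3`) and the surface mean diameter d3,2 (`p = 3,
#' q = 2`), for which the exponent is 1 and the mean is the plain moment
#' ratio.  Volume-weighted input is converted to number weights first.
#'
#' @param dist a [size_distribution()].
#' @param p,q non-negative moment orders with `p > q`.
#' @return The mean diameter in micrometres.
#' @export
mean_diameter <- function(dist, p = 4, q = 3) {
  stopifnot(inherits(dist, "size_distribution"))
  if (!(p > q && q >= 0)) stop("require p > q >= 0")
  nd <- as_number_weights(dist)
  (sum(nd$weights * nd$diameters^p) /
     sum(nd$weights * nd$diameters^q))^(1 / (p - q))
}

#' @rdname mean_diameter
#' @export
d43 <- function(dist) mean_diameter(dist, 4, 3)

#' @rdname mean_diameter
#' @export
d32 <- function(dist) mean_diameter(dist, 3, 2)

#' Read / write size distributions as CSV
#'
#' Two-column CSV (`diameter_um`, `weight`) preceded by a comment line
#' `# weighting=number|volume` declaring the weighting convention.
#'
#' @param path file path.
#' @param dist a [size_distribution()] (for writing).
#' @return `read_size_distribution` returns a `size_distribution`;
#'   `write_size_distribution` returns `path` invisibly.
#' @export
read_size_distribution <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("weighting\\s*=\\s*(number|volume)", first))[[1]]
  if (length(m) < 2L) {
    stop("missing '# weighting=number|volume' header line in ", path)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("diameter_um", "weight")
  if (!all(need %in% names(df))) {
    stop("size distribution CSV must have columns diameter_um, weight")
  }
  size_distribution(df$diameter_um, df$weight, m[2])
}

#' @rdname read_size_distribution
#' @export
write_size_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "size_distribution"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weighting=%s", dist$weighting), con)
  utils::write.csv(data.frame(diameter_um = dist$diameters,
                              weight = dist$weights),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
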