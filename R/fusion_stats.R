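# Binomial statistics for replicate fusion outcomes.

#' Binomial estimate of a fusion probability
#'
#' Point estimate and standard deviation for `k` successes in `n` Bernoulli
#' trials: `p_hat = k / n` with the binomial sampling standard deviation
#' `sqrt(p_hat (1 - p_hat) / n)` (the population proportion is replaced by
#' its plug-in estimate, which is what reproduces conventional reported
#' `p +/- sd` values).  The sd is zero exactly when `p_hat` is 0 or 1.
#'
#' @param k number of successes (fused runs).
#' @param n number of trials (runs), at least 1.
#' @return An object of class `binomial_estimate`: `k`, `n`, `p_hat`, `sd`.
#' @examples
#' binomial_estimate(7, 10)   # 0.70 +/- 0.14
#' @export
binomial_estimate <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1L) stop("need at least one trial")
  if (k < 0L || k > n) stop("successes must lie in [0, n]")
  p <- k / n
  structure(list(k = as.integer(k), n = as.integer(n), p_hat = p,
                 sd = sqrt(p * (1 - p) / n)),
            class = "binomial_estimate")
}

#' @export
print.binomial_estimate <- function(x, ...) {
  cat(sprintf("fusion probability: %.2f +/- %.2f (%d of %d runs)\n",
              x$p_hat, x$sd, x$k, x$n))
  invisible(x)
}

#' Aggregate fusion records into a binomial estimate
#'
#' @param records a list of [fusion_record()] objects.
#' @return A [binomial_estimate()] over the fused fraction.
#' @export
fusion_probability <- function(records) {
  if (!length(records)) stop("no fusion records")
  stopifnot(all(vapply(records, inherits, NA, "fusion_record")))
  fused <- vapply(records, `[[`, NA, "fused")
  binomial_estimate(sum(fused), length(fused))
}

#' Wilson score interval
#'
#' Optional interval estimate for a binomial proportion; not used by the
#' default reporting (which mirrors plain `p +/- sd`), provided for users
#' who want a proper interval at small `n`.
#'
#' @param k,n successes and trials.
#' @param level confidence level.
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
wilson_interval <- function(k, n, level = 0.95) {
  stopifnot(n >= 1L, k >= 0L, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Read / write fusion records as JSON
#'
#' `write_fusion_records` writes a list of records to one JSON file;
#' `read_fusion_records` reads either such a file or a directory of
#' per-run JSON files.
#'
#' @param records list of [fusion_record()] objects.
#' @param path JSON file (write) or file/directory (read).
#' @return `read_fusion_records` returns a list of `fusion_record`s.
#' @export
write_fusion_records <- function(records, path) {
  stopifnot(all(vapply(records, inherits, NA, "fusion_record")))
  jsonlite::write_json(lapply(records, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fusion_records
#' @export
read_fusion_records <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.json$", full.names = TRUE)
  } else {
    path
  }
  if (!length(files)) stop("no JSON files at ", path)
  recs <- list()
  for (f in files) {
    raw <- jsonlite::read_json(f)
    if (!is.null(raw$run_id)) raw <- list(raw)   # single-record file
    for (r in raw) {
      recs[[length(recs) + 1L]] <- fusion_record(
        run_id = r$run_id, fused = isTRUE(r$fused),
        first_contact = if (is.null(r$first_contact)) NA_integer_
                        else r$first_contact,
        cutoff = if (is.null(r$cutoff)) NA_real_ else r$cutoff,
        persistence = if (is.null(r$persistence)) NA_integer_
                      else r$persistence)
    }
  }
  recs
}
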