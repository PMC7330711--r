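#' Canonical oscillatory frequency bands
#'
#' The six bands used throughout the pipeline: delta (1--4 Hz), theta
#' (4--8 Hz), alpha (8--12 Hz), low beta (13--20 Hz), high beta (20--30 Hz)
#' and gamma (30--80 Hz).
#'
#' @return A data frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
#' @examples
#' band_table()
band_table <- function() {
  data.frame(
    name   = c("delta", "theta", "alpha", "low_beta", "high_beta", "gamma"),
    f_low  = c(1, 4, 8, 13, 20, 30),
    f_high = c(4, 8, 12, 20, 30, 80),
    stringsAsFactors = FALSE
  )
}

#' Construct a frequency-band specification
#'
#' @param name Band name. One of the canonical names (see [band_table()]) or
#'   any label when `f_low`/`f_high` are given explicitly.
#' @param f_low,f_high Band edges in Hz. Defaults to the canonical table entry
#'   for `name`.
#' @return An object of class `band_spec`: a list with `name`, `f_low`,
#'   `f_high`.
#' @export
#' @examples
#' band_spec("alpha")
#' band_spec("mu", 9, 13)
band_spec <- function(name, f_low = NULL, f_high = NULL) {
  tab <- band_table()
  if (is.null(f_low) || is.null(f_high)) {
    row <- tab[tab$name == name, ]
    if (nrow(row) != 1L) {
      stop("unknown band name '", name, "'; canonical bands are: ",
           paste(tab$name, collapse = ", "), call. = FALSE)
    }
    f_low <- row$f_low
    f_high <- row$f_high
  }
  stopifnot(is.numeric(f_low), is.numeric(f_high), length(f_low) == 1L,
            length(f_high) == 1L)
  if (!(f_low > 0 && f_low < f_high)) {
    stop("band edges must satisfy 0 < f_low < f_high (got ", f_low, ", ",
         f_high, ")", call. = FALSE)
  }
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

as_band_spec <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) return(band_spec(band))
  stop("'band' must be a band_spec or a canonical band name", call. = FALSE)
}
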