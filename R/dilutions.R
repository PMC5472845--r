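#' Construct a dilution series
#'
#' A dilution series is an ordered set of prepared tastant concentrations,
#' strictly decreasing (sample 1 = strongest), spaced equidistantly on the
#' decadic logarithmic scale. All adaptive-engine arithmetic happens on
#' log10 concentration in mM.
#'
#' @param concentrations Concentrations in mM, strictly decreasing, length
#'   >= 3 (length 2 is allowed for degenerate endpoint-only series built by
#'   [make_series()]).
#' @param tastant Label for the tastant.
#' @param start_index Index of the session's starting concentration
#'   (1 = strongest).
#' @param quality Optional taste-quality label (sweet, sour, salty, bitter).
#' @param molar_mass Optional molar mass in g/mol, stored as metadata only.
#' @param check_spacing If `TRUE` (default), require the log10 spacing
#'   between adjacent entries to be constant within `spacing_tol`.
#' @param spacing_tol Tolerance on the spread of adjacent log10 gaps. The
#'   default 0.02 accepts published concentration tables that are rounded or
#'   hand-adjusted in the fourth significant digit; series generated by
#'   [make_series()] are equidistant to machine precision.
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(concentrations, tastant = "tastant",
                            start_index = 1L, quality = NA_character_,
                            molar_mass = NA_real_, check_spacing = TRUE,
                            spacing_tol = 0.02) {
  conc <- as.numeric(concentrations)
  if (length(conc) < 2 || any(!is.finite(conc)) || any(conc <= 0)) {
    stop("concentrations must be >= 2 finite positive values", call. = FALSE)
  }
  if (any(diff(conc) >= 0)) {
    stop("concentrations must be strictly decreasing (sample 1 = strongest)",
         call. = FALSE)
  }
  lg <- log10(conc)
  if (check_spacing && length(conc) > 2) {
    gaps <- -diff(lg)
    if (max(gaps) - min(gaps) > spacing_tol) {
      stop(sprintf("log10 spacing not constant within %g log10 units",
                   spacing_tol), call. = FALSE)
    }
  }
  start_index <- as.integer(start_index)
  stopifnot(start_index >= 1, start_index <= length(conc))
  structure(
    list(tastant = tastant, quality = quality, concentrations = conc,
         log10_conc = lg, n_steps = length(conc), start_index = start_index,
         molar_mass = molar_mass),
    class = "dilution_series"
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "Dilution series '%s': %d samples, %.6g to %.6g mM (step width %.3f log10), start at sample %d\n",
    x$tastant, x$n_steps, x$concentrations[1],
    x$concentrations[x$n_steps], step_width(x), x$start_index))
  invisible(x)
}

#' @method as_tibble dilution_series
#' @export
as_tibble.dilution_series <- function(x, ...) {
  tibble::tibble(
    tastant = x$tastant, quality = x$quality,
    sample = seq_len(x$n_steps), conc_mM = x$concentrations,
    log10_mM = x$log10_conc, start = seq_len(x$n_steps) == x$start_index
  )
}

#' Generate a log-equidistant dilution series from its endpoints
#'
#' Produces `n` concentrations spaced equidistantly on the decadic log grid,
#' with the endpoints equal to `c_max` and `c_min` exactly:
#' entry k is \eqn{10^{\log_{10} c_{max} - (k-1)\Delta}} with
#' \eqn{\Delta = (\log_{10} c_{max} - \log_{10} c_{min})/(n-1)}.
#'
#' @param c_max Strongest concentration in mM.
#' @param c_min Weakest concentration in mM; `0 < c_min < c_max`.
#' @param n Number of samples, `n >= 2`.
#' @inheritParams dilution_series
#' @return A `dilution_series`.
#' @examples
#' make_series(342.231348, 0.342231, 12, tastant = "sodium chloride")
#' @export
make_series <- function(c_max, c_min, n, tastant = "tastant",
                        start_index = 1L, quality = NA_character_,
                        molar_mass = NA_real_) {
  stopifnot(is.numeric(c_max), is.numeric(c_min), c_min > 0, c_max > c_min,
            n >= 2)
  lg <- seq(log10(c_max), log10(c_min), length.out = n)
  conc <- 10 ^ lg
  conc[1] <- c_max
  conc[n] <- c_min
  dilution_series(conc, tastant = tastant, start_index = start_index,
                  quality = quality, molar_mass = molar_mass)
}

#' Step width of a dilution series in log10 units
#'
#' `(log10(c_max) - log10(c_min)) / (n - 1)`, rounded to three decimals for
#' reporting, matching how step widths are quoted for prepared series.
#'
#' @param series A `dilution_series`.
#' @param digits Decimals to round to; `NULL` for the unrounded value.
#' @export
step_width <- function(series, digits = 3) {
  stopifnot(inherits(series, "dilution_series"))
  w <- (series$log10_conc[1] - series$log10_conc[series$n_steps]) /
    (series$n_steps - 1)
  if (is.null(digits)) w else round(w, digits)
}

#' Nearest prepared concentration to a continuous proposal
#'
#' Maps an engine proposal (log10 mM) to the index of the closest prepared
#' concentration, with closeness measured in log10 space. Proposals beyond
#' either end are clamped. Exact ties are broken toward the stronger
#' concentration, so that the presented stimulus stays detectable and the
#' adaptive track informative.
#'
#' @param series A `dilution_series`.
#' @param proposal Intensity in log10 mM (vectorised).
#' @return Integer indices into the series (1 = strongest).
#' @export
nearest_step <- function(series, proposal) {
  stopifnot(inherits(series, "dilution_series"))
  if (any(!is.finite(proposal))) stop("proposal must be finite", call. = FALSE)
  vapply(proposal, function(p) {
    d <- abs(series$log10_conc - p)
    # distances within 1e-9 log10 units count as tied; entries are ordered
    # strongest first, so the tie resolves to the stronger concentration
    which(d <= min(d) + 1e-9)[1]
  }, integer(1))
}

#' Load one of the packaged tastant dilution series
#'
#' The four prepared series (sweet/sucrose, sour/citric acid, salty/sodium
#' chloride, bitter/quinine hydrochloride) ship with the package verbatim,
#' including each session's starting concentration.
#'
#' @param quality One of `"sweet"`, `"sour"`, `"salty"`, `"bitter"`.
#' @return A `dilution_series`.
#' @examples
#' taste_series("salty")
#' @export
taste_series <- function(quality = c("sweet", "sour", "salty", "bitter")) {
  quality <- match.arg(quality)
  path <- system.file("extdata", "dilution_series.tsv", package = "gustadapt",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  tab <- tab[tab$quality == quality, , drop = FALSE]
  tab <- tab[order(tab$sample), , drop = FALSE]
  dilution_series(tab$conc_mM, tastant = tab$tastant[1],
                  start_index = which(tab$start == 1), quality = quality,
                  molar_mass = tab$molar_mass_g_mol[1])
}

#' Read / write a dilution series as delimited text
#'
#' The on-disk format is a tab-separated table with columns `tastant`,
#' `sample`, `conc_mM` and optional `start` (0/1), `quality`,
#' `molar_mass_g_mol`.
#'
#' @param series A `dilution_series`.
#' @param path File path.
#' @return `write_series()` returns `series` invisibly; `read_series()`
#'   returns a `dilution_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dilution_series"))
  out <- tibble::tibble(
    tastant = series$tastant, quality = series$quality,
    molar_mass_g_mol = series$molar_mass,
    sample = seq_len(series$n_steps), conc_mM = series$concentrations,
    start = as.integer(seq_len(series$n_steps) == series$start_index)
  )
  readr::write_tsv(out, path)
  invisible(series)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("tastant", "sample", "conc_mM") %in% names(tab)))
  tab <- tab[order(tab$sample), , drop = FALSE]
  start <- if ("start" %in% names(tab) && any(tab$start == 1)) {
    which(tab$start == 1)[1]
  } else 1L
  dilution_series(
    tab$conc_mM, tastant = tab$tastant[1], start_index = start,
    quality = if ("quality" %in% names(tab)) tab$quality[1] else NA_character_,
    molar_mass = if ("molar_mass_g_mol" %in% names(tab)) {
      tab$molar_mass_g_mol[1]
    } else NA_real_
  )
}
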