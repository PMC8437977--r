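#' Dose-volume histogram objects
#'
#' A `dvh` is a tibble with one row per dose bin and columns `dose_gy` (bin
#' midpoint, Gy) and `volume_fraction` (differential fractional volume).
#' Bins are uniformly spaced on the dose axis and volumes are normalised to
#' sum to one, so the object represents the distribution of absorbed dose
#' over the structure volume. The structure name and bin width travel as
#' attributes.
#'
#' @param dose_gy Numeric vector of bin midpoint doses in Gy, strictly
#'   increasing and uniformly spaced.
#' @param volume_fraction Non-negative differential volumes, one per bin.
#'   They are normalised to sum to one (normalisation is idempotent).
#' @param structure Structure name, default `"heart"`.
#' @return A tibble of class `dvh`.
#' @examples
#' d <- dvh(c(5, 15, 25), c(0.2, 0.3, 0.5))
#' mean_dose(d)
#' @export
dvh <- function(dose_gy, volume_fraction, structure = "heart") {
  if (length(dose_gy) == 0L) abort_malformed("DVH must have at least one bin")
  if (length(dose_gy) != length(volume_fraction)) {
    abort_malformed("dose_gy and volume_fraction must have equal length")
  }
  if (any(!is.finite(dose_gy)) || any(!is.finite(volume_fraction))) {
    abort_malformed("DVH doses and volumes must be finite")
  }
  if (any(volume_fraction < 0)) abort_malformed("DVH volumes must be non-negative")
  if (is.unsorted(dose_gy, strictly = TRUE)) {
    abort_malformed("DVH bin doses must be strictly increasing")
  }
  if (length(dose_gy) > 1L) {
    w <- diff(dose_gy)
    width <- w[1L]
    if (any(abs(w - width) > 1e-12 + 1e-9 * width)) {
      abort_malformed("DVH bin width must be constant")
    }
  } else {
    width <- 0.1
  }
  total <- sum(volume_fraction)
  if (total <= 0) abort_malformed("DVH total volume must be positive")
  out <- tibble::tibble(
    dose_gy = as.numeric(dose_gy),
    volume_fraction = as.numeric(volume_fraction) / total
  )
  structure(out,
    class = c("dvh", class(out)),
    structure_name = structure,
    bin_width = width
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "<dvh> structure '%s', %d bins of %.4g Gy, mean dose %.2f Gy\n",
    attr(x, "structure_name"), nrow(x), attr(x, "bin_width"), mean_dose(x)
  ))
  NextMethod()
}

is_dvh <- function(x) inherits(x, "dvh")

check_dvh <- function(x) {
  if (!is_dvh(x)) abort_malformed("expected a dvh object")
  if (nrow(x) == 0L) abort_malformed("empty DVH")
  invisible(x)
}

#' Cumulative form of a DVH
#'
#' Returns the cumulative representation V(D): the fraction of the structure
#' volume receiving at least dose D, evaluated at the bin lower edges. The
#' cumulative curve is non-increasing and starts at 1.
#'
#' @param x A [dvh()].
#' @return A tibble with columns `dose_gy` (bin lower edge) and
#'   `volume_fraction` (cumulative).
#' @export
dvh_cumulative <- function(x) {
  check_dvh(x)
  w <- attr(x, "bin_width")
  edges <- x$dose_gy - w / 2
  tibble::tibble(
    dose_gy = c(edges, max(x$dose_gy) + w / 2),
    volume_fraction = c(rev(cumsum(rev(x$volume_fraction))), 0)
  )
}

#' Mean dose of a DVH
#'
#' The volume-weighted mean dose, computed as the sum of bin midpoint dose
#' times fractional volume. For the heart structure this is the mean heart
#' dose (MHD), the dose metric of the whole-organ (n = 1) NTCP models.
#'
#' @param x A [dvh()].
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(x) {
  check_dvh(x)
  sum(x$dose_gy * x$volume_fraction)
}

#' Fractional volume receiving at least a threshold dose
#'
#' V(threshold): the fraction of structure volume whose bin dose is at or
#' above `threshold`. A non-increasing step function of the threshold with
#' V(0) = 1.
#'
#' @param x A [dvh()].
#' @param threshold Dose threshold in Gy, non-negative. Vectorised.
#' @return Fractional volume in `[0, 1]`.
#' @export
volume_at_dose <- function(x, threshold) {
  check_dvh(x)
  if (any(threshold < 0)) abort_domain("dose threshold must be non-negative")
  vapply(threshold, function(t) sum(x$volume_fraction[x$dose_gy >= t]), numeric(1))
}

#' Maximum dose with non-zero volume
#'
#' @param x A [dvh()].
#' @return Highest bin midpoint dose (Gy) carrying volume.
#' @export
max_dose <- function(x) {
  check_dvh(x)
  max(x$dose_gy[x$volume_fraction > 0])
}

#' Read DVHs from an interchange CSV file
#'
#' The interchange format is a long CSV with columns `structure`, `dose_gy`
#' and `volume_fraction`, one row per (structure, bin), optionally preceded
#' by a comment line `# kind: differential` or `# kind: cumulative`
#' declaring the dialect. Differential rows carry bin midpoint doses;
#' cumulative rows carry bin-edge doses with the fraction of volume
#' receiving at least that dose, and are converted to differential form by
#' adjacent differencing.
#'
#' @param path Path to the CSV file.
#' @param dialect `"auto"` (read the header comment), `"differential"` or
#'   `"cumulative"`.
#' @return A named list of [dvh()] objects, one per structure.
#' @export
read_dvh <- function(path, dialect = c("auto", "differential", "cumulative")) {
  dialect <- tryCatch(match.arg(dialect),
    error = function(e) abort_config("unknown DVH dialect")
  )
  if (!file.exists(path)) abort_malformed(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (dialect == "auto") {
    if (grepl("^#\\s*kind:\\s*cumulative", first)) {
      dialect <- "cumulative"
    } else if (grepl("^#\\s*kind:\\s*differential", first)) {
      dialect <- "differential"
    } else {
      abort_config("dialect 'auto' requires a '# kind: ...' header comment")
    }
  }
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("structure", "dose_gy", "volume_fraction")
  if (!all(need %in% names(tab))) {
    abort_malformed(sprintf("DVH file must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(tab$volume_fraction < 0)) abort_malformed("negative volumes in DVH file")
  split(tab, tab$structure) |>
    purrr::map(function(df) {
      df <- dplyr::arrange(df, .data$dose_gy)
      if (dialect == "differential") {
        dvh(df$dose_gy, df$volume_fraction, structure = df$structure[1L])
      } else {
        cumulative_to_dvh(df$dose_gy, df$volume_fraction, df$structure[1L])
      }
    })
}

# Cumulative rows are (edge dose, volume receiving >= edge); differencing
# adjacent edges gives the differential volume of each bin, located at the
# edge midpoint. Residual volume above the last edge, if any, is assigned
# to one extra bin.
cumulative_to_dvh <- function(edges, cum_volume, structure) {
  if (length(edges) < 2L) abort_malformed("cumulative DVH needs at least two edges")
  total <- cum_volume[1L]
  if (total <= 0) abort_malformed("cumulative DVH must start with positive volume")
  cum <- cum_volume / total
  if (any(diff(cum) > 1e-9)) {
    abort_malformed("cumulative DVH volumes must be non-increasing")
  }
  diff_vol <- -diff(cum)
  mid <- (edges[-length(edges)] + edges[-1L]) / 2
  w <- diff(edges)[1L]
  resid <- cum[length(cum)]
  if (resid > 1e-12) {
    mid <- c(mid, edges[length(edges)] + w / 2)
    diff_vol <- c(diff_vol, resid)
  }
  dvh(mid, diff_vol, structure = structure)
}

#' Write DVHs to the interchange CSV format
#'
#' @param x A [dvh()] or a (possibly named) list of them.
#' @param path Output path.
#' @param kind `"differential"` (bin midpoints) or `"cumulative"`
#'   (bin edges); declared in the header comment for round-tripping.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(x, path, kind = c("differential", "cumulative")) {
  kind <- match.arg(kind)
  if (is_dvh(x)) x <- list(x)
  rows <- purrr::map(x, function(d) {
    check_dvh(d)
    if (kind == "differential") {
      tibble::tibble(
        structure = attr(d, "structure_name"),
        dose_gy = d$dose_gy,
        volume_fraction = d$volume_fraction
      )
    } else {
      cum <- dvh_cumulative(d)
      tibble::tibble(
        structure = attr(d, "structure_name"),
        dose_gy = cum$dose_gy,
        volume_fraction = cum$volume_fraction
      )
    }
  })
  tab <- dplyr::bind_rows(rows)
  writeLines(sprintf("# kind: %s", kind), path)
  readr::write_csv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
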