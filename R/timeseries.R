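#' Build a tidy abundance series
#'
#' Converts a species-by-day abundance matrix into the long (tidy) form used
#' throughout the package: one row per species per day, with columns
#' `species`, `day` and `abundance`.
#'
#' @param values Non-negative numeric matrix, species in rows, days in columns.
#' @param species_ids Character vector of species identifiers; defaults to the
#'   matrix rownames (or `sp_1 ...` when absent).
#' @param days Integer vector of day labels, strictly increasing; defaults to
#'   column names parsed as `day_<n>` (or `1:ncol`).
#' @return A tibble with columns `species` (character), `day` (integer),
#'   `abundance` (double).
#' @examples
#' m <- matrix(c(2, 0, 1, 3), nrow = 2, dimnames = list(c("a", "b"), NULL))
#' abundance_series(m, days = c(1L, 2L))
#' @export
abundance_series <- function(values, species_ids = NULL, days = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix (species x days)")
  }
  if (any(values < 0) || anyNA(values)) {
    stop_invalid("abundances must be non-negative and non-missing")
  }
  species_ids <- species_ids %||% rownames(values) %||%
    sprintf("sp_%d", seq_len(nrow(values)))
  days <- days %||% parse_day_labels(colnames(values)) %||% seq_len(ncol(values))
  days <- as.integer(days)
  if (length(species_ids) != nrow(values) || length(days) != ncol(values)) {
    stop_invalid("`species_ids`/`days` lengths must match the matrix dimensions")
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop_invalid("day labels must be strictly increasing")
  }
  tibble(
    species = rep(as.character(species_ids), times = length(days)),
    day = rep(days, each = length(species_ids)),
    abundance = as.numeric(values)
  )
}

parse_day_labels <- function(x) {
  if (is.null(x)) return(NULL)
  suppressWarnings(as.integer(sub("^day_", "", x)))
}

validate_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("species", "day", "abundance") %in% names(series))) {
    stop_invalid("an abundance series needs columns `species`, `day`, `abundance`")
  }
  if (any(series$abundance < 0, na.rm = TRUE) || anyNA(series$abundance)) {
    stop_invalid("abundances must be non-negative and non-missing")
  }
  invisible(series)
}

# Long tibble -> species x day matrix with sorted integer day columns.
as_abundance_matrix <- function(series) {
  validate_series(series)
  days <- sort(unique(as.integer(series$day)))
  species <- unique(series$species)
  m <- matrix(0, nrow = length(species), ncol = length(days),
              dimnames = list(species, sprintf("day_%d", days)))
  m[cbind(match(series$species, species), match(as.integer(series$day), days))] <-
    series$abundance
  attr(m, "days") <- days
  m
}

#' Per-day relative abundances
#'
#' Normalizes each day's column to sum to one, so downstream dissimilarities
#' compare community compositions rather than sequencing depths or total
#' coverages.
#'
#' @param series Abundance series tibble (see [abundance_series()]).
#' @return A tibble of the same shape with `abundance` replaced by the
#'   within-day relative abundance.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 2, 0), nrow = 3, dimnames = list(c("a","b","c")))
#' relative_abundance(abundance_series(m, days = 1:2))
#' @export
relative_abundance <- function(series) {
  validate_series(series)
  totals <- tapply(series$abundance, series$day, sum)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0) {
    stop_invalid(sprintf("day(s) %s have zero total abundance; cannot normalize",
                         paste(zero, collapse = ", ")))
  }
  series %>%
    group_by(.data$day) %>%
    mutate(abundance = .data$abundance / sum(.data$abundance)) %>%
    ungroup() %>%
    as_tibble()
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(u, v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}. Zero for
#' identical compositions, one for disjoint supports. On vectors that each
#' sum to one it equals half the L1 distance, so a value above 0.5 means more
#' than half of the composition turned over.
#'
#' @param u,v Non-negative numeric vectors of equal length, not both all-zero.
#' @return A single dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 0), c(1, 1)) # 0.5
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop_invalid("`u` and `v` must have equal length")
  if (any(u < 0) || any(v < 0) || anyNA(u) || anyNA(v)) {
    stop_invalid("abundance vectors must be non-negative and non-missing")
  }
  if (sum(u) + sum(v) == 0) {
    stop_invalid("Bray-Curtis is undefined when both vectors are all-zero")
  }
  as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
}

#' Windowed abruptness index of community turnover
#'
#' For each time point `t` at which both windows fit, the abruptness is the
#' Bray-Curtis dissimilarity between the average community composition over
#' the trailing window (samples `t - w + 1 ... t`) and the leading window
#' (samples `t + 1 ... t + w`). Large values flag rapid compositional shifts;
#' with per-day normalization a value above 0.5 means more than half of the
#' composition turned over between the windows.
#'
#' @param series Abundance series tibble.
#' @param window Window width `w` in samples (default 5, i.e. 5-day windows
#'   on a daily series).
#' @param normalize Normalize each day to relative abundances before window
#'   averaging (default `TRUE`). Raw per-day totals then carry no weight.
#' @param contiguous If `TRUE`, only emit time points whose two windows span
#'   calendar-consecutive day labels; with irregular sampling (gaps) the
#'   default `FALSE` builds windows over available consecutive samples.
#' @return A tibble of class `facilinet_abruptness` with columns `t` (the day
#'   label of the last sample of the trailing window) and `abruptness`.
#' @examples
#' m <- cbind(matrix(c(2, 0), 2, 5), matrix(c(1, 1), 2, 5))
#' rownames(m) <- c("a", "b")
#' abruptness(abundance_series(m, days = 1:10), window = 5)
#' @export
abruptness <- function(series, window = 5, normalize = TRUE, contiguous = FALSE) {
  w <- check_count(window, "window", min = 1L)
  validate_series(series)
  if (normalize) series <- relative_abundance(series)
  m <- as_abundance_matrix(series)
  days <- attr(m, "days")
  n <- length(days)
  if (n < 2L * w) {
    stop_invalid(sprintf("need at least 2 * window = %d samples, got %d", 2L * w, n))
  }
  idx <- seq.int(w, n - w)
  if (contiguous) {
    span_ok <- vapply(idx, function(i) {
      days[i + w] - days[i - w + 1L] == 2L * w - 1L
    }, logical(1))
    idx <- idx[span_ok]
  }
  vals <- vapply(idx, function(i) {
    bray_curtis(rowMeans(m[, (i - w + 1L):i, drop = FALSE]),
                rowMeans(m[, (i + 1L):(i + w), drop = FALSE]))
  }, numeric(1))
  out <- tibble(t = days[idx], abruptness = vals)
  class(out) <- c("facilinet_abruptness", class(out))
  attr(out, "window") <- w
  out
}

#' Read / write a species-by-day abundance TSV
#'
#' The on-disk format is wide: first column `species`, remaining columns
#' `day_<n>` holding non-negative abundances.
#'
#' @param path File path.
#' @return `read_abundance_tsv()` returns a tidy abundance series tibble.
#' @export
read_abundance_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  abundance_series(m, days = parse_day_labels(colnames(m)))
}

#' @rdname read_abundance_tsv
#' @param series Abundance series tibble to write.
#' @export
write_abundance_tsv <- function(series, path) {
  m <- as_abundance_matrix(series)
  df <- tibble::as_tibble(m, rownames = "species")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @export
autoplot.facilinet_abruptness <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$abruptness)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "day", y = "abruptness (Bray-Curtis between windows)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
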