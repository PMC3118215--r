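#' Tukey biweight location estimate
#'
#' The robust "bi-weight mean" used to centre array log2 ratios around zero.
#' Initialised at the median with scale `c * MAD` (MAD unscaled, held fixed),
#' the estimate iterates the weighted mean with weights `(1 - u^2)^2` for
#' `|u| = |x - m| / (c * MAD) < 1` (0 otherwise) until the update is below
#' `tol` or `max_iter` iterations. When the MAD is zero the median is returned.
#'
#' @param x Numeric vector, at least one finite value.
#' @param c Tuning constant (default 5.0).
#' @param tol Convergence tolerance on the location update.
#' @param max_iter Iteration cap.
#' @return The biweight location, a single number.
#' @export
#' @examples
#' biweight_mean(c(0, 0.1, -0.1, 0.05, 8))  # outlier barely moves it
biweight_mean <- function(x, c = 5.0, tol = 1e-9, max_iter = 50L) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("biweight_mean: no finite values")
  m <- median(x)
  s <- median(abs(x - m))  # unscaled MAD, fixed across iterations
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Centre signal tracks by biweight-mean subtraction
#'
#' Subtracts the array-wide biweight mean of the log2 ratios from every probe,
#' independently for each (tissue, stage, replicate) track, so that each
#' track's ratio distribution is centred around zero.
#'
#' @param signal Signal tibble with columns `tissue`, `stage`, `replicate`,
#'   `probe_id`, `log2_ratio` (one or many tracks).
#' @param c Biweight tuning constant.
#' @return The same tibble with centred `log2_ratio`, carrying attribute
#'   `medip_scaled = TRUE`. Scaling an already-scaled object errors.
#' @export
scale_tracks <- function(signal, c = 5.0) {
  if (isTRUE(attr(signal, "medip_scaled"))) {
    abort("scale_tracks: track is already scaled")
  }
  if (!all(c("probe_id", "log2_ratio") %in% names(signal))) {
    abort("signal needs columns probe_id, log2_ratio")
  }
  keys <- intersect(c("tissue", "stage", "replicate"), names(signal))
  out <- signal |>
    group_by(across(all_of(keys))) |>
    mutate(log2_ratio = .data$log2_ratio - biweight_mean(.data$log2_ratio, c = c)) |>
    ungroup()
  attr(out, "medip_scaled") <- TRUE
  out
}

#' Pearson concordance between two replicate tracks
#'
#' @param a,b Tibbles with `probe_id` and a value column (`log2_ratio` or
#'   `pscore`) over the same probe universe.
#' @param value Name of the value column; guessed when `NULL`.
#' @return One-row tibble with `r` (Pearson coefficient over matched probes)
#'   and `n_probes`. `r` is `NaN` with a warning when either vector has zero
#'   variance.
#' @export
replicate_concordance <- function(a, b, value = NULL) {
  value <- value %||% intersect(c("pscore", "log2_ratio"), names(a))[1]
  if (is.na(value) || !value %in% names(a) || !value %in% names(b)) {
    abort("replicate_concordance: value column not found in both tracks")
  }
  m <- left_join(select(a, all_of(c("probe_id", value))),
                 select(b, all_of(c("probe_id", value))),
                 by = "probe_id", suffix = c("_a", "_b"))
  if (anyNA(m)) abort("replicate_concordance: probe universes differ")
  va <- m[[paste0(value, "_a")]]
  vb <- m[[paste0(value, "_b")]]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warn("replicate_concordance: zero variance, r undefined")
    r <- NaN
  } else {
    r <- cor(va, vb)
  }
  tibble(r = r, n_probes = nrow(m))
}
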