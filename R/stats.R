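#' Normalize per-oocyte amplitudes to a reference construct, batch-wise
#'
#' Divides every value by the mean value of the reference construct measured
#' in the same batch, so the reference mean maps to 1 within each batch and
#' constructs recorded in different batches remain comparable.
#'
#' @param values data frame with columns `construct`, `value` and optionally
#'   `batch` (a single batch is assumed when absent).
#' @param reference name of the reference construct; must be present (with at
#'   least one value) in every batch.
#' @return The input data frame with an added `normalized` column.
#' @examples
#' d <- data.frame(construct = c("wt", "wt", "mut"), value = c(2, 4, 1.8))
#' normalize_batch(d, "wt")$normalized   # 0.667 1.333 0.6
#' @export
normalize_batch <- function(values, reference) {
  stopifnot(is.data.frame(values), all(c("construct", "value") %in% names(values)))
  if (!"batch" %in% names(values)) values$batch <- 1L
  out <- lapply(split(values, values$batch), function(b) {
    ref <- b$value[b$construct == reference]
    if (length(ref) == 0)
      .kv_stop("kv_missing_reference",
               sprintf("reference construct '%s' absent from batch", reference))
    b$normalized <- b$value / mean(ref)
    b
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map a p-value to significance stars
#'
#' `"n.s."` for p >= 0.05, `"*"` for p < 0.05, `"**"` for p < 0.01,
#' `"***"` for p < 0.001.
#'
#' @param p p-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "n.s."
  }, character(1))
}

#' Group summary with optional two-group comparison
#'
#' Mean, standard error of the mean and n for one group; when a second group
#' is supplied, a Welch unequal-variance t-test p-value and the corresponding
#' significance stars are added.
#'
#' @param values numeric vector (first group).
#' @param comparison optional numeric vector (second group).
#' @return List with `mean`, `sem`, `n` and, with a comparison group,
#'   `mean2`, `sem2`, `n2`, `p_value`, `stars`.
#' @export
summarize_groups <- function(values, comparison = NULL) {
  if (length(values) < 2)
    .kv_stop("kv_insufficient_data", "need n >= 2 to compute a s.e.m.")
  out <- list(mean = mean(values),
              sem = stats::sd(values) / sqrt(length(values)),
              n = length(values))
  if (!is.null(comparison)) {
    if (length(comparison) < 2)
      .kv_stop("kv_insufficient_data", "comparison group needs n >= 2")
    p <- if (stats::sd(values) == 0 && stats::sd(comparison) == 0) {
      if (isTRUE(all.equal(mean(values), mean(comparison)))) 1 else 0
    } else {
      stats::t.test(values, comparison, var.equal = FALSE)$p.value
    }
    out$mean2 <- mean(comparison)
    out$sem2 <- stats::sd(comparison) / sqrt(length(comparison))
    out$n2 <- length(comparison)
    out$p_value <- p
    out$stars <- significance_stars(p)
  }
  out
}
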