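#' Median score over samples common to all datasets
#'
#' For the samples present in every dataset of a long score table, returns
#' the per-sample median of the raw HRDsum scores. These consensus medians
#' are the regression target of the per-dataset spline maps.
#'
#' @param scores Long tibble with columns `sample, dataset, hrdsum` (at most
#'   one row per sample/dataset pair).
#' @return Tibble `sample, median_hrdsum` covering exactly the common samples.
#' @export
consensus_medians <- function(scores) {
  check_score_matrix(scores)
  n_ds <- dplyr::n_distinct(scores$dataset)
  if (n_ds < 2) abort("need scores from at least 2 datasets")
  med <- scores %>%
    group_by(.data$sample) %>%
    summarise(n_datasets = n(), median_hrdsum = median(.data$hrdsum),
              .groups = "drop") %>%
    filter(.data$n_datasets == n_ds) %>%
    select("sample", "median_hrdsum")
  if (nrow(med) == 0) abort("no samples are present in all datasets")
  med
}

check_score_matrix <- function(scores) {
  req <- c("sample", "dataset", "hrdsum")
  miss <- setdiff(req, names(scores))
  if (length(miss) > 0)
    abort(paste0("score table is missing columns: ",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(scores[c("sample", "dataset")]))
    abort("more than one score for the same sample/dataset pair")
  if (any(scores$hrdsum < 0)) abort("raw HRDsum scores must be >= 0")
  invisible(scores)
}

#' Fit a natural-spline map from one dataset's raw scores to the consensus
#'
#' Least-squares fit of a natural cubic spline basis (intercept plus `df`
#' basis functions, interior knots at quantiles of the raw scores)
#' predicting the consensus median score from a dataset's raw score.
#' Natural splines are linear beyond the boundary knots, so scores outside
#' the fitted range are mapped by that linear extension.
#'
#' @param dataset_scores Tibble `sample, hrdsum` for one dataset.
#' @param medians Tibble `sample, median_hrdsum` from [consensus_medians()].
#' @param df Degrees of freedom of the natural-spline basis (default 4).
#' @return Object of class `spline_map` wrapping the fitted `lm`.
#' @export
fit_spline_map <- function(dataset_scores, medians, df = 4) {
  dat <- inner_join(dataset_scores, medians, by = "sample")
  if (nrow(dat) < df + 2)
    abort(paste0("only ", nrow(dat), " common samples; need at least ",
                 df + 2, " for a df=", df, " spline fit"))
  if (dplyr::n_distinct(dat$hrdsum) < 2)
    abort("raw scores are constant; spline map is degenerate")
  fit <- lm(median_hrdsum ~ splines::ns(hrdsum, df = df), data = dat)
  structure(list(fit = fit, df = df, n = nrow(dat),
                 range = range(dat$hrdsum)),
            class = "spline_map")
}

#' Evaluate a spline map at raw scores
#'
#' @param map A `spline_map`.
#' @param raw Numeric raw scores.
#' @param clamp Clamp predictions below at 0 (HRDsum is a count).
#' @return Numeric transformed scores.
#' @export
predict_spline_map <- function(map, raw, clamp = TRUE) {
  out <- unname(predict(map$fit, newdata = data.frame(hrdsum = raw)))
  if (clamp) out <- pmax(out, 0)
  out
}

#' @export
tidy.spline_map <- function(x, ...) {
  co <- coef(x$fit)
  tibble(term = names(co), estimate = unname(co))
}

#' @export
glance.spline_map <- function(x, ...) {
  tibble(df = x$df, n_common = x$n,
         sigma = summary(x$fit)$sigma,
         r.squared = summary(x$fit)$r.squared,
         raw_min = x$range[1], raw_max = x$range[2])
}

#' Harmonize HRDsum scores across datasets
#'
#' Implements the three-step merge of per-dataset HRDsum scores into one
#' summary score per sample: (1) the median raw score is computed for the
#' samples shared by all datasets; (2) for each dataset a natural-spline
#' regression is fitted predicting that median from the dataset's raw
#' scores; (3) every score is transformed by its dataset's map, clamped
#' below at 0, and samples present in more than one dataset receive the
#' mean of their transformed scores.
#'
#' @param scores Long tibble `sample, dataset, hrdsum`.
#' @param df Spline degrees of freedom (default 4).
#' @return Tibble `sample, summary_hrdsum, n_datasets` covering every sample
#'   present in at least one dataset. The fitted maps are attached as
#'   attribute `"maps"`.
#' @examples
#' sim <- simulate_multidataset(n = 50, seed = 1)
#' harmonize_scores(sim$scores)
#' @export
harmonize_scores <- function(scores, df = 4) {
  check_score_matrix(scores)
  med <- consensus_medians(scores)
  maps <- scores %>%
    split(.$dataset) %>%
    purrr::map(~fit_spline_map(select(.x, "sample", "hrdsum"), med, df = df))
  out <- scores %>%
    group_by(.data$dataset) %>%
    mutate(normalized = predict_spline_map(maps[[first(.data$dataset)]],
                                           .data$hrdsum)) %>%
    ungroup() %>%
    group_by(.data$sample) %>%
    summarise(summary_hrdsum = mean(.data$normalized),
              n_datasets = n(), .groups = "drop")
  attr(out, "maps") <- maps
  out
}
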