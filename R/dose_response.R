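#' Normalize plate absorbances to control wells
#'
#' Divides every well's absorbance by the mean absorbance of the control
#' (e.g. DMSO) wells, giving viability relative to control. Response
#' (inhibition) is `1 - viability`.
#'
#' @param plate Tibble with columns `absorbance` and logical `is_control`
#'   (other columns carried through).
#' @return Input tibble with added `viability` and `response` columns.
#' @export
normalize_plate <- function(plate) {
  ctrl <- plate$absorbance[plate$is_control]
  if (length(ctrl) == 0) abort("no control wells on plate")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0)
    abort("control-well mean must be positive")
  mutate(plate, viability = .data$absorbance / m,
         response = 1 - .data$viability)
}

# primary model: y = 1 - 1/(1 + 10^(10^b * (x - a))); midpoint y(a) = 0.5,
# IC50 = 10^a nmol/L. x is log10(concentration in nmol/L).
dr_primary <- function(x, a, b) 1 - 1 / (1 + 10^((10^b) * (x - a)))

# fallback model: y = 1/(1 + exp(-|b| * (x - a))); y(a) = 0.5, IC50 = a
# in the printed convention (10^a on the primary scale recorded for audit).
dr_fallback <- function(x, a, b) 1 / (1 + exp(-abs(b) * (x - a)))

fit_one_model <- function(x, y, fn, b_grid) {
  a_grid <- seq(min(x), max(x), length.out = 7)
  best <- NULL
  for (a0 in a_grid) for (b0 in b_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ fn(x, a, b), start = list(a = a0, b = b0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  best
}

#' Fit a dose-response curve and compute the IC50
#'
#' Fits the primary two-parameter model
#' `y = 1 - 1/(1 + 10^(10^b (x - a)))` by bounded least squares with a
#' deterministic multistart grid over the observed `x` range; `x` is the
#' log10 of the concentration in nmol/L and the IC50 is `10^a` nmol/L
#' (the curve satisfies `y(a) = 0.5` identically). If the primary
#' optimization fails, the fallback model `y = 1/(1 + exp(-|b|(x - a)))`
#' is fitted instead; its printed IC50 convention is the parameter `a`
#' itself, and `10^a` is recorded alongside for audit.
#'
#' @param points Tibble with columns `x` (log10 concentration, nmol/L) and
#'   `y` (normalized response: 0 none, 1 complete inhibition), e.g. the
#'   `response` column of [normalize_plate()]. At least 4 points spanning
#'   at least 2 distinct `x` values.
#' @param slope_power Interpret the printed primary slope term as `10^b`
#'   (default `TRUE`); set `FALSE` for slope `10 * b`.
#' @return Object of class `dr_fit` with elements `model`
#'   (`"primary"`/`"fallback"`), `a`, `b`, `ic50_nmolL`, `ic50_printed`,
#'   `max_response`, `converged`, `rss`, `points`.
#' @examples
#' sim <- simulate_dose_response(a = 2, b = 0, noise_sd = 0, seed = 1)
#' fit <- fit_dose_response(sim$points)
#' fit$ic50_nmolL
#' @export
fit_dose_response <- function(points, slope_power = TRUE) {
  x <- points$x; y <- points$y
  if (length(x) < 4 || dplyr::n_distinct(x) < 2)
    abort("need at least 4 points spanning at least 2 distinct x values")
  primary_fn <- if (slope_power) dr_primary
                else function(x, a, b) 1 - 1 / (1 + 10^((10 * b) * (x - a)))
  best <- fit_one_model(x, y, primary_fn, b_grid = c(-0.5, 0, 0.5))
  if (!is.null(best)) {
    co <- coef(best$fit)
    out <- list(model = "primary", a = unname(co["a"]), b = unname(co["b"]),
                ic50_nmolL = 10^unname(co["a"]),
                ic50_printed = 10^unname(co["a"]),
                max_response = max(y), converged = TRUE, rss = best$rss,
                points = points)
    return(structure(out, class = "dr_fit"))
  }
  best <- fit_one_model(x, y, dr_fallback, b_grid = c(0.5, 1, 3))
  if (!is.null(best)) {
    co <- coef(best$fit)
    out <- list(model = "fallback", a = unname(co["a"]),
                b = abs(unname(co["b"])),
                ic50_nmolL = 10^unname(co["a"]),
                ic50_printed = unname(co["a"]),
                max_response = max(y), converged = TRUE, rss = best$rss,
                points = points)
    return(structure(out, class = "dr_fit"))
  }
  structure(list(model = NA_character_, a = NA_real_, b = NA_real_,
                 ic50_nmolL = NA_real_, ic50_printed = NA_real_,
                 max_response = max(y), converged = FALSE, rss = NA_real_,
                 points = points),
            class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit> model:", x$model,
      " a:", signif(x$a, 4), " b:", signif(x$b, 4),
      " IC50:", signif(x$ic50_nmolL, 4), "nmol/L",
      " max response:", signif(x$max_response, 3),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @export
tidy.dr_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @export
glance.dr_fit <- function(x, ...) {
  tibble(model = x$model, ic50_nmolL = x$ic50_nmolL,
         ic50_printed = x$ic50_printed, max_response = x$max_response,
         converged = x$converged, rss = x$rss, n = nrow(x$points))
}

#' PARP-inhibitor sensitivity call from replicate fits
#'
#' A cell line is `"sensitive"` when at least 66% of replicate fits show an
#' IC50 strictly below 1 umol/L (1,000 nmol/L) together with a maximal
#' inhibitory response above 75%; `"insensitive"` when at least 66% show an
#' IC50 of at least 1 umol/L together with a maximal response below 35%;
#' anything else is `"excluded"`. Failed fits count toward the replicate
#' total but satisfy neither rule; with no successful fit the call is
#' `"excluded"` with a reason.
#'
#' @param fits List of `dr_fit` objects (replicates of one cell line/drug).
#' @param ic50_cut_nmolL IC50 boundary in nmol/L (default 1000).
#' @param sens_max_response Maximal-response lower bound for sensitivity
#'   (default 0.75, strict `>`).
#' @param insens_max_response Maximal-response upper bound for
#'   insensitivity (default 0.35, strict `<`).
#' @param vote Fraction of replicates required (default 0.66, `>=`).
#' @return Tibble `call, n_replicates, n_converged, frac_sensitive,
#'   frac_insensitive, reason`.
#' @export
classify_sensitivity <- function(fits, ic50_cut_nmolL = 1000,
                                 sens_max_response = 0.75,
                                 insens_max_response = 0.35, vote = 0.66) {
  n <- length(fits)
  if (n == 0) abort("no replicate fits supplied")
  conv <- purrr::map_lgl(fits, "converged")
  if (!any(conv))
    return(tibble(call = "excluded", n_replicates = n, n_converged = 0L,
                  frac_sensitive = NA_real_, frac_insensitive = NA_real_,
                  reason = "no successful fits"))
  ic50 <- purrr::map_dbl(fits, "ic50_nmolL")
  mr <- purrr::map_dbl(fits, "max_response")
  sens <- conv & ic50 < ic50_cut_nmolL & mr > sens_max_response
  insens <- conv & ic50 >= ic50_cut_nmolL & mr < insens_max_response
  fs <- sum(sens) / n; fi <- sum(insens) / n
  call <- if (fs >= vote) "sensitive"
          else if (fi >= vote) "insensitive"
          else "excluded"
  tibble(call = call, n_replicates = n, n_converged = sum(conv),
         frac_sensitive = fs, frac_insensitive = fi,
         reason = if (call == "excluded") "replicate vote not reached"
                  else NA_character_)
}
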