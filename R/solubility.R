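# The charge-based intracellular solubility predictor and the linear
# charge -> solubility model it was derived from.

#' The default charge-to-solubility model
#'
#' percent solubility = -4.6237 x net charge + 8.2469, with predictions
#' clamped to \[0, 100\] (clamping is applied after, never during,
#' fitting).
#'
#' @param slope percent per unit charge.
#' @param intercept percent at zero charge.
#' @param clamp clamp predictions into \[0, 100\].
#' @return an object of class `solubility_model`.
#' @export
solubility_model <- function(slope = -4.6237, intercept = 8.2469,
                             clamp = TRUE) {
  structure(list(slope = slope, intercept = intercept, clamp = clamp),
            class = "solubility_model")
}

#' @export
print.solubility_model <- function(x, ...) {
  cat(sprintf("percent solubility = %.4f x net charge + %.4f%s\n",
              x$slope, x$intercept,
              if (x$clamp) "  (clamped to [0,100])" else ""))
  invisible(x)
}

#' Predict percent solubility from net charge
#'
#' @param charge integer counting net charge (vectorised).
#' @param model a [solubility_model()].
#' @return predicted percent in \[0, 100\] when clamping is on.
#' @examples
#' predict_percent(0)   # 8.2469
#' predict_percent(-9)  # 49.86
#' @export
predict_percent <- function(charge, model = solubility_model()) {
  p <- model$slope * charge + model$intercept
  if (model$clamp) p <- pmin(100, pmax(0, p))
  p
}

#' High-solubility threshold (percent)
#'
#' High solubility is defined as strictly more than 70% partitioning in
#' the soluble mammalian cell fraction.
#' @export
HIGH_SOLUBILITY_PERCENT <- 70

#' Classify a prediction as high solubility or not
#'
#' Strict boundary: exactly 70% is not-high.
#'
#' @param percent predicted percent solubility (vectorised), or a
#'   `solubility_prediction`.
#' @return logical, TRUE when percent > 70.
#' @export
classify_high_solubility <- function(percent) {
  if (inherits(percent, "solubility_prediction")) percent <- percent$percent
  percent > HIGH_SOLUBILITY_PERCENT
}

#' Predict solubility for a sequence or construct
#'
#' In "asis" mode the charge is computed over the entire input
#' (including tags and linkers); in "fv" mode variable domains are
#' first isolated with [extract_fv()] and the charge computed on the
#' Fv portion only.
#'
#' @param x sequence string, [seq_record] or `scfv_construct`.
#' @param mode "asis" or "fv".
#' @param model a [solubility_model()].
#' @param config see [forge_config()].
#' @return a `solubility_prediction`: net_charge, percent,
#'   high_solubility.
#' @export
predict_for_sequence <- function(x, mode = c("asis", "fv"),
                                 model = solubility_model(),
                                 config = forge_config()) {
  mode <- match.arg(mode)
  seq <- if (inherits(x, "scfv_construct")) x$sequence else as_residues(x)
  charge <- if (mode == "asis") {
    net_charge(seq, config$residue_policy)
  } else {
    doms <- extract_fv(seq, config = config)
    sum(vapply(doms, function(d) net_charge(d$sequence), integer(1)))
  }
  pct <- predict_percent(charge, model)
  structure(list(net_charge = charge, percent = pct,
                 high_solubility = classify_high_solubility(pct)),
            class = "solubility_prediction")
}

#' @export
print.solubility_prediction <- function(x, ...) {
  cat(sprintf("net charge %+d -> %.2f%% soluble (%shigh solubility)\n",
              x$net_charge, x$percent, if (x$high_solubility) "" else "not "))
  invisible(x)
}

#' Fit the linear charge-to-solubility model
#'
#' Ordinary least squares of mean percent solubility on net charge.
#'
#' @param charge numeric vector of net charges (n >= 3, not constant).
#' @param percent matching percent-solubility values.
#' @return a `linear_model_fit`: slope, intercept, r_squared, n,
#'   residuals, and the model as a [solubility_model()] (unclamped).
#' @export
fit_linear <- function(charge, percent) {
  if (length(charge) != length(percent)) {
    stop("charge and percent must have equal length", call. = FALSE)
  }
  if (length(charge) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(charge) == 0) {
    stop("degenerate fit: net charge is constant", call. = FALSE)
  }
  fit <- stats::lm(percent ~ charge)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((percent - mean(percent))^2)
  structure(list(
    slope = unname(co["charge"]),
    intercept = unname(co["(Intercept)"]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = length(charge),
    residuals = unname(stats::residuals(fit)),
    model = solubility_model(unname(co["charge"]), unname(co["(Intercept)"]),
                             clamp = FALSE)
  ), class = "linear_model_fit")
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("fit (n = %d): percent = %.4f x charge + %.4f, R^2 = %.3f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
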