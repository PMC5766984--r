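#' Michaelis-Menten parameters with mixed/competitive inhibition
#'
#' @param k_cat turnover number, s^-1.
#' @param enzyme_conc enzyme concentration, uM (V_max = k_cat * enzyme_conc).
#' @param K_M Michaelis constant, mM.
#' @param K_ic competitive inhibition constant, uM.
#' @param K_iu uncompetitive inhibition constant, uM; `Inf` gives pure
#'   competitive inhibition.
#' @return An object of class `mm_params`.
#' @examples
#' mm_params(k_cat = 0.057, enzyme_conc = 0.12, K_M = 0.72, K_ic = 24)
#' @export
mm_params <- function(k_cat, enzyme_conc, K_M, K_ic = Inf, K_iu = Inf) {
  if (any(c(k_cat, enzyme_conc, K_M) <= 0) ||
      any(!is.finite(c(k_cat, enzyme_conc, K_M))))
    stop("k_cat, enzyme_conc and K_M must be finite and positive",
         call. = FALSE)
  if (K_ic <= 0 || K_iu <= 0)
    stop("inhibition constants must be positive (Inf allowed)", call. = FALSE)
  structure(list(k_cat = k_cat, enzyme_conc = enzyme_conc, K_M = K_M,
                 K_ic = K_ic, K_iu = K_iu),
            class = "mm_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf(
    "MM params: k_cat %.3g s^-1, [E] %.3g uM, K_M %.3g mM, K_ic %.3g uM, K_iu %s uM\n",
    x$k_cat, x$enzyme_conc, x$K_M, x$K_ic,
    if (is.infinite(x$K_iu)) "Inf" else sprintf("%.3g", x$K_iu)))
  invisible(x)
}

#' Reaction rate under mixed (or competitive) inhibition
#'
#' Evaluates `v = V_max * S / (K_M * (1 + I/K_ic) + S * (1 + I/K_iu))` with
#' `V_max = k_cat * enzyme_conc`. With `K_iu = Inf` this is the competitive
#' inhibition form; with `I = 0` it reduces to plain Michaelis-Menten.
#'
#' @param params an [mm_params()] object.
#' @param substrate substrate concentration(s), mM.
#' @param inhibitor inhibitor concentration(s), uM.
#' @return Rate(s), uM/s.
#' @examples
#' p <- mm_params(0.057, 0.12, 0.72, K_ic = 24)
#' mm_rate(p, substrate = 2, inhibitor = 100)
#' @export
mm_rate <- function(params, substrate, inhibitor = 0) {
  stopifnot(inherits(params, "mm_params"))
  if (any(substrate < 0) || any(inhibitor < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  vmax <- params$k_cat * params$enzyme_conc
  vmax * substrate /
    (params$K_M * (1 + inhibitor / params$K_ic) +
       substrate * (1 + inhibitor / params$K_iu))
}

#' Convert endpoint absorbance at 405 nm to a hydrolysis rate
#'
#' For p-nitrophenol released from a chromogenic substrate:
#' `rate = (a405 / (epsilon * path_cm)) * 1000 * dilution_factor /
#' incubation_s`, in uM/s (the factor 1000 converts the Beer-Lambert mM
#' concentration to uM).
#'
#' @param a405 measured absorbance at 405 nm.
#' @param epsilon molar extinction coefficient, mM^-1 cm^-1 (default 18.3
#'   for p-nitrophenolate after alkaline quench).
#' @param path_cm optical path length, cm.
#' @param incubation_s reaction time, s.
#' @param dilution_factor quench dilution (default 2: equal volume of
#'   carbonate added to the reaction).
#' @return Rate, uM/s.
#' @examples
#' absorbance_to_rate(0.183, incubation_s = 1800, dilution_factor = 1)
#' @export
absorbance_to_rate <- function(a405, epsilon = 18.3, path_cm = 1,
                               incubation_s, dilution_factor = 2) {
  if (any(a405 < 0)) stop("absorbance must be non-negative", call. = FALSE)
  if (epsilon <= 0 || path_cm <= 0 || dilution_factor <= 0)
    stop("epsilon, path_cm and dilution_factor must be positive",
         call. = FALSE)
  if (any(incubation_s <= 0))
    stop("incubation time must be positive", call. = FALSE)
  (a405 / (epsilon * path_cm)) * 1000 * dilution_factor / incubation_s
}

#' Construct a steady-state rate dataset
#'
#' @param substrate_mM substrate concentrations, mM.
#' @param inhibitor_uM inhibitor concentrations, uM.
#' @param rate_uM_per_s observed rates, uM/s.
#' @param enzyme_conc enzyme concentration, uM.
#' @param replicate optional replicate identifiers.
#' @return An object of class `rate_dataset` (a data frame with attribute
#'   `enzyme_conc`).
#' @export
rate_dataset <- function(substrate_mM, inhibitor_uM, rate_uM_per_s,
                         enzyme_conc, replicate = NULL) {
  if (any(substrate_mM <= 0)) stop("substrate must be > 0", call. = FALSE)
  if (any(inhibitor_uM < 0)) stop("inhibitor must be >= 0", call. = FALSE)
  if (any(rate_uM_per_s < 0)) stop("rates must be >= 0", call. = FALSE)
  d <- data.frame(substrate_mM = substrate_mM, inhibitor_uM = inhibitor_uM,
                  rate_uM_per_s = rate_uM_per_s)
  if (!is.null(replicate)) d$replicate <- replicate
  attr(d, "enzyme_conc") <- enzyme_conc
  class(d) <- c("rate_dataset", "data.frame")
  d
}

#' Hanes-Woolf transformation
#'
#' Returns S and S/v per inhibitor level together with the least-squares
#' line for each level. For plain Michaelis-Menten data the line has slope
#' `1/V_max` and intercept `K_M/V_max`; competitive inhibition inflates the
#' intercept by `(1 + I/K_ic)` while leaving the slope unchanged.
#'
#' @param data a [rate_dataset()].
#' @return A list with `table` (data frame `inhibitor_uM`, `substrate_mM`,
#'   `s_over_v`) and `lines` (per inhibitor level: `slope`, `intercept`).
#'   Records with zero rate are skipped with a warning.
#' @export
hanes_wolff <- function(data) {
  stopifnot(inherits(data, "rate_dataset"))
  zero <- data$rate_uM_per_s == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero rate skipped")
    data <- data[!zero, , drop = FALSE]
  }
  tab <- data.frame(inhibitor_uM = data$inhibitor_uM,
                    substrate_mM = data$substrate_mM,
                    s_over_v = data$substrate_mM / data$rate_uM_per_s)
  lines <- do.call(rbind, lapply(split(tab, tab$inhibitor_uM), function(d) {
    co <- stats::coef(stats::lm(s_over_v ~ substrate_mM, data = d))
    data.frame(inhibitor_uM = d$inhibitor_uM[1],
               intercept = co[[1]], slope = co[[2]])
  }))
  rownames(lines) <- NULL
  list(table = tab, lines = lines)
}

mm_resid <- function(logp, data, enzyme_conc, competitive) {
  p <- exp(logp)
  pars <- mm_params(k_cat = p[["k_cat"]], enzyme_conc = enzyme_conc,
                    K_M = p[["K_M"]],
                    K_ic = if ("K_ic" %in% names(p)) p[["K_ic"]] else Inf,
                    K_iu = if (competitive) Inf else p[["K_iu"]])
  vc <- mm_rate(pars, data$substrate_mM, data$inhibitor_uM)
  # statistical weighting: squared residual divided by the calculated rate
  (data$rate_uM_per_s - vc) / sqrt(pmax(vc, .Machine$double.eps))
}

#' Fit the mixed-inhibition model with weighted least squares
#'
#' Minimizes the statistically weighted objective
#' `sum((v_obs - v_calc)^2 / v_calc)` over `(k_cat, K_M, K_ic, K_iu)` on the
#' log scale, starting from Hanes-Woolf line estimates. The mixed model is
#' evaluated first; if the fitted uncompetitive constant exceeds ten times
#' the competitive one (more than an order of magnitude) the model is refit
#' as pure competitive and reported with `mode = "competitive"`.
#'
#' @param data a [rate_dataset()] containing at least six distinct substrate
#'   levels; inhibition constants are estimated only when both inhibitor-free
#'   and inhibitor-containing records are present.
#' @param selection_ratio threshold on `K_iu / K_ic` above which the pure
#'   competitive model is selected (default 10).
#' @return An object of class `inhibition_fit`: `params` ([mm_params()]),
#'   `mode` ("mixed", "competitive" or "none"), `weighted_ssr`, and
#'   `rmsd_percent` (100 * RMSD(v_obs, v_calc) / mean(v_obs), the
#'   experimental-error indicator).
#' @examples
#' truth <- mm_params(0.067, 0.12, 0.9, K_ic = 49)
#' d <- gen_mm_dataset(truth, noise_cv = 0, reps = 1, seed = 1)
#' fit_inhibition(d)
#' @export
fit_inhibition <- function(data, selection_ratio = 10) {
  stopifnot(inherits(data, "rate_dataset"))
  enzyme_conc <- attr(data, "enzyme_conc")
  if (length(unique(data$substrate_mM)) < 6)
    stop("need at least 6 distinct substrate levels", call. = FALSE)
  if (all(data$rate_uM_per_s == 0))
    stop("no signal: all rates are zero", call. = FALSE)
  has_inh <- any(data$inhibitor_uM > 0)
  if (has_inh && !any(data$inhibitor_uM == 0))
    stop("need an inhibitor-free series to anchor K_M", call. = FALSE)

  # deterministic start from the Hanes-Woolf line of the inhibitor-free data
  d0 <- data[data$inhibitor_uM == 0 & data$rate_uM_per_s > 0, , drop = FALSE]
  hw <- hanes_wolff(rate_dataset(d0$substrate_mM, d0$inhibitor_uM,
                                 d0$rate_uM_per_s, enzyme_conc))
  vmax0 <- 1 / hw$lines$slope[1]
  km0 <- hw$lines$intercept[1] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(data$rate_uM_per_s)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(data$substrate_mM)
  kcat0 <- vmax0 / enzyme_conc
  kic0 <- if (has_inh) mean(data$inhibitor_uM[data$inhibitor_uM > 0]) else NA

  run_fit <- function(start, competitive) {
    lb <- rep(log(1e-8), length(start)); ub <- rep(log(1e8), length(start))
    minpack.lm::nls.lm(par = log(start), lower = lb, upper = ub,
                       fn = mm_resid, data = data,
                       enzyme_conc = enzyme_conc, competitive = competitive,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  }

  if (!has_inh) {
    fit <- run_fit(c(k_cat = kcat0, K_M = km0), competitive = TRUE)
    est <- exp(fit$par)
    pars <- mm_params(est[["k_cat"]], enzyme_conc, est[["K_M"]])
    mode <- "none"
  } else {
    fit <- run_fit(c(k_cat = kcat0, K_M = km0, K_ic = kic0,
                     K_iu = 10 * kic0), competitive = FALSE)
    est <- exp(fit$par)
    if (est[["K_iu"]] > selection_ratio * est[["K_ic"]]) {
      fit <- run_fit(c(k_cat = est[["k_cat"]], K_M = est[["K_M"]],
                       K_ic = est[["K_ic"]]), competitive = TRUE)
      est <- exp(fit$par)
      pars <- mm_params(est[["k_cat"]], enzyme_conc, est[["K_M"]],
                        K_ic = est[["K_ic"]])
      mode <- "competitive"
    } else {
      pars <- mm_params(est[["k_cat"]], enzyme_conc, est[["K_M"]],
                        K_ic = est[["K_ic"]], K_iu = est[["K_iu"]])
      mode <- "mixed"
    }
  }
  vc <- mm_rate(pars, data$substrate_mM, data$inhibitor_uM)
  vo <- data$rate_uM_per_s
  structure(list(params = pars, mode = mode,
                 weighted_ssr = sum((vo - vc)^2 / pmax(vc, 1e-300)),
                 rmsd_percent = 100 * sqrt(mean((vo - vc)^2)) / mean(vo)),
            class = "inhibition_fit")
}

#' @export
print.inhibition_fit <- function(x, ...) {
  cat(sprintf("Inhibition fit (%s): weighted SSR %.4g, RMSD %.2f%%\n",
              x$mode, x$weighted_ssr, x$rmsd_percent))
  print(x$params)
  invisible(x)
}

#' Published pNP-lactoside kinetics for the three Cel7A catalytic domains
#'
#' Fitted Michaelis-Menten constants and competitive cellobiose inhibition
#' constants (pH 4.5, 30 C), with the enzyme concentrations used in the
#' assays, for use as generating values in recovery simulations.
#'
#' @return Data frame: `enzyme`, `k_cat` (s^-1), `K_M` (mM), `K_i` (uM),
#'   `enzyme_conc` (uM).
#' @examples
#' cel7_inhibition_table()
#' @export
cel7_inhibition_table <- function() {
  data.frame(
    enzyme = c("TreCel7A_CD", "TatCel7A_CD", "ThaCel7A_CD"),
    k_cat = c(0.057, 0.019, 0.067),
    K_M = c(0.72, 1.00, 0.90),
    K_i = c(24, 72, 49),
    enzyme_conc = c(0.12, 0.22, 0.12),
    stringsAsFactors = FALSE)
}

#' Substrate levels used in the chromogenic assays
#'
#' The ten p-nitrophenyl-beta-lactoside concentrations (mM) of the kinetic
#' series.
#' @return Numeric vector of length 10.
#' @export
pnp_lac_levels <- function() c(0.1, 0.2, 0.4, 0.67, 1.2, 2, 3, 4, 5, 6.7)
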