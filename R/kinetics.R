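# Quantitative qPCR/ChIP/RNA-IP conventions and first-order RNA decay
# fitting from transcription-shutoff (actinomycin D) time courses.

#' Delta-delta-Ct relative fold change
#'
#' `efficiency^-((ct_target_case - ct_ref_case) - (ct_target_control -
#' ct_ref_control))`: the fold change of the target in the case condition
#' relative to control, normalized to a reference transcript (e.g. GAPDH).
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   finite Ct values (cycles).
#' @param efficiency per-cycle amplification factor (> 1; default 2.0,
#'   perfect doubling).
#' @return Fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_control, ct_ref_control,
                             efficiency = 2.0) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("non-finite Ct value")
  if (efficiency <= 1) stop("efficiency must be > 1")
  ddct <- (ct_target_case - ct_ref_case) -
    (ct_target_control - ct_ref_control)
  efficiency^(-ddct)
}

#' Normalize a decay time course to a stable reference transcript
#'
#' `abundance(t) = (target(t)/reference(t)) / (target(0)/reference(0))`,
#' so the series starts at exactly 1.
#'
#' @param time_min strictly increasing times in minutes, starting at 0.
#' @param target,reference raw abundance series on the same timepoints
#'   (reference values > 0).
#' @return List of class `timecourse`: `time_min`, `abundance`.
#' @export
normalize_timecourse <- function(time_min, target, reference) {
  if (length(time_min) != length(target) ||
      length(time_min) != length(reference)) {
    stop("series must share timepoints")
  }
  if (time_min[[1]] != 0) stop("time course must start at t = 0")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  if (any(reference <= 0)) stop("zero or negative reference value")
  ratio <- target / reference
  structure(list(time_min = time_min, abundance = ratio / ratio[[1]]),
            class = "timecourse")
}

#' Fit first-order RNA decay to a normalized time course
#'
#' Least-squares fit of `ln(abundance) = -k * t` (no intercept: the series
#' is normalized to 1 at t = 0). The decay rate is clipped at zero (no
#' negative decay) and `half_life = ln(2) / k`. Series with
#' `k < stable_tol` are flagged stable.
#'
#' @param tc a `timecourse` from [normalize_timecourse()], or any list with
#'   `time_min` and `abundance` (>= 3 points, all abundances > 0).
#' @param stable_tol stability tolerance on k, per minute (default 1e-4:
#'   under 1% decay over a 72-h chase).
#' @return List of class `decay_fit`: `k` (per minute), `half_life`
#'   (minutes, Inf when stable), `r_squared`, `stable`.
#' @export
fit_first_order_decay <- function(tc, stable_tol = 1e-4) {
  t <- tc$time_min
  a <- tc$abundance
  if (length(t) < 3) stop("need >= 3 timepoints")
  if (any(a <= 0)) stop("non-positive abundance")
  y <- log(a)
  fit <- lm(y ~ 0 + t)
  k <- max(0, -unname(coef(fit)[[1]]))
  ss_res <- sum((y - (-k * t))^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res == 0)
  stable <- k < stable_tol
  structure(list(k = k, half_life = if (k > 0) log(2) / k else Inf,
                 r_squared = r2, stable = stable),
            class = "decay_fit")
}

#' ChIP enrichment
#'
#' `fold_over_control` mode returns `signal_ab / signal_control` (signal in
#' the antibody precipitate over a no-antibody control purification).
#' `percent_input` mode returns `100 * signal_ab / input_signal`, normalized
#' by the same quantity computed for the control purification when
#' `control_percent` is supplied.
#'
#' @param signal_ab antibody-precipitate signal.
#' @param signal_control no-antibody control signal (fold mode, > 0).
#' @param input_signal input chromatin signal (percent mode, > 0).
#' @param mode `"fold_over_control"` or `"percent_input"`.
#' @param control_percent percent-input of the control purification to
#'   normalize by (optional; percent mode).
#' @return Enrichment value.
#' @export
chip_enrichment <- function(signal_ab, signal_control = NULL,
                            input_signal = NULL,
                            mode = c("fold_over_control", "percent_input"),
                            control_percent = NULL) {
  mode <- match.arg(mode)
  if (mode == "fold_over_control") {
    if (is.null(signal_control) || any(signal_control <= 0)) {
      stop("fold_over_control mode needs signal_control > 0")
    }
    return(signal_ab / signal_control)
  }
  if (is.null(input_signal) || any(input_signal <= 0)) {
    stop("percent_input mode needs input_signal > 0")
  }
  pct <- 100 * signal_ab / input_signal
  if (!is.null(control_percent)) {
    if (any(control_percent <= 0)) stop("control_percent must be > 0")
    pct <- pct / control_percent
  }
  pct
}

#' RNA immunoprecipitation enrichment
#'
#' `[(ip_target/input_target) / (ip_ref/input_ref)]` divided by the same
#' double ratio computed for a control IP: the target's IP:input
#' enrichment relative to a control antibody, normalized to a reference
#' RNA (e.g. the SRP RNA).
#'
#' @param ip_target,input_target,ip_ref,input_ref signals for the specific
#'   IP (all > 0).
#' @param control_ip_target,control_input_target,control_ip_ref,control_input_ref
#'   signals for the control IP (all > 0).
#' @return Normalized enrichment.
#' @export
rip_enrichment <- function(ip_target, input_target, ip_ref, input_ref,
                           control_ip_target, control_input_target,
                           control_ip_ref, control_input_ref) {
  vals <- c(ip_target, input_target, ip_ref, input_ref, control_ip_target,
            control_input_target, control_ip_ref, control_input_ref)
  if (any(vals <= 0)) stop("all signals must be > 0")
  ((ip_target / input_target) / (ip_ref / input_ref)) /
    ((control_ip_target / control_input_target) /
       (control_ip_ref / control_input_ref))
}
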