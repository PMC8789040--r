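# 1:1 Langmuir SPR kinetics: closed-form sensorgram model, double
# referencing, global nonlinear least-squares fitting of (k_on, k_off,
# R_max) across all analyte concentrations and both phases, K_D = k_off/k_on,
# replicate aggregation and binding-selectivity matrices.

#' Closed-form 1:1 Langmuir association phase
#'
#' `R(t) = R_max * C k_on / (C k_on + k_off) * (1 - exp(-(C k_on + k_off) t))`.
#'
#' @param t time since injection start (s), >= 0.
#' @param conc analyte concentration C (M).
#' @param k_on association rate constant (1/(M s)).
#' @param k_off dissociation rate constant (1/s).
#' @param r_max surface capacity (RU).
#' @return response (RU).
#' @export
langmuir_association <- function(t, conc, k_on, k_off, r_max) {
  kobs <- conc * k_on + k_off
  r_max * conc * k_on / kobs * (1 - exp(-kobs * t))
}

#' Closed-form 1:1 Langmuir dissociation phase
#'
#' `R(t) = R0 * exp(-k_off (t - t0))` for t >= t0.
#'
#' @param t time (s).
#' @param r0 response at the start of dissociation (RU).
#' @param k_off dissociation rate constant (1/s).
#' @param t0 dissociation start time (s).
#' @return response (RU).
#' @export
langmuir_dissociation <- function(t, r0, k_off, t0 = 0) {
  r0 * exp(-k_off * (t - t0))
}

#' Simulate a multi-concentration sensorgram set
#'
#' Closed-form 1:1 curves plus Gaussian noise and linear baseline drift,
#' with a pre-injection baseline window used downstream for noise
#' estimation. Phase labels: "baseline" (t < 0), "association"
#' (0 <= t <= t_assoc), "dissociation" (t > t_assoc). Deterministic given
#' the seed.
#'
#' @param k_on,k_off,r_max generating 1:1 parameters.
#' @param concs analyte concentrations (M), > 0.
#' @param t_assoc association duration (s), e.g. 100 or 200.
#' @param t_dissoc dissociation duration (s), e.g. 420 or 1500.
#' @param dt sampling interval (s).
#' @param t_baseline pre-injection baseline duration (s).
#' @param noise_sd Gaussian noise sd (RU).
#' @param drift_slope linear baseline drift (RU/s).
#' @param seed optional seed.
#' @return data.frame of class `sensorgram_set`: time, response, conc, phase.
#' @export
simulate_sensorgrams <- function(k_on, k_off, r_max, concs, t_assoc = 100,
                                 t_dissoc = 420, dt = 1, t_baseline = 10,
                                 noise_sd = 0, drift_slope = 0, seed = NULL) {
  stopifnot(all(concs > 0), k_on > 0, k_off > 0, r_max > 0)
  run <- function() {
    out <- lapply(concs, function(C) {
      t <- seq(-t_baseline, t_assoc + t_dissoc, by = dt)
      phase <- ifelse(t < 0, "baseline",
               ifelse(t <= t_assoc, "association", "dissociation"))
      r <- numeric(length(t))
      ia <- phase == "association"
      id <- phase == "dissociation"
      r[ia] <- langmuir_association(t[ia], C, k_on, k_off, r_max)
      r0 <- langmuir_association(t_assoc, C, k_on, k_off, r_max)
      r[id] <- langmuir_dissociation(t[id], r0, k_off, t0 = t_assoc)
      r <- r + drift_slope * (t - min(t))
      if (noise_sd > 0) r <- r + stats::rnorm(length(t), 0, noise_sd)
      data.frame(time = t, response = r, conc = C, phase = phase,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    class(df) <- c("sensorgram_set", "data.frame")
    df
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Double referencing of sensorgrams
#'
#' `R_corr = (R_sample - R_reference) - (R_blank - R_blank_reference)`:
#' subtracts both the reference flow cell and a blank (buffer-only)
#' injection. All four sets must share the same time grid and curve layout.
#'
#' @param sample,reference_cell,blank_sample,blank_reference `sensorgram_set`s
#'   (or data.frames with time/response columns) on a common grid.
#' @return corrected `sensorgram_set` with the sample's metadata.
#' @export
double_reference <- function(sample, reference_cell, blank_sample,
                             blank_reference) {
  grids <- list(reference_cell, blank_sample, blank_reference)
  for (g in grids)
    if (nrow(g) != nrow(sample) || any(g$time != sample$time))
      stop("sensorgram grids do not match", call. = FALSE)
  out <- sample
  out$response <- (sample$response - reference_cell$response) -
    (blank_sample$response - blank_reference$response)
  out
}

#' K_D from rate constants
#'
#' `K_D = k_off / k_on`, the ratio of the dissociation and association rate
#' constants. Exact quotient; nonpositive rates are rejected.
#'
#' @param k_on association rate constant (1/(M s)), > 0.
#' @param k_off dissociation rate constant (1/s), > 0.
#' @return K_D (M).
#' @export
kd_from_rates <- function(k_on, k_off) {
  if (any(k_on <= 0) || any(k_off <= 0))
    stop("rate constants must be positive", call. = FALSE)
  k_off / k_on
}

# log-linear regression of the dissociation tail -> k_off estimate
.init_koff <- function(sg, t_assoc) {
  slopes <- c()
  for (C in unique(sg$conc)) {
    d <- sg[sg$conc == C & sg$phase == "dissociation" & sg$response > 0, ]
    if (nrow(d) < 5L) next
    keep <- d$response > max(d$response) * 1e-6
    if (sum(keep) < 5L) next
    fit <- stats::lm(log(response) ~ time, data = d[keep, ])
    slopes <- c(slopes, -stats::coef(fit)[["time"]])
  }
  if (length(slopes) == 0L) return(NA_real_)
  stats::median(slopes)
}

# k_obs-vs-concentration regression -> k_on estimate
.init_kon <- function(sg, t_assoc, koff0) {
  concs <- sort(unique(sg$conc))
  kobs <- rep(NA_real_, length(concs))
  for (i in seq_along(concs)) {
    a <- sg[sg$conc == concs[i] & sg$phase == "association", ]
    if (nrow(a) < 5L) next
    req <- max(a$response)
    if (req <= 0) next
    y <- 1 - a$response / (req * 1.0001)
    keep <- y > 1e-8 & a$time > 0
    if (sum(keep) < 3L) next
    fit <- stats::lm(log(y[keep]) ~ a$time[keep])
    kobs[i] <- -stats::coef(fit)[[2L]]
  }
  ok <- !is.na(kobs)
  if (sum(ok) >= 2L) {
    sl <- stats::coef(stats::lm(kobs[ok] ~ concs[ok]))[[2L]]
    if (is.finite(sl) && sl > 0) return(sl)
  }
  if (sum(ok) >= 1L && is.finite(koff0))
    return(max((kobs[ok][1L] - koff0) / concs[ok][1L], 1e3))
  1e6
}

#' Global 1:1 Langmuir fit of a sensorgram set
#'
#' Fits a single (k_on, k_off, R_max) jointly to all concentrations and
#' both phases by Levenberg-Marquardt least squares on log10-scale
#' parameters. Initialization: k_off from log-linear regression of the
#' dissociation tails, k_on from the slope of k_obs versus concentration.
#' Box bounds k_on in \[1e3, 1e10\] 1/(M s), k_off in \[1e-6, 1\] 1/s;
#' relative convergence tolerance 1e-10. The reported K_D is k_off/k_on of
#' the same fit (single source of truth). The no-binding flag is set when
#' the maximum corrected response is below max(3 x baseline noise SD, 1% of
#' fitted R_max); baseline noise is estimated from the pre-injection window
#' when present. Non-convergence is reported in the returned object, never
#' silently.
#'
#' @param sg a `sensorgram_set` over >= 3 concentrations (ideally spanning
#'   at least a decade around K_D), with association and dissociation phases.
#' @param r_max_init optional initial R_max (default: max response).
#' @return object of class `kinetic_fit`: k_on, k_off, r_max, k_d, se (named,
#'   log10-scale standard errors), rss, converged, no_binding, noise_sd,
#'   message.
#' @export
fit_kinetics <- function(sg, r_max_init = NULL) {
  stopifnot(all(c("time", "response", "conc", "phase") %in% names(sg)))
  concs <- sort(unique(sg$conc))
  if (length(concs) < 3L)
    warning("fewer than 3 analyte concentrations; global fit is weakly constrained")
  t_assoc <- max(sg$time[sg$phase == "association"])
  base <- sg$response[sg$phase == "baseline"]
  noise_sd <- if (length(base) >= 3L) stats::sd(base) else 0
  fitdat <- sg[sg$phase %in% c("association", "dissociation"), ]

  koff0 <- .init_koff(fitdat, t_assoc)
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- 1 / (2 * max(fitdat$time))
  koff0 <- min(max(koff0, 1e-6), 1)
  kon0 <- min(max(.init_kon(fitdat, t_assoc, koff0), 1e3), 1e10)
  rmax0 <- if (is.null(r_max_init)) {
    kd0 <- koff0 / kon0
    top <- max(fitdat$response, 1e-3)
    top / max(equilibrium_bound_fraction(kd0, max(concs)), 1e-3)
  } else r_max_init

  model <- function(kon, koff, rmax) {
    kobs <- fitdat$conc * kon + koff
    req <- rmax * fitdat$conc * kon / kobs
    ia <- fitdat$phase == "association"
    r <- numeric(nrow(fitdat))
    r[ia] <- req[ia] * (1 - exp(-kobs[ia] * fitdat$time[ia]))
    r0 <- req[!ia] * (1 - exp(-kobs[!ia] * t_assoc))
    r[!ia] <- r0 * exp(-koff * (fitdat$time[!ia] - t_assoc))
    r
  }
  resid_fn <- function(par) {
    p <- 10^par
    model(p[1L], p[2L], p[3L]) - fitdat$response
  }
  lower <- log10(c(1e3, 1e-6, rmax0 / 1e3))
  upper <- log10(c(1e10, 1, rmax0 * 1e3))
  # multi-start: the dissociation-tail k_off is reliable; k_on is scanned
  # over decades in case the k_obs regression lands in the wrong basin
  top <- max(fitdat$response, 1e-3)
  starts <- lapply(unique(c(kon0, 10^(4:9))), function(k0) {
    rm0 <- min(max(top / max(equilibrium_bound_fraction(koff0 / k0,
                                                        max(concs)), 1e-3),
                   rmax0 / 1e3), rmax0 * 1e3)
    pmin(pmax(log10(c(k0, koff0, rm0)), lower), upper)
  })
  fits <- lapply(starts, function(s)
    minpack.lm::nls.lm(
      par = s, fn = resid_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, maxiter = 500, maxfev = 5000)))
  fit <- fits[[which.min(vapply(fits, function(f) sum(f$fvec^2),
                                numeric(1L)))]]
  p <- 10^fit$par
  se <- tryCatch({
    s <- summary(fit)
    stats::setNames(s$coefficients[, "Std. Error"],
                    c("log10_k_on", "log10_k_off", "log10_r_max"))
  }, error = function(e) stats::setNames(rep(NA_real_, 3L),
                                         c("log10_k_on", "log10_k_off",
                                           "log10_r_max")))
  # signal estimate: plateau mean over the last quarter of each association
  # phase (robust to Gaussian noise tails, unlike a raw pointwise max)
  plateau <- vapply(concs, function(C) {
    a <- fitdat[fitdat$conc == C & fitdat$phase == "association", ]
    abs(mean(utils::tail(a$response, max(3L, nrow(a) %/% 4L))))
  }, numeric(1L))
  no_binding <- max(plateau) < max(3 * noise_sd, 0.01 * p[3L])
  structure(list(k_on = p[1L], k_off = p[2L], r_max = p[3L],
                 k_d = p[2L] / p[1L], se = se,
                 rss = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4,
                 no_binding = no_binding, noise_sd = noise_sd,
                 message = fit$message),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$no_binding) cat("N.B.: no binding detected\n")
  cat(sprintf("k_on  = %.3g 1/(M s)\nk_off = %.3g 1/s\nK_D   = %.3g M\n",
              x$k_on, x$k_off, x$k_d))
  cat(sprintf("R_max = %.3g RU; RSS = %.3g; converged: %s\n",
              x$r_max, x$rss, x$converged))
  invisible(x)
}

#' Aggregate replicate kinetic fits
#'
#' Per-parameter sample means and standard deviations over >= 2 independent
#' fits. K_D is aggregated as the mean of the per-replicate K_Ds — not the
#' ratio of the mean rates, which is a different number whenever replicates
#' vary. Mixed no-binding replicates are rejected.
#'
#' @param fits list of `kinetic_fit` objects (all converged, none flagged
#'   no-binding).
#' @return data.frame with one row per parameter (k_on, k_off, r_max, k_d):
#'   mean, sd, n.
#' @export
aggregate_replicates <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1L), "kinetic_fit")))
  nb <- vapply(fits, function(f) f$no_binding, logical(1L))
  if (any(nb))
    stop(sprintf("replicate set mixes binding and no-binding fits (%d of %d flagged N.B.)",
                 sum(nb), length(nb)), call. = FALSE)
  if (!all(vapply(fits, function(f) f$converged, logical(1L))))
    stop("all replicate fits must have converged", call. = FALSE)
  vals <- vapply(fits, function(f)
    c(k_on = f$k_on, k_off = f$k_off, r_max = f$r_max, k_d = f$k_d),
    numeric(4L))
  data.frame(parameter = rownames(vals),
             mean = apply(vals, 1L, mean),
             sd = apply(vals, 1L, stats::sd),
             n = length(fits), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Binding selectivity fold ratio
#'
#' Ratio of an off-target K_D to the cognate K_D, reported to 3 significant
#' figures (the convention for printed fold-selectivities).
#'
#' @param k_d_offtarget,k_d_cognate dissociation constants (M), > 0.
#' @return fold ratio (3 significant figures).
#' @export
selectivity <- function(k_d_offtarget, k_d_cognate) {
  stopifnot(all(k_d_offtarget > 0), all(k_d_cognate > 0))
  signif(k_d_offtarget / k_d_cognate, 3)
}

#' Selectivity matrix and orthogonal-pair proposals
#'
#' From a complete K_D table over RNA x protein pairs (NA = no binding
#' detected), computes per-RNA fold selectivities oriented off-target /
#' cognate (so entries are >= 1 when the cognate assignment is correct) and
#' proposes mutually orthogonal pairs: (RNA_i, P_i) and (RNA_j, P_j) are
#' orthogonal when both cross-selectivities meet `selectivity_min`.
#' No-binding entries are treated as selectivity bounded below by
#' `kd_nb_floor / K_D(cognate)` (the concentration-limit bound) and flagged
#' as censored.
#'
#' @param kd_table numeric matrix, rows = RNAs, cols = proteins; NA for
#'   no binding.
#' @param cognate named character vector mapping each RNA (row name) to its
#'   cognate protein (column name).
#' @param selectivity_min fold threshold for orthogonality (default 4000).
#' @param kd_nb_floor concentration-limit K_D bound substituted for
#'   no-binding entries (default 1e-6 M).
#' @return list: `selectivity` (matrix), `censored` (logical matrix),
#'   `pairs` (data.frame of RNA pairs with cross-selectivities and an
#'   `orthogonal` flag).
#' @export
orthogonality_matrix <- function(kd_table, cognate, selectivity_min = 4000,
                                 kd_nb_floor = 1e-6) {
  stopifnot(is.matrix(kd_table), !is.null(rownames(kd_table)),
            !is.null(colnames(kd_table)),
            all(names(cognate) %in% rownames(kd_table)),
            all(cognate %in% colnames(kd_table)))
  censored <- is.na(kd_table)
  kd <- kd_table
  kd[censored] <- kd_nb_floor
  sel <- kd
  for (r in rownames(kd))
    sel[r, ] <- signif(kd[r, ] / kd[r, cognate[r]], 3)
  rnas <- names(cognate)
  pairs <- list()
  if (length(rnas) >= 2L) {
    combs <- utils::combn(rnas, 2L)
    for (k in seq_len(ncol(combs))) {
      ri <- combs[1L, k]; rj <- combs[2L, k]
      pi_ <- cognate[ri]; pj <- cognate[rj]
      cross_i <- sel[ri, pj]
      cross_j <- sel[rj, pi_]
      pairs[[k]] <- data.frame(
        rna_a = ri, protein_a = unname(pi_), rna_b = rj,
        protein_b = unname(pj),
        cross_selectivity_a = cross_i, cross_selectivity_b = cross_j,
        censored = censored[ri, pj] || censored[rj, pi_],
        orthogonal = cross_i >= selectivity_min && cross_j >= selectivity_min,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs) > 0L) do.call(rbind, pairs)
           else data.frame()
  list(selectivity = sel, censored = censored, pairs = pairs)
}
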