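# Evaluation against known truth: one-to-one peak matching at a
# relative m/z tolerance, sensitivity / FDR / F1, and the two-peak
# model-comparison study.

#' Match detected peaks to a truth list at a relative m/z tolerance
#'
#' Greedy nearest-first one-to-one matching: every (detected, truth)
#' pair with `|d - t| / t <= rel_tol` is a candidate; candidates are
#' accepted in order of increasing relative distance (ties broken
#' toward the lower detected m/z) while both sides are still unmatched.
#'
#' @param detected numeric vector of detected summit m/z values.
#' @param truth numeric vector of true m/z values.
#' @param rel_tol relative tolerance (default 0.01, i.e. +/- 1%).
#' @return list with `matches` (two-column matrix of truth/detected
#'   indices), `n_tp`, `n_fp`, `n_fn`.
#' @export
match_peaks <- function(detected, truth, rel_tol = 0.01) {
  stopifnot(rel_tol > 0)
  cand <- expand.grid(ti = seq_along(truth), di = seq_along(detected))
  if (nrow(cand)) {
    cand$dist <- abs(detected[cand$di] - truth[cand$ti]) / abs(truth[cand$ti])
    cand <- cand[cand$dist <= rel_tol, , drop = FALSE]
    cand <- cand[order(cand$dist, detected[cand$di]), , drop = FALSE]
  }
  used_t <- logical(length(truth))
  used_d <- logical(length(detected))
  matches <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("truth", "detected")))
  for (i in seq_len(nrow(cand))) {
    ti <- cand$ti[i]; di <- cand$di[i]
    if (!used_t[ti] && !used_d[di]) {
      used_t[ti] <- TRUE
      used_d[di] <- TRUE
      matches <- rbind(matches, c(ti, di))
    }
  }
  n_tp <- nrow(matches)
  list(matches = matches, n_tp = n_tp,
       n_fp = length(detected) - n_tp,
       n_fn = length(truth) - n_tp)
}

#' Sensitivity and false discovery rate of a match result (percent)
#'
#' Sensitivity is the percentage of true peaks that were identified;
#' FDR is the percentage of identified peaks that match no true peak.
#' With no detections the FDR is 0 by convention.
#'
#' @param mr result of [match_peaks()].
#' @return percentage in `[0, 100]`.
#' @export
sensitivity <- function(mr) {
  total <- mr$n_tp + mr$n_fn
  if (total == 0L) stop("sensitivity undefined: empty truth", call. = FALSE)
  100 * mr$n_tp / total
}

#' @rdname sensitivity
#' @export
fdr <- function(mr) {
  total <- mr$n_tp + mr$n_fp
  if (total == 0L) return(0)
  100 * mr$n_fp / total
}

#' F1 score from sensitivity and FDR (fractional form)
#'
#' `F1 = 2 * (1 - FDR) * Sens / ((1 - FDR) + Sens)`, with the
#' convention that the score is 0 when both terms vanish.
#'
#' @param sens sensitivity as a fraction in `[0, 1]`.
#' @param fdr_frac FDR as a fraction in `[0, 1]`.
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(sens, fdr_frac) {
  if (sens < 0 || sens > 1 || fdr_frac < 0 || fdr_frac > 1)
    stop("sensitivity and FDR must be fractions in [0, 1]", call. = FALSE)
  precision <- 1 - fdr_frac
  if (precision + sens == 0) return(0)
  2 * precision * sens / (precision + sens)
}

#' Absolute percentage error of an estimate
#'
#' @param estimate estimated value(s).
#' @param truth true value(s), nonzero.
#' @return `100 * |estimate - truth| / |truth|`.
#' @export
percentage_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("truth must be nonzero", call. = FALSE)
  100 * abs(estimate - truth) / abs(truth)
}

# split a two-peak spectrum into its two components at the deepest
# point between the true summits (boundary point shared)
split_two_peak <- function(sp, alpha_a, alpha_b) {
  m <- sp$mz
  lo <- which.min(abs(m - alpha_a))
  hi <- which.min(abs(m - alpha_b))
  if (hi - lo >= 2L) {
    cut <- lo + which.min(sp$intensity[(lo + 1L):(hi - 1L)])
  } else cut <- lo
  list(a = seq_len(cut), b = cut:length(m))
}

#' Compare peak models on simulated two-component spectra
#'
#' For every design row (see [dataset1_grid()]) the spectrum is
#' simulated, split into its two components at the deepest sampled
#' point between the true summits, and each component is fitted with
#' every requested model using the same HPSO settings (so the
#' comparison is unbiased). Summit-location and area percentage errors
#' against the exact truth are aggregated as mean +/- standard error
#' per (model, asymmetry level).
#'
#' @param designs data frame from [dataset1_grid()].
#' @param models subset of `c("gaussian", "lorentz", "bigaussian",
#'   "mapv")`.
#' @param hpso list of [hpso_config()] overrides shared by all fits.
#' @return list with `per_fit` (one row per fitted component) and
#'   `summary` (mean/SEM of the percentage errors per model and mu
#'   level).
#' @export
run_model_comparison <- function(designs,
                                 models = c("gaussian", "lorentz",
                                            "bigaussian", "mapv"),
                                 hpso = list()) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- vector("list", nrow(designs) * length(models) * 2L)
  k <- 0L
  for (i in seq_len(nrow(designs))) {
    de <- designs[i, ]
    th_a <- de$theta_a[[1L]]
    th_b <- de$theta_b[[1L]]
    sim <- simulate_two_peak_spectrum(
      th_a, th_b, grid = c(de$grid_start, de$grid_stop, de$grid_by),
      noise_sd = de$noise_sd, seed = de$seed + 1L)
    idx <- split_two_peak(sim$spectrum, th_a[["alpha"]], th_b[["alpha"]])
    comps <- list(list(idx = idx$a, truth = th_a),
                  list(idx = idx$b, truth = th_b))
    for (ci in seq_along(comps)) {
      comp <- comps[[ci]]
      m <- sim$spectrum$mz[comp$idx]
      y <- sim$spectrum$intensity[comp$idx]
      if (max(y) <= 0) next
      for (mod in models) {
        fit_seed <- (de$seed + 4242L * ci + match(mod, models)) %%
          .Machine$integer.max
        fit <- fit_peak_model(m, y, mod,
                              modifyList(list(seed = fit_seed), hpso))
        alpha_hat <- fit$theta[["alpha"]]
        area_hat <- model_area(mod, fit$theta)
        k <- k + 1L
        rows[[k]] <- data.frame(
          setting = de$setting, rep = de$rep, component = ci,
          model = mod, mu = de$mu, sep = de$sep,
          noise_frac = de$noise_frac,
          summit_error = percentage_error(alpha_hat,
                                          comp$truth[["alpha"]]),
          area_error = percentage_error(area_hat, peak_area(comp$truth)))
      }
    }
  }
  per_fit <- do.call(rbind, rows[seq_len(k)])
  agg <- function(v, g) {
    mean_v <- tapply(v, g, mean)
    sem_v <- tapply(v, g, function(z) stats::sd(z) / sqrt(length(z)))
    list(mean = mean_v, sem = sem_v)
  }
  grp <- paste(per_fit$model, per_fit$mu, sep = "|")
  se <- agg(per_fit$summit_error, grp)
  ae <- agg(per_fit$area_error, grp)
  parts <- strsplit(names(se$mean), "|", fixed = TRUE)
  summary <- data.frame(
    model = vapply(parts, `[`, character(1), 1L),
    mu = as.numeric(vapply(parts, `[`, character(1), 2L)),
    summit_mpe = as.numeric(se$mean), summit_sem = as.numeric(se$sem),
    area_mpe = as.numeric(ae$mean), area_sem = as.numeric(ae$sem))
  summary <- summary[order(summary$mu, summary$model), ]
  rownames(summary) <- NULL
  list(per_fit = per_fit, summary = summary)
}
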