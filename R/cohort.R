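#' Cohort configuration
#'
#' Describes a multi-group study: per-group mean kinetic parameters,
#' between-subject standard deviations, group sizes, measurement noise and
#' per-group ex vivo alanine/lactate concentration distributions.
#'
#' @param groups Named list; each element a list with fields
#'   `mean` (a [kinetic_params()]), `sd` (named numeric vector of
#'   between-subject SDs for any of `k_pl_per_s`, `k_pa_per_s`,
#'   `r1p_eff_per_s`, `r1l_eff_per_s`, `r1a_eff_per_s`, `p0`; omitted
#'   parameters have SD 0), `n` (subjects, >= 1), and `ex_vivo` (list with
#'   `ala_mean`, `ala_sd`, `lac_mean`, `lac_sd`).
#' @param noise_sd Complex-noise SD relative to the first-transient
#'   pyruvate signal amplitude (`sin(theta) * p0`); the reciprocal of the
#'   nominal SNR.
#' @param seed Integer seed; the same `(config, seed)` pair reproduces the
#'   cohort exactly.
#' @return Object of class `cohort_config`.
#' @seealso [default_cohort_config()] for the three-group PanIN-progression
#'   layout.
#' @export
cohort_config <- function(groups, noise_sd = 0.01, seed = 20200525) {
  if (length(groups) < 1 || is.null(names(groups)))
    stop("groups must be a named list")
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (!inherits(gr$mean, "kinetic_params"))
      stop(sprintf("group '%s': mean must be kinetic_params", g))
    if (is.null(gr$n) || gr$n < 1)
      stop(sprintf("group '%s': n_subjects must be >= 1", g))
    if (!is.null(gr$sd) && any(gr$sd < 0))
      stop(sprintf("group '%s': SDs must be >= 0", g))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(groups = groups, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "cohort_config")
}

#' Default three-group cohort configuration
#'
#' Three groups of ten subjects emulating PanIN progression in the KC
#' mouse model: healthy controls at 20 weeks, KC mice with early lesions
#' at 20 weeks, and KC mice with advanced lesions at 30 weeks. Group mean
#' rate constants and their between-subject SDs are the published in vivo
#' values for this model (control kPA 0.0098 +/- 0.0005, kPL 0.0125 +/-
#' 0.0005; KC-20 0.0076 +/- 0.0006, 0.0224 +/- 0.0004; KC-30 0.0055 +/-
#' 0.0005, 0.0296 +/- 0.0004 /s). Effective relaxation assumes T1 about
#' 40 s (pyruvate) and 30 s (products). Ex vivo alanine/lactate relative
#' concentrations are chosen so the group-mean Ala/Lac ratio falls with
#' progression (about 0.89, 0.55, 0.29), the direction seen in tissue
#' extracts; no published concentration table exists, so magnitudes are
#' plausible rather than anchored.
#'
#' @param n_per_group Subjects per group (default 10).
#' @param noise_sd Relative dynamic-signal noise SD (default 0.01, i.e.
#'   nominal SNR 100 on the first pyruvate transient).
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
default_cohort_config <- function(n_per_group = 10, noise_sd = 0.01,
                                  seed = 20200525) {
  kp <- function(kpl, kpa) kinetic_params(k_pl_per_s = kpl, k_pa_per_s = kpa)
  sds <- function(kpl_sd, kpa_sd)
    c(k_pl_per_s = kpl_sd, k_pa_per_s = kpa_sd, p0 = 0.05)
  ev <- function(ala, lac)
    list(ala_mean = ala, ala_sd = 0.1 * ala, lac_mean = lac,
         lac_sd = 0.1 * lac)
  cohort_config(
    groups = list(
      control = list(mean = kp(0.0125, 0.0098), sd = sds(5e-4, 5e-4),
                     n = n_per_group, ex_vivo = ev(4.0, 4.5)),
      kc20 = list(mean = kp(0.0224, 0.0076), sd = sds(4e-4, 6e-4),
                  n = n_per_group, ex_vivo = ev(3.0, 5.5)),
      kc30 = list(mean = kp(0.0296, 0.0055), sd = sds(4e-4, 5e-4),
                  n = n_per_group, ex_vivo = ev(2.2, 7.5))),
    noise_sd = noise_sd, seed = seed)
}

# one draw per parameter from N(mean, sd) truncated at 0 (rejection);
# warns when half or more of the mass lies below 0.
.rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  if (stats::pnorm(0, mean, sd) >= 0.5)
    warning(sprintf(
      "truncation at 0 removes >50%% of draws (mean %.3g, sd %.3g)",
      mean, sd))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < 0)
  }
  out
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each subject's kinetic parameters from its group distribution
#' (independent Gaussians truncated at 0), runs the forward model to
#' produce the dynamic series, adds measurement noise (amplitude-domain by
#' default, or full per-transient FIDs), and synthesizes an ex vivo 1H
#' spectrum per subject. All ground truth is recorded in the returned
#' manifest; the same `(config, seed)` reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @param acq An [acq_params()].
#' @param fids If `TRUE`, also synthesize per-transient 13C FID arrays
#'   (slower; exercises the spectral pipeline). Noise then enters the FIDs
#'   rather than the amplitude series.
#' @return Object of class `cohort`: list with `subjects` (each having
#'   `id`, `group`, `truth` ([kinetic_params()]), `series`, optional
#'   `fids`, `h1_spectrum`, `ex_vivo_truth`) and `manifest` (config echo,
#'   seed, per-subject true parameters).
#' @export
generate_cohort <- function(config, acq = acq_params(), fids = FALSE) {
  stopifnot(inherits(config, "cohort_config"), inherits(acq, "acq_params"))
  set.seed(config$seed)
  theta <- deg2rad(acq$flip_deg)

  par_names <- c("k_pl_per_s", "k_pa_per_s", "r1p_eff_per_s",
                 "r1l_eff_per_s", "r1a_eff_per_s", "p0")
  subjects <- list()
  truth_rows <- list()
  sid <- 0
  for (g in names(config$groups)) {
    gr <- config$groups[[g]]
    for (j in seq_len(gr$n)) {
      sid <- sid + 1
      draw <- vapply(par_names, function(pn) {
        m <- gr$mean[[pn]]
        s <- if (!is.null(gr$sd) && pn %in% names(gr$sd)) gr$sd[[pn]] else 0
        .rtruncnorm0(1, m, s)
      }, 0)
      truth <- kinetic_params(draw["k_pl_per_s"], draw["k_pa_per_s"],
                              draw["r1p_eff_per_s"], draw["r1l_eff_per_s"],
                              draw["r1a_eff_per_s"], draw["p0"],
                              t0_s = gr$mean$t0_s)
      series <- forward_model(truth, acq)
      noise_abs <- config$noise_sd * truth$p0 * sin(theta)
      subj_fids <- NULL
      if (fids) {
        subj_fids <- synthesize_13c_fids(
          series, acq, noise_sd = noise_abs,
          phase0_deg = stats::runif(1, -60, 60))
        series <- extract_series(subj_fids, acq)
      } else if (noise_abs > 0) {
        for (ch in c("pyruvate", "lactate", "alanine"))
          series[[ch]] <- series[[ch]] +
            stats::rnorm(nrow(series), 0, noise_abs)
      }
      ev <- gr$ex_vivo
      if (is.null(ev)) {
        ala <- NA_real_; lac <- NA_real_; h1 <- NULL
      } else {
        ala <- .rtruncnorm0(1, ev$ala_mean, ev$ala_sd)
        lac <- .rtruncnorm0(1, ev$lac_mean, ev$lac_sd)
        h1 <- synthesize_1h_spectrum(ala, lac, noise_sd = config$noise_sd)
      }
      subjects[[sid]] <- list(
        id = sprintf("%s_%02d", g, j), group = g, truth = truth,
        series = series, fids = subj_fids, h1_spectrum = h1,
        ex_vivo_truth = list(ala = ala, lac = lac, ala_lac = ala / lac))
      truth_rows[[sid]] <- data.frame(
        subject = sprintf("%s_%02d", g, j), group = g,
        k_pl_per_s = truth$k_pl_per_s, k_pa_per_s = truth$k_pa_per_s,
        r1p_eff_per_s = truth$r1p_eff_per_s,
        r1l_eff_per_s = truth$r1l_eff_per_s,
        r1a_eff_per_s = truth$r1a_eff_per_s, p0 = truth$p0,
        ala_conc = ala, lac_conc = lac)
    }
  }
  manifest <- list(seed = config$seed, noise_sd = config$noise_sd,
                   n_subjects = sid,
                   groups = names(config$groups),
                   acq = unclass(acq),
                   truth = do.call(rbind, truth_rows))
  structure(list(subjects = subjects, manifest = manifest),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat(sprintf("Synthetic cohort: %d subjects in %d groups (%s); seed %d\n",
              length(x$subjects), length(tab),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              x$manifest$seed))
  invisible(x)
}

#' Write a cohort to a directory tree
#'
#' One directory per subject with `series.csv` (time_s, pyruvate, lactate,
#' alanine) and `h1_spectrum.csv` (ppm, intensity), plus a cohort-level
#' `manifest.json` holding the seed and all generating ground truth.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    utils::write.csv(as.data.frame(s$series),
                     file.path(sd, "series.csv"), row.names = FALSE)
    if (!is.null(s$h1_spectrum))
      utils::write.csv(data.frame(ppm = s$h1_spectrum$ppm,
                                  intensity = Re(s$h1_spectrum$intensity)),
                       file.path(sd, "h1_spectrum.csv"), row.names = FALSE)
  }
  man <- cohort$manifest
  man$truth <- as.list(man$truth)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A `cohort` (without FID arrays; `truth` entries are plain
#'   lists from the manifest).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  truth <- as.data.frame(man$truth)
  subjects <- lapply(seq_len(nrow(truth)), function(i) {
    sd <- file.path(dir, truth$subject[i])
    ser <- utils::read.csv(file.path(sd, "series.csv"))
    h1 <- utils::read.csv(file.path(sd, "h1_spectrum.csv"))
    list(id = truth$subject[i], group = truth$group[i],
         truth = as.list(truth[i, ]),
         series = as_metabolite_series(ser),
         fids = NULL,
         h1_spectrum = nmr_spectrum(h1$ppm, h1$intensity,
                                    referenced = "tmsp"),
         ex_vivo_truth = list(ala = truth$ala_conc[i],
                              lac = truth$lac_conc[i],
                              ala_lac = truth$ala_conc[i] /
                                truth$lac_conc[i]))
  })
  man$truth <- truth
  structure(list(subjects = subjects, manifest = man), class = "cohort")
}
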