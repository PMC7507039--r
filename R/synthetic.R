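# Seed hygiene: all generators take an explicit seed and restore the
# caller's RNG state on exit, so the same seed gives bit-identical output
# regardless of surrounding code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  # inverse-CDF truncated normal; exact, vectorised, no rejection loop
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Ground-truth record for the phantom regions
#'
#' One row per region label: the pre-contrast T1 and the extended Tofts
#' parameters the region's dynamic curve is generated from. The default
#' describes a three-region stroke-imaging scenario — an acute lesion
#' territory with a leaky blood-brain barrier, its contralateral mirror
#' territory, and normal-appearing background tissue — with Ktrans group
#' means matching the cohort reference values (see
#' [default_cohort_config()]).
#'
#' @param region_label Integer region labels (> 0).
#' @param t1_ms Pre-contrast T1 per region, ms.
#' @param ktrans Volume transfer constant per region, 1/min.
#' @param ve Extravascular-extracellular volume fraction.
#' @param vp Plasma volume fraction.
#' @param m0 Equilibrium signal per region (arbitrary units).
#' @return A validated data frame of class `phantom_truth`.
#' @export
phantom_truth <- function(region_label = c(1, 2, 3),
                          t1_ms = c(1200, 1200, 1000),
                          ktrans = c(0.098, 0.003, 0.007),
                          ve = c(0.2, 0.2, 0.2),
                          vp = c(0.02, 0.01, 0.01),
                          m0 = 1000) {
  d <- data.frame(region_label = as.integer(region_label), t1_ms = t1_ms,
                  ktrans = ktrans, ve = ve, vp = vp, m0 = m0)
  stopifnot(all(d$t1_ms > 0), all(d$ktrans >= 0),
            all(d$vp >= 0 & d$vp <= 1),
            all(d$ktrans == 0 | (d$ve > 0 & d$ve <= 1)),
            all(d$ve + d$vp <= 1), all(d$m0 > 0),
            !anyDuplicated(d$region_label), all(d$region_label > 0))
  class(d) <- c("phantom_truth", "data.frame")
  d
}

#' Generate a DCE-MRI phantom with known kinetic ground truth
#'
#' Builds the full forward model of the acquisition: per region, the VFA
#' series follows the SPGR closed form at the region's T1; the tissue
#' concentration follows the extended Tofts model driven by a plasma curve
#' (population AIF by default); concentration maps to signal through the
#' same SPGR form via `R1(t) = 1/T1 + r1 C(t)`. A sinus region carries the
#' whole-blood signal, i.e. the plasma curve scaled by `(1 - hematocrit)`
#' and relaxed at blood T1. Optional additive Gaussian noise on the
#' magnitude signal at a stated SNR (baseline tissue signal / noise SD) is
#' applied to both the VFA and the dynamic series.
#'
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @param protocol A [scan_protocol()].
#' @param truth A [phantom_truth()] covering every non-zero, non-sinus
#'   label in `labels`.
#' @param grid_shape Integer vector (nx, ny, nz) of the voxel grid.
#' @param labels Optional integer 3D array of region labels (0 =
#'   background, excluded). By default the grid is split into equal slabs
#'   along x, one per truth row, with the last y-column of the grid
#'   assigned to the sinus.
#' @param snr Signal-to-noise ratio (baseline signal / noise SD); `NULL`
#'   or `Inf` for noiseless.
#' @param aif_curve Plasma input as an [aif()] on the frame grid; default
#'   [population_aif()].
#' @param blood_t1_ms Pre-contrast blood T1, ms.
#' @param blood_m0 Blood equilibrium signal.
#' @return A list of class `dce_phantom`: `vfa` (4D, flip angle last),
#'   `dyn` (4D, time last), `times`, `labels`, `sinus_mask`, `truth`,
#'   `aif` (the generating plasma curve), `conc_truth` (region x frame
#'   matrix of true tissue concentrations), `protocol`, `snr`.
#' @export
generate_phantom <- function(seed,
                             protocol = scan_protocol(),
                             truth = phantom_truth(),
                             grid_shape = c(32, 32, 4),
                             labels = NULL,
                             snr = NULL,
                             aif_curve = NULL,
                             blood_t1_ms = 1650,
                             blood_m0 = 1000) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (!inherits(truth, "phantom_truth")) truth <- do.call(phantom_truth, truth)
  if (!is.null(snr) && is.finite(snr) && snr <= 0) stop("snr must be positive")
  tt <- frame_times(protocol)
  if (is.null(aif_curve)) aif_curve <- population_aif(tt)
  stopifnot(inherits(aif_curve, "aif"),
            isTRUE(all.equal(aif_curve$times, tt)))

  sinus_label <- max(truth$region_label) + 1L
  if (is.null(labels)) {
    labels <- array(0L, grid_shape)
    nreg <- nrow(truth)
    # equal slabs along x (remainder goes to the last region, so the
    # lesion and mirror regions match in size); last y-column is sinus
    sizes <- rep(grid_shape[1] %/% nreg, nreg)
    sizes[nreg] <- sizes[nreg] + grid_shape[1] %% nreg
    edges <- cumsum(c(0, sizes))
    for (r in seq_len(nreg))
      labels[(edges[r] + 1):edges[r + 1], , ] <- truth$region_label[r]
    if (grid_shape[2] >= 2) labels[, grid_shape[2], ] <- sinus_label
  } else {
    labels <- array(as.integer(labels), grid_shape)
    present <- setdiff(unique(as.vector(labels)), c(0L, sinus_label))
    missing <- setdiff(present, truth$region_label)
    if (length(missing))
      stop("labels present in mask but absent from truth: ",
           paste(missing, collapse = ", "))
  }
  sinus_mask <- labels == sinus_label

  nvox <- prod(grid_shape)
  nang <- length(protocol$flip_angles)
  nf <- protocol$n_dynamics
  lab_v <- as.vector(labels)

  # region-wise true tissue concentration curves
  conc_truth <- t(vapply(seq_len(nrow(truth)), function(r)
    tofts_forward(truth$ktrans[r], truth$ve[r], truth$vp[r], aif_curve),
    numeric(nf)))
  rownames(conc_truth) <- as.character(truth$region_label)
  cb <- aif_curve$cp * (1 - protocol$hematocrit)     # whole-blood conc

  vfa <- matrix(0, nvox, nang)
  dyn <- matrix(0, nvox, nf)
  for (r in seq_len(nrow(truth))) {
    sel <- lab_v == truth$region_label[r]
    if (!any(sel)) next
    vfa[sel, ] <- matrix(spgr_signal(truth$m0[r], truth$t1_ms[r],
                                     protocol$flip_angles, protocol$tr),
                         sum(sel), nang, byrow = TRUE)
    r1t <- 1000 / truth$t1_ms[r] + protocol$relaxivity_r1 * conc_truth[r, ]
    dyn[sel, ] <- matrix(spgr_signal(truth$m0[r], 1000 / r1t,
                                     protocol$flip_angle_dyn, protocol$tr),
                         sum(sel), nf, byrow = TRUE)
  }
  sel <- as.vector(sinus_mask)
  if (any(sel)) {
    vfa[sel, ] <- matrix(spgr_signal(blood_m0, blood_t1_ms,
                                     protocol$flip_angles, protocol$tr),
                         sum(sel), nang, byrow = TRUE)
    r1b <- 1000 / blood_t1_ms + protocol$relaxivity_r1 * cb
    dyn[sel, ] <- matrix(spgr_signal(blood_m0, 1000 / r1b,
                                     protocol$flip_angle_dyn, protocol$tr),
                         sum(sel), nf, byrow = TRUE)
  }

  if (!is.null(snr) && is.finite(snr)) {
    tissue <- lab_v != 0
    s0 <- mean(dyn[tissue, seq_len(protocol$n_baseline)])
    sd_noise <- s0 / snr
    with_seed(seed, {
      vfa <- vfa + stats::rnorm(length(vfa), 0, sd_noise)
      dyn <- dyn + stats::rnorm(length(dyn), 0, sd_noise)
    })
  }

  structure(list(vfa = array(vfa, c(grid_shape, nang)),
                 dyn = array(dyn, c(grid_shape, nf)),
                 times = tt, labels = labels, sinus_mask = sinus_mask,
                 truth = truth, aif = aif_curve, conc_truth = conc_truth,
                 protocol = protocol,
                 snr = if (is.null(snr)) Inf else snr,
                 seed = seed),
            class = "dce_phantom")
}

#' @export
print.dce_phantom <- function(x, ...) {
  cat(sprintf("DCE phantom: grid %s, %d regions + sinus, SNR %s, seed %d\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$truth),
              ifelse(is.finite(x$snr), format(x$snr), "Inf (noiseless)"),
              x$seed))
  invisible(x)
}

#' Generate annular vessel cross-sections with known areas
#'
#' Renders, for each requested (lumen area, vessel area) pair, a labelled
#' cross-section image: a disc of lumen pixels (label 1) surrounded by an
#' annulus of wall pixels (label 2) on background 0. Pixel membership is
#' chosen by ranking pixel-centre distances from a slightly jittered
#' centre, so the pixel-count areas match the requested areas to within
#' one pixel's area exactly (the rounding of area / spacing^2).
#'
#' @param seed Integer seed (controls the sub-pixel centre jitter).
#' @param spec Data frame (or list coercible to one) with columns `la`
#'   and `va` in mm^2, `va >= la >= 0`.
#' @param pixel_spacing Pixel edge length, mm.
#' @return A list of class `vessel_sections`: `images` (list of integer
#'   label matrices), `truth` (data frame `section`, `la`, `va`, `wa`,
#'   requested mm^2), `pixel_spacing`.
#' @export
generate_vessel_sections <- function(seed, spec, pixel_spacing = 0.1) {
  spec <- as.data.frame(spec)
  stopifnot(all(c("la", "va") %in% names(spec)),
            pixel_spacing > 0, all(spec$la >= 0))
  if (any(spec$va < spec$la))
    stop("vessel area must be >= lumen area")
  px_area <- pixel_spacing^2
  images <- vector("list", nrow(spec))
  with_seed(seed, {
    for (k in seq_len(nrow(spec))) {
      n_lumen <- round(spec$la[k] / px_area)
      n_vessel <- round(spec$va[k] / px_area)
      r_out <- sqrt(n_vessel / pi)
      n <- 2 * ceiling(r_out + 3) + 1
      cx <- (n + 1) / 2 + stats::runif(1, -0.45, 0.45)
      cy <- (n + 1) / 2 + stats::runif(1, -0.45, 0.45)
      d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
      ord <- order(d2)
      img <- matrix(0L, n, n)
      if (n_vessel > 0) img[ord[seq_len(n_vessel)]] <- 2L
      if (n_lumen > 0) img[ord[seq_len(n_lumen)]] <- 1L
      images[[k]] <- img
    }
  })
  truth <- data.frame(section = seq_len(nrow(spec)),
                      la = spec$la, va = spec$va, wa = spec$va - spec$la)
  structure(list(images = images, truth = truth,
                 pixel_spacing = pixel_spacing),
            class = "vessel_sections")
}

#' Reference cohort configuration
#'
#' The count-level structure and group-level summary statistics of the
#' 36-patient aetiology cohort the pipeline analyses: 23 CNS-vasculitis,
#' 10 atherosclerosis and 3 moyamoya patients; per-group risk-factor
#' counts; the vasculitis infarct-stage by stenosis-category cross-table;
#' and the Ktrans group means/SDs (1/min) for the lesion ROI, the mirror
#' ROI and the 6-month follow-up, by cerebrovascular-event group. These
#' numbers are the generator's defaults; [generate_cohort()] reproduces
#' every count exactly and draws continuous fields from truncated normals
#' at the stated mean/SD.
#'
#' @return A nested list; see source for structure.
#' @export
default_cohort_config <- function() {
  list(
    groups = c(vasculitis = 23L, atherosclerosis = 10L, moyamoya = 3L),
    sex_male = c(vasculitis = 16L, atherosclerosis = 6L, moyamoya = 2L),
    age = list(vasculitis = list(mean = 37.7, sd = 10.2, min = 16, max = 58),
               atherosclerosis = list(mean = 50.0, sd = 10.4, min = 33, max = 68),
               moyamoya = list(mean = 26.7, sd = 5.0, min = 21, max = 31)),
    age_cut = 55,
    # risk-factor counts per group (vasculitis, atherosclerosis, moyamoya)
    risk_flags = list(
      age_ge_55 = c(1L, 4L, 0L),
      smoking = c(15L, 2L, 1L),
      drinking = c(7L, 3L, 1L),
      hypertension = c(8L, 7L, 0L),
      diabetes = c(3L, 4L, 0L),
      hyperlipidemia = c(4L, 5L, 0L),
      heart_disease = c(0L, 0L, 0L),
      family_history_stroke = c(0L, 0L, 0L),
      infection_immune_positive = c(18L, 1L, 0L)),
    # vasculitis stage x stenosis cross-table, rows = (extent, severity)
    stage_stenosis = list(
      rows = data.frame(
        extent = c("focal", "focal", "segmental", "segmental",
                   "full_length", "full_length"),
        severity = c("mild", "moderate_severe", "moderate_severe",
                     "occlusion", "moderate_severe", "occlusion"),
        stringsAsFactors = FALSE),
      counts = matrix(c(2L, 0L, 0L,
                        0L, 1L, 2L,
                        2L, 2L, 4L,
                        2L, 0L, 0L,
                        1L, 0L, 1L,
                        3L, 0L, 3L), nrow = 6, byrow = TRUE,
                      dimnames = list(NULL, c("acute_subacute", "chronic",
                                              "none")))),
    # Ktrans (1/min) by vasculitis event group: lesion, mirror, follow-up
    ktrans = list(
      acute_subacute = list(lesion = c(0.098, 0.038),
                            mirror = c(0.003, 0.001),
                            followup = c(0.039, 0.014), n_followup = 10L),
      chronic = list(lesion = c(0.044, 0.012),
                     mirror = c(0.003, 0.001),
                     followup = c(0.018, 0.009), n_followup = 2L),
      none = list(lesion = c(0.007, 0.001),
                  mirror = c(0.003, 0.001),
                  followup = c(0.006, 0.001), n_followup = 4L),
      other_groups = list(lesion = c(0.007, 0.002),
                          mirror = c(0.003, 0.001))))
}

#' Generate the synthetic patient cohort
#'
#' Builds a patient-level table whose categorical structure matches the
#' configured counts exactly (not probabilistically): group sizes, sex and
#' risk-flag counts per group, and the vasculitis infarct-stage by
#' stenosis-degree/extent cross-table. Continuous fields (age, Ktrans
#' lesion / mirror / follow-up) are drawn from truncated normal
#' distributions at the configured group means and SDs; ages are drawn
#' consistently with each patient's `age_ge_55` flag. Which patients carry
#' which flags is randomised by the seed; the marginal counts never
#' change.
#'
#' @param seed Integer seed.
#' @param config Configuration list; see [default_cohort_config()].
#' @return A data frame of class `cohort_table`, one row per patient.
#' @examples
#' ch <- generate_cohort(1)
#' table(ch$aetiology)
#' @export
generate_cohort <- function(seed, config = default_cohort_config()) {
  cfg <- config
  gsizes <- cfg$groups
  for (fl in names(cfg$risk_flags))
    if (any(cfg$risk_flags[[fl]] > gsizes))
      stop("flag counts exceed group size for ", fl)
  if (any(cfg$sex_male > gsizes)) stop("male counts exceed group size")

  with_seed(seed, {
    rows <- list()
    pid <- 0L
    for (g in names(gsizes)) {
      n <- gsizes[[g]]
      gi <- match(g, names(gsizes))
      flags <- lapply(cfg$risk_flags, function(cnt)
        sample(rep(c(TRUE, FALSE), c(cnt[gi], n - cnt[gi]))))
      sex <- sample(rep(c("male", "female"),
                        c(cfg$sex_male[[g]], n - cfg$sex_male[[g]])))
      ap <- cfg$age[[g]]
      ge55 <- flags$age_ge_55
      age <- numeric(n)
      cut <- cfg$age_cut
      age[ge55] <- rtruncnorm1(sum(ge55), ap$mean, ap$sd,
                               lower = max(cut, ap$min), upper = ap$max)
      age[!ge55] <- rtruncnorm1(sum(!ge55), ap$mean, ap$sd,
                                lower = ap$min, upper = min(cut, ap$max))

      if (g == "vasculitis") {
        ss <- cfg$stage_stenosis
        stage <- extent <- severity <- character(0)
        for (r in seq_len(nrow(ss$rows)))
          for (s in colnames(ss$counts)) {
            k <- ss$counts[r, s]
            if (k > 0) {
              stage <- c(stage, rep(s, k))
              extent <- c(extent, rep(ss$rows$extent[r], k))
              severity <- c(severity, rep(ss$rows$severity[r], k))
            }
          }
        stopifnot(length(stage) == n)
        perm <- sample(n)
        stage <- stage[perm]; extent <- extent[perm]
        severity <- severity[perm]
      } else {
        stage <- rep("none", n)
        extent <- rep("segmental", n)
        severity <- rep("moderate_severe", n)
      }

      kt_l <- kt_m <- kt_f <- numeric(n)
      kt_f[] <- NA_real_
      if (g == "vasculitis") {
        for (s in unique(stage)) {
          kp <- cfg$ktrans[[s]]
          sel <- which(stage == s)
          kt_l[sel] <- rtruncnorm1(length(sel), kp$lesion[1], kp$lesion[2],
                                   lower = 0)
          kt_m[sel] <- rtruncnorm1(length(sel), kp$mirror[1], kp$mirror[2],
                                   lower = 0)
          nf <- min(kp$n_followup, length(sel))
          fu <- sel[sample.int(length(sel), nf)]
          kt_f[fu] <- rtruncnorm1(nf, kp$followup[1], kp$followup[2],
                                  lower = 0)
        }
      } else {
        kp <- cfg$ktrans$other_groups
        kt_l <- rtruncnorm1(n, kp$lesion[1], kp$lesion[2], lower = 0)
        kt_m <- rtruncnorm1(n, kp$mirror[1], kp$mirror[2], lower = 0)
      }

      d <- data.frame(patient_id = sprintf("P%03d", pid + seq_len(n)),
                      aetiology = g, sex = sex, age = age,
                      infarct_stage = stage, stenosis_grade = severity,
                      lesion_extent = extent,
                      ktrans_lesion = kt_l, ktrans_mirror = kt_m,
                      ktrans_followup = kt_f,
                      stringsAsFactors = FALSE)
      for (fl in names(flags)) d[[fl]] <- flags[[fl]]
      pid <- pid + n
      rows[[g]] <- d
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
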