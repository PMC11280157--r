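#' Thoracic phantom specification
#'
#' Parameters of the synthetic axial-chest phantom: a fat-density body
#' ellipse containing two lung ellipses, a vertebral body and a rib ring
#' (bone), with three muscle compartments drawn as the pipeline expects
#' them — two ventral pectoralis bodies, two dorsal paraspinal erector
#' spinae bodies, and thin lateral intercostal arcs just inside the ribs.
#' All muscle HU values lie inside the (-250, 150) muscle/fat window so
#' the windowed input channels are informative. Per-subject size jitter,
#' an age-related decline and a sex effect drive true volume variation,
#' and synthetic PFT values are a monotone (affine) function of total
#' muscle volume with configurable noise on the volume scale.
#'
#' @param image_size (rows, cols) of each slice; default 64x64 so that a
#'   small network trains on CPU in minutes.
#' @param n_slices slices per volume.
#' @param pixel_spacing_mm,slice_thickness_mm voxel geometry.
#' @param muscle_hu_range admissible (lo, hi) for muscle compartments.
#' @param class_hu generating HU per class (pectoralis, erector spinae,
#'   intercostal); each must lie inside `muscle_hu_range`.
#' @param fat_hu,lung_hu,bone_hu context compartment HU.
#' @param noise_sd_hu SD of additive Gaussian HU noise (muscle voxels are
#'   kept inside the muscle/fat window after noising).
#' @param geometry_scale per-class multiplicative size factors.
#' @param pft_coupling list: `rho_target` (Spearman rho between each PFT
#'   parameter and total muscle volume, used by [generate_cohort] to
#'   calibrate the noise) and `noise_sd` (SD of the volume-scale noise in
#'   cc; overrides `rho_target` when non-NULL; 0 = deterministic link).
#' @param p_male probability a subject is male.
#' @param rng_seed default seed used when none is passed explicitly.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = c(64L, 64L), n_slices = 12L,
                         pixel_spacing_mm = c(0.7, 0.7),
                         slice_thickness_mm = 3,
                         muscle_hu_range = c(30, 50),
                         class_hu = c(pectoralis = 48, erector_spinae = 46,
                                      intercostal = 31),
                         fat_hu = -100, lung_hu = -800, bone_hu = 700,
                         noise_sd_hu = 8,
                         geometry_scale = c(pectoralis = 1,
                                            erector_spinae = 1,
                                            intercostal = 1),
                         pft_coupling = list(rho_target = 0.8,
                                             noise_sd = NULL),
                         p_male = 0.7, rng_seed = 1L) {
  if (any(class_hu < muscle_hu_range[1]) || any(class_hu > muscle_hu_range[2]))
    stop("class_hu values must lie inside muscle_hu_range")
  if (muscle_hu_range[1] <= -250 || muscle_hu_range[2] >= 150)
    stop("muscle_hu_range must lie strictly inside the (-250, 150) window")
  structure(list(image_size = as.integer(image_size),
                 n_slices = as.integer(n_slices),
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 muscle_hu_range = muscle_hu_range, class_hu = class_hu,
                 fat_hu = fat_hu, lung_hu = lung_hu, bone_hu = bone_hu,
                 noise_sd_hu = noise_sd_hu, geometry_scale = geometry_scale,
                 pft_coupling = pft_coupling, p_male = p_male,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# affine PFT links: value = intercept + slope * (V_total + volume noise)
.PFT_LINKS <- list(
  FVC = c(1.2, 0.22), IC = c(0.8, 0.10), VC = c(1.3, 0.23),
  FEV1 = c(0.9, 0.18), TLC = c(3.0, 0.25), FEV6 = c(1.1, 0.21),
  DLCO = c(8.0, 1.20))

# one axial slice layout; `s` is the subject muscle-size factor and
# `fs` the slice-level body taper. Returns HU matrix and class label matrix.
.phantom_slice <- function(H, W, s, fs, spec) {
  u <- matrix(rep(seq(-1, 1, length.out = H), W), H, W)           # row axis
  v <- matrix(rep(seq(-1, 1, length.out = W), each = H), H, W)    # col axis
  au <- 0.85 * fs
  av <- 0.92 * fs
  re2 <- (u / au)^2 + (v / av)^2
  hu <- matrix(-1000, H, W)
  hu[re2 <= 1] <- spec$fat_hu
  lung <- (((u + 0.05) / (0.45 * fs))^2 + ((abs(v) - 0.42 * fs) / (0.30 * fs))^2) <= 1
  hu[lung] <- spec$lung_hu
  rib <- re2 >= 0.90^2 & re2 <= 0.96^2
  hu[rib] <- spec$bone_hu
  vert <- ((u - 0.50 * fs)^2 + v^2) <= (0.10 * fs)^2
  hu[vert] <- spec$bone_hu

  gs <- spec$geometry_scale
  sp <- s * gs[["pectoralis"]]
  se <- s * gs[["erector_spinae"]]
  si <- s * gs[["intercostal"]]
  pect <- (((u + 0.55 * fs) / (0.12 * sp))^2 +
           ((abs(v) - 0.28 * fs) / (0.18 * sp))^2) <= 1
  esp <- (((u - 0.52 * fs) / (0.14 * se))^2 +
          ((abs(v) - 0.30 * fs) / (0.15 * se))^2) <= 1
  phi <- atan2(abs(v), -u)              # 0 = ventral, pi = dorsal
  band <- 0.030 * si
  ic <- re2 >= (0.84 - band)^2 & re2 <= (0.84 + band)^2 &
    phi > 50 * pi / 180 & phi < 130 * pi / 180
  lab <- matrix(0L, H, W)
  lab[ic] <- 3L
  lab[esp] <- 2L
  lab[pect] <- 1L
  hu[lab == 1L] <- spec$class_hu[["pectoralis"]]
  hu[lab == 2L] <- spec$class_hu[["erector_spinae"]]
  hu[lab == 3L] <- spec$class_hu[["intercostal"]]
  list(hu = hu, lab = lab,
       overlap = sum((pect & esp) | (pect & ic & !esp) | (esp & ic)))
}

#' Generate one phantom subject
#'
#' Builds the CT volume, the exact generating multi-class mask, subject
#' metadata (sex, age, CT date) and a synthetic PFT record monotonically
#' coupled to total muscle volume. Muscle size shrinks with age and is
#' larger for males; a log-normal jitter adds individual variation. If a
#' drawn geometry would overlap two classes it is regenerated with
#' perturbed size (bounded retries).
#'
#' @param spec a [phantom_spec].
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier (default derived from the seed).
#' @param pft_noise_sd SD (cc) of the volume-scale noise entering the PFT
#'   link; defaults to `spec$pft_coupling$noise_sd` or 0.
#' @return list with `ct` ([ct_volume]), `mask` (multiclass
#'   [muscle_mask]), `meta` (list: subject_id, sex, age_years, ct_date,
#'   size_factor) and `pft` (one-row data frame).
#' @export
generate_subject <- function(spec, subject_seed,
                             subject_id = sprintf("P%06d", subject_seed),
                             pft_noise_sd = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(pft_noise_sd))
    pft_noise_sd <- if (!is.null(spec$pft_coupling$noise_sd))
      spec$pft_coupling$noise_sd else 0
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(subject_seed %% 2147483647L)

  H <- spec$image_size[1]
  W <- spec$image_size[2]
  ns <- spec$n_slices
  sex <- if (runif(1) < spec$p_male) "M" else "F"
  age <- runif(1, 40, 80)
  base <- if (sex == "M") 1.15 else 0.90
  s <- base * (1 - 0.006 * (age - 40)) * exp(rnorm(1, 0, 0.08))
  s <- min(max(s, 0.60), 1.35)

  vox <- array(0, c(ns, H, W))
  lab <- array(0L, c(ns, H, W))
  mid <- (ns + 1) / 2
  for (sl in seq_len(ns)) {
    fs <- 1 - 0.12 * ((sl - mid) / mid)^2
    attempt <- 0L
    repeat {
      ph <- .phantom_slice(H, W, s * (1 - 0.02 * attempt), fs, spec)
      if (ph$overlap == 0L) break
      attempt <- attempt + 1L
      if (attempt > 5L)
        stop("phantom geometry produced overlapping muscle classes after ",
             "5 perturbed retries")
    }
    vox[sl, , ] <- ph$hu
    lab[sl, , ] <- ph$lab
  }
  if (spec$noise_sd_hu > 0) {
    vox <- vox + rnorm(length(vox), 0, spec$noise_sd_hu)
    # keep muscle voxels inside the muscle/fat window the pipeline assumes
    msel <- lab != 0L
    vox[msel] <- pmin(pmax(vox[msel], -249), 149)
  }
  ct_date <- as.Date("2022-01-01") + sample.int(365L, 1L) - 1L
  ct <- ct_volume(vox, spec$pixel_spacing_mm, spec$slice_thickness_mm,
                  subject_id = subject_id, acquisition_date = ct_date)
  mask <- muscle_mask(lab, "multiclass", spec$pixel_spacing_mm,
                      spec$slice_thickness_mm)
  vtot <- muscle_volume_cc(mask$voxels != 0L, spec$pixel_spacing_mm,
                           spec$slice_thickness_mm)
  vnoisy <- vtot + if (pft_noise_sd > 0) rnorm(1, 0, pft_noise_sd) else 0
  pft <- data.frame(subject_id = subject_id,
                    test_date = ct_date + sample(-75:75, 1L))
  for (p in names(.PFT_LINKS))
    pft[[p]] <- .PFT_LINKS[[p]][1] + .PFT_LINKS[[p]][2] * vnoisy
  list(ct = ct, mask = mask,
       meta = list(subject_id = subject_id, sex = sex, age_years = age,
                   ct_date = ct_date, size_factor = s,
                   true_volume_cc = vtot),
       pft = pft)
}

#' Generate a phantom cohort
#'
#' Generates `n_subjects` phantoms reproducibly under `seed`. When
#' `spec$pft_coupling$noise_sd` is NULL the volume-scale PFT noise is
#' calibrated from the realized cohort volume spread so that the Spearman
#' correlation between each PFT parameter and total muscle volume targets
#' `rho_target`, via the bivariate-normal relation
#' `r = 2 sin(pi * rho / 6)` and `noise_sd = sd(V) * sqrt(1/r^2 - 1)`.
#' With `dir` set, writes `ct_<id>.nii.gz`, `mask_<id>.nii.gz`,
#' `subjects.csv` and `pft.csv` (the layout the training and analysis
#' entry points consume); otherwise returns everything in memory.
#'
#' @param spec a [phantom_spec].
#' @param n_subjects cohort size (>= 1).
#' @param seed integer master seed; per-subject seeds are folded from it.
#' @param dir optional output directory.
#' @return invisibly (with `dir`) or visibly (in memory): list with
#'   `subjects` (list of [generate_subject] results), `subjects_df`,
#'   `pft_df` and `pft_noise_sd`.
#' @export
generate_cohort <- function(spec, n_subjects, seed = spec$rng_seed,
                            dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    subjects[[i]] <- generate_subject(spec, sseed,
                                      subject_id = sprintf("P%04d", i),
                                      pft_noise_sd = 0)
  }
  vols <- vapply(subjects, function(s) s$meta$true_volume_cc, 0)
  noise_sd <- spec$pft_coupling$noise_sd
  if (is.null(noise_sd)) {
    rho <- spec$pft_coupling$rho_target
    r <- 2 * sin(pi * rho / 6)
    noise_sd <- sd(vols) * sqrt(1 / r^2 - 1)
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed((as.integer(seed) + 104729L) %% 2147483647L)
  eta <- if (noise_sd > 0) rnorm(n_subjects, 0, noise_sd) else numeric(n_subjects)
  pft_df <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    row <- subjects[[i]]$pft
    vn <- vols[i] + eta[i]
    for (p in names(.PFT_LINKS))
      row[[p]] <- .PFT_LINKS[[p]][1] + .PFT_LINKS[[p]][2] * vn
    row
  }))
  subjects_df <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$meta$subject_id, sex = s$meta$sex,
               age_years = s$meta$age_years,
               ct_date = as.character(s$meta$ct_date),
               true_volume_cc = s$meta$true_volume_cc)))
  for (i in seq_len(n_subjects)) subjects[[i]]$pft <- pft_df[i, , drop = FALSE]
  out <- list(subjects = subjects, subjects_df = subjects_df,
              pft_df = pft_df, pft_noise_sd = noise_sd)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      write_ct(s$ct, file.path(dir, paste0("ct_", s$meta$subject_id,
                                           ".nii.gz")))
      write_mask(s$mask, file.path(dir, paste0("mask_", s$meta$subject_id,
                                               ".nii.gz")))
    }
    write.csv(subjects_df, file.path(dir, "subjects.csv"), row.names = FALSE)
    pd <- pft_df
    pd$test_date <- as.character(pd$test_date)
    write.csv(pd, file.path(dir, "pft.csv"), row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Load a phantom cohort directory
#'
#' Reads the `ct_*.nii.gz` / `mask_*.nii.gz` / `subjects.csv` / `pft.csv`
#' layout written by [generate_cohort].
#'
#' @param dir cohort directory.
#' @return list with `subjects` (subject_id, ct, mask each), `subjects_df`
#'   and `pft_df`.
#' @export
load_cohort <- function(dir) {
  sdf <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  pft <- read_pft(file.path(dir, "pft.csv"))
  subjects <- lapply(seq_len(nrow(sdf)), function(i) {
    id <- sdf$subject_id[i]
    ct <- read_ct(file.path(dir, paste0("ct_", id, ".nii.gz")),
                  subject_id = id, acquisition_date = sdf$ct_date[i])
    mask <- read_mask(file.path(dir, paste0("mask_", id, ".nii.gz")),
                      mode = "multiclass")
    list(subject_id = id, ct = ct, mask = mask, sex = sdf$sex[i],
         age_years = sdf$age_years[i], ct_date = as.Date(sdf$ct_date[i]))
  })
  list(subjects = subjects, subjects_df = sdf, pft_df = pft)
}
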