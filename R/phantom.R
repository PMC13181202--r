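#' Specification for a synthetic CT nodule phantom study
#'
#' Defines the conditions under which CT-like phantom volumes are generated:
#' an air-dominated background near -900 HU with additive Gaussian noise and
#' one embedded nodule per volume. Benign nodules are small, smooth, low
#' contrast ellipsoids; malignant nodules are larger, brighter, and carry
#' radial spicules (line segments of random direction, the margin
#' irregularity radiologists weight). Classes are therefore separable by
#' size, contrast, and boundary shape - the three cues a volumetric
#' classifier is expected to learn.
#'
#' @param n_benign,n_malignant case counts.
#' @param volume_shape `(D, H, W)` voxel grid (default 64^3; large enough
#'   that 32^3 patch extraction is exercised identically to full CT).
#' @param noise_sigma additive Gaussian noise, HU (default 40).
#' @param background background intensity, HU (default -900).
#' @param contrast_benign,contrast_malignant nodule contrast over background,
#'   HU (defaults 200 / 400).
#' @param radius_benign,radius_malignant per-class semi-axis ranges, mm.
#' @param spike_count_malignant spicules per malignant nodule (default 8).
#' @param spike_length spicule length range, mm (default 2-5).
#' @param spacing voxel spacing `(z, y, x)` mm (default 1 mm isotropic).
#' @param rng_seed base seed; every case is deterministic in
#'   `(rng_seed, class, index)`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_benign = 20L, n_malignant = 20L,
                         volume_shape = c(64L, 64L, 64L),
                         noise_sigma = 40, background = -900,
                         contrast_benign = 200, contrast_malignant = 400,
                         radius_benign = c(2, 4), radius_malignant = c(5, 8),
                         spike_count_malignant = 8L, spike_length = c(2, 5),
                         spacing = c(1, 1, 1), rng_seed = 1L) {
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  margin <- max(radius_malignant) + max(spike_length) + 2
  if (2 * margin >= min(volume_shape * spacing))
    stop("nodule radii/spicules cannot fit inside volume_shape", call. = FALSE)
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 volume_shape = as.integer(volume_shape),
                 noise_sigma = noise_sigma, background = background,
                 contrast_benign = contrast_benign,
                 contrast_malignant = contrast_malignant,
                 radius_benign = radius_benign,
                 radius_malignant = radius_malignant,
                 spike_count_malignant = as.integer(spike_count_malignant),
                 spike_length = spike_length, spacing = as.numeric(spacing),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

.case_seed <- function(spec, class, index) {
  malig <- as.integer(class == "malignant")
  as.integer((as.numeric(spec$rng_seed) * 7919 + index * 131 +
                malig * 65537) %% 2147483629)
}

#' Generate one phantom case
#'
#' @param spec a [phantom_spec()].
#' @param class `"benign"` or `"malignant"`.
#' @param index case index (part of the deterministic seed).
#' @return list with `volume` (a [ct_volume()]), `annotation` (one-row
#'   annotation data.frame in the LUNA16 dialect plus a `ratings` list
#'   column), `mask` (logical ground-truth nodule mask), and `class`.
#' @export
phantom_case <- function(spec, class = c("benign", "malignant"), index = 1L) {
  class <- match.arg(class)
  d <- spec$volume_shape
  sp <- spec$spacing
  with_seed(.case_seed(spec, class, index), {
    vox <- array(stats::rnorm(prod(d), spec$background, spec$noise_sigma), d)
    rr <- if (class == "benign") spec$radius_benign else spec$radius_malignant
    contrast <- if (class == "benign") spec$contrast_benign else spec$contrast_malignant
    margin <- max(rr) + max(spec$spike_length) + 2
    ctr <- vapply(1:3, function(a)
      runif(1, margin / sp[a] + 1, d[a] - margin / sp[a]), numeric(1))
    semi <- runif(3, rr[1], rr[2])                    # mm, per axis
    zz <- ((seq_len(d[1]) - ctr[1]) * sp[1]) / semi[1]
    yy <- ((seq_len(d[2]) - ctr[2]) * sp[2]) / semi[2]
    xx <- ((seq_len(d[3]) - ctr[3]) * sp[3]) / semi[3]
    r2 <- outer(outer(zz^2, yy^2, `+`), xx^2, `+`)
    mask <- r2 <= 1
    if (class == "malignant" && spec$spike_count_malignant > 0) {
      for (s in seq_len(spec$spike_count_malignant)) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        r_dir <- 1 / sqrt(sum((dir / semi)^2))        # ellipsoid radius along dir
        len <- runif(1, spec$spike_length[1], spec$spike_length[2])
        ts <- seq(0, len, by = 0.5)
        for (t in ts) {
          p <- ctr + dir * (r_dir + t) / sp           # voxel coords
          iz <- round(p[1]); iy <- round(p[2]); ix <- round(p[3])
          for (oz in -1:1) for (oy in -1:1) for (ox in -1:1) {
            z <- iz + oz; y <- iy + oy; x <- ix + ox
            if (z >= 1 && z <= d[1] && y >= 1 && y <= d[2] &&
                x >= 1 && x <= d[3] &&
                (oz^2 + oy^2 + ox^2) <= 1)
              mask[z, y, x] <- TRUE
          }
        }
      }
    }
    vox[mask] <- vox[mask] + contrast
    ratings <- if (class == "malignant") sample(4:5, 3L, replace = TRUE)
               else sample(1:2, 3L, replace = TRUE)
    uid <- sprintf("phantom-%s-%03d", class, index)
    vol <- ct_volume(vox, spacing = sp, origin = c(0, 0, 0), series_uid = uid)
    ann <- data.frame(seriesuid = uid,
                      coordX = (ctr[3] - 1) * sp[3],
                      coordY = (ctr[2] - 1) * sp[2],
                      coordZ = (ctr[1] - 1) * sp[1],
                      diameter_mm = 2 * mean(semi),
                      ratings = I(list(as.integer(ratings))),
                      stringsAsFactors = FALSE)
    list(volume = vol, annotation = ann, mask = mask, class = class)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes one `.mhd`/`.raw` pair per case plus a LUNA16-dialect
#' `annotations.csv` (with a semicolon-separated `ratings` column) and a
#' `manifest.csv` listing every file with its true class.
#'
#' @param spec a [phantom_spec()].
#' @param out_dir writable output directory (created if absent).
#' @return the manifest data.frame, invisibly; columns `file, seriesuid,
#'   class`.
#' @export
phantom_dataset <- function(spec, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  anns <- list(); manifest <- list()
  cases <- rbind(
    data.frame(class = rep("benign", spec$n_benign),
               index = seq_len(spec$n_benign)),
    data.frame(class = rep("malignant", spec$n_malignant),
               index = seq_len(spec$n_malignant)))
  for (i in seq_len(nrow(cases))) {
    cs <- phantom_case(spec, cases$class[i], cases$index[i])
    f <- file.path(out_dir, paste0(cs$volume$series_uid, ".mhd"))
    write_mhd(cs$volume, f, element_type = "MET_SHORT")
    a <- cs$annotation
    a$ratings <- vapply(a$ratings, paste, character(1), collapse = ";")
    anns[[i]] <- a
    manifest[[i]] <- data.frame(file = basename(f),
                                seriesuid = cs$volume$series_uid,
                                class = cs$class, stringsAsFactors = FALSE)
  }
  ann_df <- do.call(rbind, anns)
  write.csv(ann_df, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  man_df <- do.call(rbind, manifest)
  write.csv(man_df, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man_df)
}
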