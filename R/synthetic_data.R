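# Synthetic image generator with planted, ground-truth shortcuts.
#
# Emulates the structure of ROI-annotated medical image datasets (chest
# radiographs with lung masks; eye fundus photographs with optic-disc masks):
# a plausible ROI per image, a disease signal strictly inside the ROI of
# positives, and configurable shortcut signals outside the ROI (or confounded
# with ROI size), plus label-correlated tabular metadata. Because the
# shortcuts are planted, the downstream audit can be validated against ground
# truth.

#' Shortcut specification
#'
#' Describes one planted spurious signal. `correlation` is the probability
#' that shortcut presence matches the image label: 1 means the shortcut is a
#' perfect label proxy, 0.5 means it is independent of the label. Shortcut
#' pixels never intersect the ROI mask; `global_offset` therefore shifts all
#' non-ROI pixels.
#'
#' @param kind One of `"token"` (small bright rounded rectangle with a
#'   lead-like line, emulating a pacemaker), `"border_text"` (high-contrast
#'   glyph band in a corner strip, emulating burnt-in camera text), or
#'   `"global_offset"` (intensity offset of all non-ROI pixels).
#' @param correlation Probability in \[0, 1\] that presence matches the label.
#' @param placement `"outside_roi"` or `"image_border"`; defaults depend on
#'   `kind`.
#' @param amplitude Additive intensity of the shortcut on the \[0, 1\] scale.
#' @return Object of class `shortcut_spec`.
#' @export
shortcut_spec <- function(kind = c("token", "border_text", "global_offset"),
                          correlation = 0.9,
                          placement = NULL,
                          amplitude = 0.5) {
  kind <- match.arg(kind)
  if (!is.numeric(correlation) || correlation < 0 || correlation > 1) {
    stopf("`correlation` must lie in [0, 1]")
  }
  if (is.null(placement)) {
    placement <- if (kind == "border_text") "image_border" else "outside_roi"
  }
  placement <- match.arg(placement, c("outside_roi", "image_border"))
  structure(list(kind = kind, correlation = correlation,
                 placement = placement, amplitude = amplitude),
            class = "shortcut_spec")
}

#' Synthetic dataset configuration
#'
#' @param n_images Number of images.
#' @param image_size Pixels per side (>= 32); 128 is a convenient working
#'   size, 512 mirrors full-resolution runs.
#' @param prevalence Fraction of positive labels in \[0, 1\]; the positive
#'   count is exactly `round(n_images * prevalence)` (stratified, not
#'   sampled).
#' @param roi_shape `"two_lungs"` (two vertically elongated ellipses with a
#'   central gap) or `"disc"` (one filled circle at a jittered position).
#' @param disease_amplitude In-ROI disease signal strength in units of
#'   `noise_sd`: a localised texture change (extra high-frequency energy
#'   under a Gaussian window at a random in-ROI location) plus a mild
#'   intensity bump. 0 means no disease signal.
#' @param shortcut_specs List of [shortcut_spec()] objects (possibly empty).
#' @param roi_size_label_slope Relative ROI radius increase for positives
#'   (the ROI-size confound); 0 disables it.
#' @param roi_size_jitter SD of the per-image multiplicative ROI size jitter
#'   (anatomical variability; makes ROI size an imperfect label proxy even
#'   at high slope).
#' @param metadata_auc Target discriminability of the generated tabular
#'   metadata in \[0.5, 1\]; 0.5 yields label-independent metadata.
#' @param noise_sd Standard deviation of additive pixel noise on \[0, 1\].
#' @param low_quality_frac Fraction of records whose `mask_quality` is drawn
#'   below 0.7 (so quality filtering has something to remove).
#' @param class_name Name of the single disease class.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 600L,
                             image_size = 128L,
                             prevalence = 0.35,
                             roi_shape = c("two_lungs", "disc"),
                             disease_amplitude = 2.5,
                             shortcut_specs = list(),
                             roi_size_label_slope = 0,
                             roi_size_jitter = 0.08,
                             metadata_auc = 0.5,
                             noise_sd = 0.08,
                             low_quality_frac = 0.1,
                             class_name = "disease",
                             seed = 1L) {
  roi_shape <- match.arg(roi_shape)
  if (prevalence < 0 || prevalence > 1) stopf("`prevalence` must lie in [0, 1]")
  if (image_size < 32) stopf("`image_size` must be >= 32")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  if (metadata_auc < 0.5 || metadata_auc > 1) stopf("`metadata_auc` must lie in [0.5, 1]")
  if (length(shortcut_specs) && !all(vapply(shortcut_specs, inherits, logical(1), "shortcut_spec"))) {
    stopf("`shortcut_specs` must be a list of shortcut_spec objects")
  }
  structure(list(
    n_images = as.integer(n_images), image_size = as.integer(image_size),
    prevalence = prevalence, roi_shape = roi_shape,
    disease_amplitude = disease_amplitude, shortcut_specs = shortcut_specs,
    roi_size_label_slope = roi_size_label_slope,
    roi_size_jitter = roi_size_jitter, metadata_auc = metadata_auc,
    noise_sd = noise_sd, low_quality_frac = low_quality_frac,
    class_name = class_name, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# ---- geometry ---------------------------------------------------------------

roi_mask_two_lungs <- function(S, scale, jitter) {
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  cy <- 0.52 * S + jitter[1]
  a <- 0.29 * S * scale   # row semi-axis
  b <- 0.135 * S * scale  # col semi-axis
  left  <- ((rr - cy) / a)^2 + ((cc - (0.33 * S + jitter[2])) / b)^2 <= 1
  right <- ((rr - cy) / a)^2 + ((cc - (0.67 * S + jitter[3])) / b)^2 <= 1
  (left | right) * 1L
}

roi_mask_disc <- function(S, scale, center) {
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  r <- 0.12 * S * scale
  (((rr - center[1])^2 + (cc - center[2])^2) <= r^2) * 1L
}

body_ellipse <- function(S) {
  rr <- matrix(seq_len(S), S, S)
  cc <- matrix(seq_len(S), S, S, byrow = TRUE)
  (((rr - 0.5 * S) / (0.46 * S))^2 + ((cc - 0.5 * S) / (0.42 * S))^2 <= 1) * 1L
}

# Footprint of a pacemaker-like token (rounded rectangle + lead line),
# anchored at top-left (r0, c0). Returns an index matrix of pixels.
token_footprint <- function(S, r0, c0) {
  th <- max(4L, round(0.075 * S)); tw <- max(3L, round(0.055 * S))
  rows <- r0:(r0 + th - 1L); cols <- c0:(c0 + tw - 1L)
  px <- expand.grid(r = rows, c = cols)
  # trim the four corner pixels for a rounded look
  corner <- (px$r %in% range(rows)) & (px$c %in% range(cols))
  px <- px[!corner, ]
  lead_len <- round(0.08 * S)
  lead <- data.frame(r = (r0 + th):(r0 + th + lead_len - 1L),
                     c = c0 + tw %/% 2L)
  px <- rbind(px, lead)
  px[px$r >= 1 & px$r <= S & px$c >= 1 & px$c <= S, ]
}

# Corner strips (top-right, top-left, bottom-right, bottom-left) for text.
border_strips <- function(S) {
  h0 <- max(2L, round(0.03 * S)); h1 <- round(0.085 * S)
  w0 <- round(0.55 * S); w1 <- round(0.95 * S)
  list(
    list(rows = h0:h1, cols = w0:w1),
    list(rows = h0:h1, cols = (S - w1):(S - w0)),
    list(rows = (S - h1):(S - h0), cols = w0:w1),
    list(rows = (S - h1):(S - h0), cols = (S - w1):(S - w0))
  )
}

# Render one shortcut into `image`; returns the modified image.
# Errors if no admissible placement exists (ROI covers the placement zone).
render_shortcut <- function(image, mask, spec) {
  S <- nrow(image)
  if (spec$kind == "global_offset") {
    return(image + spec$amplitude * (mask == 0L))
  }
  if (spec$kind == "token") {
    for (try in seq_len(200L)) {
      r0 <- sample.int(S - round(0.2 * S), 1L) + round(0.02 * S)
      c0 <- sample.int(S - round(0.1 * S), 1L)
      px <- token_footprint(S, r0, c0)
      idx <- cbind(px$r, px$c)
      if (all(mask[idx] == 0L)) {
        image[idx] <- clip01(image[idx] + spec$amplitude)
        return(image)
      }
    }
    stopf("shortcut placement impossible for spec kind 'token': ROI covers the placement zone")
  }
  # border_text: blocky glyphs in a corner strip that avoids the ROI
  strips <- border_strips(S)
  ord <- sample.int(length(strips))
  for (k in ord) {
    st <- strips[[k]]
    if (all(mask[st$rows, st$cols] == 0L)) {
      glyph <- matrix(rbinom(length(st$rows) * length(st$cols), 1L, 0.45),
                      length(st$rows), length(st$cols))
      # widen glyph blocks horizontally for a text-like look
      glyph <- glyph | cbind(glyph[, -1], 0L)
      image[st$rows, st$cols] <- clip01(image[st$rows, st$cols] + spec$amplitude * glyph)
      return(image)
    }
  }
  stopf("shortcut placement impossible for spec kind 'border_text': ROI covers all corner strips")
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic ROI dataset with planted shortcuts
#'
#' Produces `config$n_images` grayscale images with binary ROI masks, binary
#' labels (exactly `round(n * prevalence)` positives), stratified fold
#' assignments (K = 5), tabular metadata with the requested discriminability,
#' a mask-quality score per record, and any planted shortcuts. When `dir` is
#' given, 8-bit PNG images and masks plus a manifest CSV are written there.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory.
#' @return Object of class `shortcut_dataset`: a list with `records` (each a
#'   list with `image`, `mask`, `labels`, `metadata`, `fold`, `mask_quality`,
#'   `shortcuts`), `manifest` (data frame), and `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_images; S <- config$image_size
  n_pos <- round(n * config$prevalence)

  labels <- with_seed(child_seed(config$seed, 0L, 1L), {
    sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  })
  folds <- make_folds(labels, k = 5L, seed = child_seed(config$seed, 0L, 2L))
  metadata <- generate_metadata(labels, config$metadata_auc,
                                seed = child_seed(config$seed, 0L, 3L))
  quality <- with_seed(child_seed(config$seed, 0L, 4L), {
    low <- runif(n) < config$low_quality_frac
    ifelse(low, runif(n, 0.3, 0.7), runif(n, 0.75, 0.99))
  })

  specs <- config$shortcut_specs
  records <- vector("list", n)
  for (i in seq_len(n)) {
    records[[i]] <- with_seed(child_seed(config$seed, i, 10L), {
      y <- labels[i]
      scale <- (1 + config$roi_size_label_slope * y) *
        max(0.6, rnorm(1, 1, config$roi_size_jitter))
      if (config$roi_shape == "two_lungs") {
        jit <- runif(3, -0.02 * S, 0.02 * S)
        mask <- roi_mask_two_lungs(S, scale, jit)
      } else {
        ctr <- runif(2, 0.35 * S, 0.65 * S)
        mask <- roi_mask_disc(S, scale, ctr)
      }
      img <- 0.15 + 0.27 * body_ellipse(S) + 0.13 * mask

      if (y == 1L && config$disease_amplitude > 0) {
        amp <- config$disease_amplitude * config$noise_sd
        in_roi <- which(mask == 1L, arr.ind = TRUE)
        ctr_d <- in_roi[sample.int(nrow(in_roi), 1L), ]
        rr <- matrix(seq_len(S), S, S)
        cc <- matrix(seq_len(S), S, S, byrow = TRUE)
        sig <- 0.06 * S
        win <- exp(-((rr - ctr_d[1])^2 + (cc - ctr_d[2])^2) / (2 * sig^2))
        texture <- matrix(rnorm(S * S, sd = amp), S, S) * win
        img <- img + (texture + 0.15 * amp * win) * mask
      }

      present <- logical(length(specs))
      if (length(specs)) {
        for (k in seq_along(specs)) {
          sp <- specs[[k]]
          match_label <- runif(1) < sp$correlation
          present[k] <- if (match_label) y == 1L else y == 0L
          if (present[k]) img <- render_shortcut(img, mask, sp)
        }
        names(present) <- vapply(specs, `[[`, character(1), "kind")
      }

      if (config$noise_sd > 0) img <- img + matrix(rnorm(S * S, sd = config$noise_sd), S, S)
      # content floor sits just above 0 so black stays reserved for
      # padding and masked-out regions
      img <- pmin(pmax(img, 0.02), 1)

      lab <- stats::setNames(y, config$class_name)
      list(image = img, mask = mask, labels = lab,
           metadata = as.list(metadata[i, ]),
           fold = folds[i], mask_quality = quality[i], shortcuts = present)
    })
  }

  manifest <- data.frame(
    image_path = sprintf("images/img_%05d.png", seq_len(n)),
    mask_path = sprintf("masks/mask_%05d.png", seq_len(n)),
    stringsAsFactors = FALSE
  )
  manifest[[config$class_name]] <- labels
  manifest$sex <- metadata$sex
  manifest$birth_year <- metadata$birth_year
  manifest$projection <- metadata$projection
  manifest$fold <- folds
  manifest$mask_quality <- quality
  for (k in seq_along(specs)) {
    manifest[[paste0("shortcut_", specs[[k]]$kind, "_present")]] <-
      vapply(records, function(r) as.integer(r$shortcuts[[k]]), integer(1))
  }

  ds <- structure(list(records = records, manifest = manifest, config = config),
                  class = "shortcut_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.shortcut_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<shortcut_dataset> %d images (%dx%d, %s ROI), %d positive\n",
              length(x$records), cfg$image_size, cfg$image_size, cfg$roi_shape,
              sum(x$manifest[[cfg$class_name]])))
  if (length(cfg$shortcut_specs)) {
    for (sp in cfg$shortcut_specs) {
      cat(sprintf("  planted shortcut: %s (rho = %.2f, amplitude = %.2f)\n",
                  sp$kind, sp$correlation, sp$amplitude))
    }
  } else cat("  no planted shortcuts\n")
  invisible(x)
}

#' Write a dataset to disk as PNGs plus a manifest CSV
#'
#' Images are written as 8-bit grayscale PNG, masks as 0/255 PNG, and the
#' manifest as CSV with one row per record.
#'
#' @param dataset A `shortcut_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$records)) {
    r <- dataset$records[[i]]
    png::writePNG(r$image, file.path(dir, dataset$manifest$image_path[i]))
    png::writePNG(r$mask * 1.0, file.path(dir, dataset$manifest$mask_path[i]))
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv`, `images/`, `masks/`.
#' @param class_name Name of the label column to read as the disease class.
#' @return A `shortcut_dataset` (with `config = NULL`).
#' @export
read_dataset <- function(dir, class_name = "disease") {
  manifest <- read.csv(file.path(dir, "manifest.csv"), check.names = FALSE)
  if (!class_name %in% names(manifest)) stopf("manifest has no `%s` label column", class_name)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- png::readPNG(file.path(dir, manifest$image_path[i]))
    if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(file.path(dir, manifest$mask_path[i]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    list(image = img, mask = binarize_mask(msk),
         labels = stats::setNames(manifest[[class_name]][i], class_name),
         metadata = list(sex = manifest$sex[i], birth_year = manifest$birth_year[i],
                         projection = manifest$projection[i]),
         fold = manifest$fold[i], mask_quality = manifest$mask_quality[i],
         shortcuts = logical(0))
  })
  structure(list(records = records, manifest = manifest, config = NULL),
            class = "shortcut_dataset")
}

#' Generate label-correlated tabular metadata
#'
#' Draws a continuous latent with binormal separability calibrated so that its
#' AUC against the label equals `metadata_auc`
#' (\eqn{d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})}), then derives the three
#' metadata columns from it: `birth_year` is an affine binning of the latent
#' (carrying essentially all of its signal), while `sex` and `projection` are
#' thresholded noisy copies. With `metadata_auc = 0.5` all columns are
#' label-independent; with 1.0 a linear rule on the metadata separates the
#' labels perfectly.
#'
#' @param labels Binary label vector.
#' @param metadata_auc Target AUC in \[0.5, 1\].
#' @param seed Integer seed.
#' @return Data frame with columns `sex` (0/1), `birth_year` (integer),
#'   `projection` ("AP"/"PA").
#' @export
generate_metadata <- function(labels, metadata_auc, seed = 1L) {
  if (metadata_auc < 0.5 || metadata_auc > 1) stopf("`metadata_auc` must lie in [0.5, 1]")
  n <- length(labels)
  with_seed(seed, {
    if (metadata_auc == 1) {
      u <- labels * 10 + runif(n)  # perfectly separable by threshold
    } else {
      d <- sqrt(2) * qnorm(metadata_auc)
      u <- labels * d + rnorm(n)
    }
    us <- (u - mean(u)) / max(sd(u), 1e-12)
    data.frame(
      sex = as.integer(us + rnorm(n, sd = 1.5) > 0),
      birth_year = as.integer(round(1955 + 8 * us)),
      projection = ifelse(us + rnorm(n, sd = 2) > 0, "PA", "AP"),
      stringsAsFactors = FALSE
    )
  })
}
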