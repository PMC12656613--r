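# Grading standard: indicator normalization, the comprehensive quality score,
# grade thresholds, dataset splitting and minority-class augmentation.

# Weights of the comprehensive score: SSC 0.5, peel red ratio 0.3,
# circularity 0.2. SSC dominates because it is the core internal-quality
# indicator in fruit grading standards; colour tracks maturity; circularity
# matters for mechanical processing suitability.
SCORE_WEIGHTS <- c(ssc = 0.5, color = 0.3, circularity = 0.2)

GRADE_PREMIUM_MIN <- 0.7
GRADE_STANDARD_MIN <- 0.3

#' Normalization bounds for the quality indicators
#'
#' Min-max bounds observed on a training batch, persisted with a model and
#' reapplied (with clipping) at inference time.
#'
#' @param ssc,color,circularity Length-2 numeric vectors `c(min, max)`.
#' @return An object of class `plum_bounds`.
#' @export
norm_bounds <- function(ssc, color, circularity) {
  b <- list(ssc = as.numeric(ssc), color = as.numeric(color),
            circularity = as.numeric(circularity))
  for (nm in names(b)) {
    if (length(b[[nm]]) != 2L || any(!is.finite(b[[nm]])))
      stop_plum("plum_bounds_error", "bounds for '%s' must be two finite numbers", nm)
    if (b[[nm]][2] <= b[[nm]][1])
      stop_plum("plum_bounds_error",
                "degenerate normalization bounds for indicator '%s' (max <= min)", nm)
  }
  structure(b, class = "plum_bounds")
}

#' Compute indicator bounds from a metadata batch
#'
#' @param metadata A data frame with columns `ssc_brix`, `red_fraction`,
#'   `circularity` (as produced by [generate_dataset()]).
#' @return A `plum_bounds` object.
#' @export
compute_bounds <- function(metadata) {
  norm_bounds(
    ssc = range(metadata$ssc_brix),
    color = range(metadata$red_fraction),
    circularity = range(metadata$circularity)
  )
}

#' Min-max normalize an indicator
#'
#' Maps `x` to `(x - min) / (max - min)`, clipping out-of-range inputs to
#' `[0, 1]` so that inference-time values beyond the training batch range
#' remain valid scores.
#'
#' @param values Numeric vector.
#' @param bounds A `plum_bounds` object.
#' @param indicator One of `"ssc"`, `"color"`, `"circularity"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values, bounds, indicator = c("ssc", "color", "circularity")) {
  indicator <- match.arg(indicator)
  if (!inherits(bounds, "plum_bounds"))
    stop_plum("plum_bounds_error", "bounds must be a 'plum_bounds' object")
  b <- bounds[[indicator]]
  clamp((values - b[1]) / (b[2] - b[1]), 0, 1)
}

#' Comprehensive quality score
#'
#' Weighted sum of the three normalized indicators:
#' `0.5 * SSC + 0.3 * Color + 0.2 * Circularity`.
#'
#' @param ssc_norm,color_norm,circ_norm Normalized indicators in `[0, 1]`
#'   (vectorized).
#' @return Score in `[0, 1]`.
#' @export
comprehensive_score <- function(ssc_norm, color_norm, circ_norm) {
  for (v in list(ssc_norm, color_norm, circ_norm)) {
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop_plum("plum_domain_error",
                "normalized indicators must lie in [0, 1]; got value outside range")
  }
  SCORE_WEIGHTS[["ssc"]] * ssc_norm +
    SCORE_WEIGHTS[["color"]] * color_norm +
    SCORE_WEIGHTS[["circularity"]] * circ_norm
}

#' Assign a grade from a comprehensive score
#'
#' Premium for score >= 0.7, standard for 0.3 <= score < 0.7, processing
#' for score < 0.3 (both lower boundaries inclusive).
#'
#' @param score Numeric vector in `[0, 1]`.
#' @return Factor with levels `processing < standard < premium`.
#' @export
assign_grade <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop_plum("plum_domain_error", "score must lie in [0, 1]")
  as_grade(ifelse(score >= GRADE_PREMIUM_MIN, "premium",
                  ifelse(score >= GRADE_STANDARD_MIN, "standard", "processing")))
}

#' Quality indicators and score for a batch
#'
#' Normalizes raw indicator values against `bounds`, computes the
#' comprehensive score and the grade.
#'
#' @param ssc,red_fraction,circularity Raw indicator vectors.
#' @param bounds A `plum_bounds` object.
#' @return Data frame with normalized indicators, `score` and `grade`.
#' @export
quality_indicators <- function(ssc, red_fraction, circularity, bounds) {
  ssc_n <- minmax_normalize(ssc, bounds, "ssc")
  col_n <- minmax_normalize(red_fraction, bounds, "color")
  cir_n <- minmax_normalize(circularity, bounds, "circularity")
  score <- comprehensive_score(ssc_n, col_n, cir_n)
  data.frame(ssc_norm = ssc_n, color_norm = col_n, circularity_norm = cir_n,
             score = score, grade = assign_grade(score))
}

#' Train/validation/test split specification
#'
#' @param ratios Numeric length-3 vector of train/val/test fractions
#'   (default 0.64/0.16/0.20), summing to 1.
#' @param stratified Preserve per-grade proportions across splits
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `plum_split_spec`.
#' @export
split_spec <- function(ratios = c(0.64, 0.16, 0.20), stratified = TRUE, seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop_plum("plum_split_error", "split ratios must be 3 non-negative fractions summing to 1")
  structure(list(ratios = as.numeric(ratios), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "plum_split_spec")
}

# Largest-remainder apportionment of n into parts proportional to `ratios`.
apportion <- function(n, ratios) {
  raw <- n * ratios
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Split samples into train/validation/test index sets
#'
#' Disjoint and exhaustive; sizes follow the ratios to within rounding.
#' With stratification (default) each grade's proportions are preserved to
#' within one sample per split.
#'
#' @param grades Factor/character vector of per-sample grades (or any labels
#'   used for stratification).
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(grades, spec = split_spec()) {
  n <- length(grades)
  if (n < 10L) stop_plum("plum_split_error", "need at least 10 samples to split, got %d", n)
  grades <- as.character(grades)

  stratified <- spec$stratified
  if (stratified && any(table(grades) < 3L)) {
    warning("a grade has fewer than 3 samples; falling back to unstratified split",
            call. = FALSE)
    stratified <- FALSE
  }

  target <- apportion(n, spec$ratios)
  assign_split <- function(idx, sizes) {
    idx <- with_seed(spec$seed + length(idx), sample(idx))
    list(train = idx[seq_len(sizes[1])],
         val = idx[sizes[1] + seq_len(sizes[2])],
         test = idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }

  if (!stratified) {
    out <- assign_split(seq_len(n), target)
  } else {
    parts <- list(train = integer(), val = integer(), test = integer())
    for (g in unique(grades)) {
      idx <- which(grades == g)
      sizes <- apportion(length(idx), spec$ratios)
      sub <- assign_split(idx, sizes)
      parts <- Map(c, parts, sub)
    }
    # Largest-remainder rounding per grade can drift from the global targets
    # by a sample or two; rebalance by moving samples of the largest grade.
    out <- parts
    sizes <- vapply(out, length, integer(1))
    while (any(sizes != target)) {
      over <- which(sizes > target)[1]
      under <- which(sizes < target)[1]
      biggest <- names(which.max(table(grades[out[[over]]])))
      movable <- out[[over]][grades[out[[over]]] == biggest]
      mv <- movable[length(movable)]
      out[[over]] <- setdiff(out[[over]], mv)
      out[[under]] <- c(out[[under]], mv)
      sizes <- vapply(out, length, integer(1))
    }
  }
  lapply(out, function(ix) sort(as.integer(ix)))
}

#' Number of duplicates needed to reach a minority-class target fraction
#'
#' Closed form for a duplication-only policy: `ceil(t * n_other / (1 - t)
#' - n_minority)`.
#'
#' @param n_minority,n_other Current class counts.
#' @param target_fraction Desired minority fraction.
#' @return Non-negative integer count of duplicates.
#' @export
augmentation_count <- function(n_minority, n_other, target_fraction) {
  max(0L, as.integer(ceiling(target_fraction * n_other / (1 - target_fraction) - n_minority)))
}

#' Augment the premium minority class in a training split
#'
#' Duplicates premium-grade training samples, applying a random rotation
#' (a multiple of 90 degrees plus a small jitter) and random horizontal /
#' vertical flips to the image, until the premium fraction of the training
#' split reaches `target_fraction`. Spectra and SSC are copied unchanged;
#' provenance (source sample id, transform) is recorded.
#'
#' @param dataset A `plum_dataset`.
#' @param train_ids Integer indices of the training split.
#' @param target_fraction Target premium fraction (default 0.15).
#' @param seed Integer seed.
#' @return List with the augmented `dataset` (new samples appended), updated
#'   `train_ids`, and a `provenance` data frame.
#' @export
augment_minority <- function(dataset, train_ids, target_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(dataset, "plum_dataset"))
  if (target_fraction <= 0 || target_fraction >= 1)
    stop_plum("plum_augment_error", "target_fraction must lie in (0, 1)")
  md <- dataset$metadata[train_ids, ]
  prem <- train_ids[md$grade == "premium"]
  if (length(prem) == 0L)
    stop_plum("plum_augment_error", "no premium-grade samples in the training split")
  n_other <- length(train_ids) - length(prem)
  n_aug <- augmentation_count(length(prem), n_other, target_fraction)
  if (n_aug == 0L) {
    return(list(dataset = dataset, train_ids = train_ids,
                provenance = data.frame(sample_id = character(), source_id = character(),
                                        rotation_deg = numeric(), flip_h = logical(),
                                        flip_v = logical())))
  }
  aug <- with_seed(seed, {
    src <- sample(prem, n_aug, replace = TRUE)
    data.frame(
      source = src,
      rotation_deg = sample(c(0, 90, 180, 270), n_aug, replace = TRUE) +
        stats::runif(n_aug, -8, 8),
      flip_h = sample(c(TRUE, FALSE), n_aug, replace = TRUE),
      flip_v = sample(c(TRUE, FALSE), n_aug, replace = TRUE)
    )
  })
  n0 <- nrow(dataset$metadata)
  new_rows <- dataset$metadata[aug$source, ]
  new_rows$sample_id <- sprintf("%s_aug%03d", new_rows$sample_id, seq_len(n_aug))
  new_rows$archetype <- dataset$metadata$archetype[aug$source]
  rownames(new_rows) <- NULL
  for (k in seq_len(n_aug)) {
    s <- dataset$samples[[aug$source[k]]]
    if (!is.null(s$image)) {
      s$image <- transform_image(s$image, aug$rotation_deg[k], aug$flip_h[k],
                                 aug$flip_v[k])
    } else {
      # lazy dataset: record the transform; dataset_image() applies it
      s$aug_transform <- list(rotation_deg = aug$rotation_deg[k],
                              flip_h = aug$flip_h[k], flip_v = aug$flip_v[k])
      s$source_index <- aug$source[k]
    }
    s$sample_id <- new_rows$sample_id[k]
    s$augmented_from <- dataset$metadata$sample_id[aug$source[k]]
    dataset$samples[[n0 + k]] <- s
  }
  dataset$metadata <- rbind(dataset$metadata, new_rows)
  list(dataset = dataset,
       train_ids = sort(c(train_ids, n0 + seq_len(n_aug))),
       provenance = data.frame(sample_id = new_rows$sample_id,
                               source_id = dataset$metadata$sample_id[aug$source],
                               rotation_deg = aug$rotation_deg,
                               flip_h = aug$flip_h, flip_v = aug$flip_v))
}

# Rotate (about the centre, bilinear, background filled with the median
# corner colour) and flip an H x W x 3 array. Used only for augmentation.
transform_image <- function(img, angle_deg, flip_h = FALSE, flip_v = FALSE) {
  if (abs(angle_deg %% 360) > 1e-9) {
    h <- dim(img)[1]; w <- dim(img)[2]
    th <- angle_deg * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    # inverse mapping: source coordinates of each output pixel
    ys <- cy + cos(th) * (yy - cy) - sin(th) * (xx - cx)
    xs <- cx + sin(th) * (yy - cy) + cos(th) * (xx - cx)
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    corners <- rbind(img[1, 1, ], img[1, w, ], img[h, 1, ], img[h, w, ])
    bg <- apply(corners, 2, stats::median)
    out <- img
    for (ch in 1:3) {
      plane <- img[, , ch]
      pick <- function(yi, xi) {
        ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
        v <- matrix(bg[ch], h, w)
        v[ok] <- plane[cbind(yi[ok], xi[ok])]
        v
      }
      out[, , ch] <- (1 - fy) * ((1 - fx) * pick(y0, x0) + fx * pick(y0, x0 + 1)) +
        fy * ((1 - fx) * pick(y0 + 1, x0) + fx * pick(y0 + 1, x0 + 1))
    }
    img <- out
  }
  if (flip_h) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (flip_v) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  img
}
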