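#' Otsu threshold over a pixel subset
#'
#' Computes the intensity threshold maximising the between-class variance
#' of the considered pixels' histogram. Pixels at or above the returned
#' value form the positive class (the threshold is inclusive). When a
#' layer mask is supplied only tissue pixels (labels 1--6; background and
#' artifact excluded) are considered, so the background outside the
#' retina cannot drive the threshold.
#'
#' @param channel integer intensity matrix.
#' @param mask optional layer label matrix restricting the histogram to
#'   tissue pixels.
#' @return the threshold (an observed intensity level); positivity is
#'   `intensity >= threshold`.
#' @examples
#' x <- matrix(c(rep(10, 50), rep(200, 50)), 10)
#' otsu_threshold(x)
#' @export
otsu_threshold <- function(channel, mask = NULL) {
  stopifnot(is.matrix(channel))
  v <- as.vector(channel)
  if (!is.null(mask)) {
    validate_layer_mask(mask)
    stopifnot(identical(dim(mask), dim(channel)))
    v <- v[mask >= 1L & mask <= 6L]
  }
  u <- sort(unique(v))
  if (length(u) < 2) {
    stop("no threshold separates classes: constant intensities", call. = FALSE)
  }
  cnt <- as.vector(table(factor(v, levels = u)))
  n <- length(v)
  w0 <- cumsum(cnt) / n              # weight of class {x < u[j+1]}
  s0 <- cumsum(cnt * u)
  mu <- s0[length(u)] / n
  k <- length(u) - 1L                # split after level j: threshold = u[j+1]
  w0 <- w0[1:k]
  mu0 <- (s0[1:k] / n) / w0
  mu1 <- (mu - w0 * mu0) / (1 - w0)
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  u[which.max(bcv) + 1L]
}

#' Threshold policy
#'
#' A policy states how the positivity threshold of each channel role is
#' chosen. `mode = "otsu"` (the default) recomputes an [otsu_threshold()]
#' per image, restricted to tissue pixels. `mode = "fixed"` injects
#' rater-chosen values: `values` is a named vector (role -> intensity),
#' and `overrides` may carry per-cohort value tables taking precedence.
#'
#' @param mode `"otsu"` or `"fixed"`.
#' @param values named numeric vector of fixed thresholds per channel
#'   role (required for `"fixed"`).
#' @param overrides named list: cohort -> named numeric vector of
#'   per-role thresholds overriding `values`.
#' @return an object of class `threshold_policy`.
#' @examples
#' threshold_policy()
#' threshold_policy("fixed", values = c(amyloid = 12000, marker = 9000))
#' @export
threshold_policy <- function(mode = c("otsu", "fixed"), values = NULL,
                             overrides = list()) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(values) || is.null(names(values))) {
      stop("fixed mode needs a named `values` vector (role -> threshold)",
           call. = FALSE)
    }
    if (any(values < 0 | values > 65535)) {
      stop("fixed thresholds must lie within the 16-bit range", call. = FALSE)
    }
  }
  structure(list(mode = mode, values = values, overrides = overrides),
            class = "threshold_policy")
}

#' Resolve a policy to one threshold value
#'
#' Applies a [threshold_policy()] to one channel: per-cohort overrides
#' take precedence over the role-level fixed values; otsu mode computes
#' the threshold from the channel (restricted to tissue when a mask is
#' given). A policy that yields no value for the role is an error.
#'
#' @inheritParams threshold_channel
#' @param policy a [threshold_policy()].
#' @return a single intensity threshold.
#' @export
resolve_threshold <- function(policy, role, cohort = NULL,
                              channel = NULL, mask = NULL) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (policy$mode == "otsu") {
    if (is.null(channel)) stop("otsu policy needs the channel image", call. = FALSE)
    return(otsu_threshold(channel, mask))
  }
  vals <- policy$values
  if (!is.null(cohort) && cohort %in% names(policy$overrides)) {
    ov <- policy$overrides[[cohort]]
    vals[names(ov)] <- ov
  }
  if (!role %in% names(vals)) {
    stop(sprintf("policy resolves no threshold for channel role '%s'", role),
         call. = FALSE)
  }
  unname(vals[[role]])
}

#' Threshold a channel into a positivity mask
#'
#' A pixel is positive iff its intensity is greater than or equal to the
#' threshold (inclusive comparison, fixed for bit-exact reproducibility).
#' The applied threshold and the channel role are recorded on the result.
#'
#' @param channel integer intensity matrix.
#' @param threshold single intensity value, or a [threshold_policy()]
#'   (resolved with `role`, `cohort`, and tissue restriction `mask`).
#' @param role channel role recorded in the output (and used to resolve
#'   a policy).
#' @param cohort,mask used when `threshold` is a policy.
#' @return a logical matrix with attributes `threshold` and `role`.
#' @examples
#' x <- matrix(c(10, 200, 150, 30), 2)
#' threshold_channel(x, 100)
#' @export
threshold_channel <- function(channel, threshold, role = NA_character_,
                              cohort = NULL, mask = NULL) {
  stopifnot(is.matrix(channel))
  if (inherits(threshold, "threshold_policy")) {
    threshold <- resolve_threshold(threshold, role, cohort, channel, mask)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  out <- channel >= threshold
  attr(out, "threshold") <- threshold
  attr(out, "role") <- role
  out
}

#' Rater comparison panels for candidate thresholds
#'
#' Writes one PNG overlay per candidate threshold: the original channel
#' in grayscale with the boundary of the thresholded positive region
#' traced in red, for side-by-side human review of threshold choices.
#' Pure presentation -- no analysis state is changed.
#'
#' @param channel integer intensity matrix.
#' @param candidates numeric vector of candidate thresholds (at least
#'   one).
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return a tibble (`threshold`, `n_positive`, `file`), invisibly.
#' @export
rater_panel <- function(channel, candidates, dir, prefix = "panel") {
  stopifnot(is.matrix(channel))
  if (length(candidates) == 0) {
    stop("need at least one candidate threshold", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- channel / 65535
  out <- purrr::map_dfr(candidates, function(t) {
    m <- channel >= t
    edge <- m & !(shift_mask(m, 1, 0) & shift_mask(m, -1, 0) &
                    shift_mask(m, 0, 1) & shift_mask(m, 0, -1))
    rgb <- array(base, dim = c(nrow(channel), ncol(channel), 3))
    rgb[, , 1][edge] <- 1
    rgb[, , 2][edge] <- 0
    rgb[, , 3][edge] <- 0
    file <- file.path(dir, sprintf("%s_t%d.png", prefix, as.integer(round(t))))
    png::writePNG(rgb, file)
    tibble::tibble(threshold = t, n_positive = sum(m), file = file)
  })
  invisible(out)
}

# Shift a logical matrix by (dr, dc), padding with FALSE.
shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
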