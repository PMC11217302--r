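# Spectrum featurisation: fixed sinusoidal m/z encoding, learned intensity
# projection, and precursor encoding. The m/z encoder supports two
# frequency layouts (see embedding_config); peaks and precursor tokens are
# combined into the encoder input by spectrum_embedding / encode_precursor.

#' Embedding configuration
#'
#' Controls the sinusoidal m/z encoder. Two layouts are available:
#' \describe{
#'   \item{\code{"literal"}}{component \eqn{i} of a peak at \eqn{m} is
#'     \eqn{\sin(m / ((\lambda_{max}/\lambda_{min}) \cdot
#'     (\lambda_{max}/2\pi)^{2i/d}))} for \eqn{i \le d/2} and the cosine
#'     analogue for \eqn{i > d/2}: a single progression with the
#'     \eqn{\lambda_{max}/\lambda_{min}} prefactor inside the wavelength,
#'     so effective wavelengths sit far above the spectral m/z range.}
#'   \item{\code{"paired"}}{the standard transformer layout: d/2
#'     sine/cosine pairs whose wavelengths run geometrically from
#'     \code{lambda_min} to \code{lambda_max}, i.e. component \eqn{k}
#'     uses \eqn{\sin(m / s_k)}, \eqn{\cos(m / s_k)} with
#'     \eqn{s_k = (\lambda_{min}/2\pi)(\lambda_{max}/\lambda_{min})^{(k-1)/(d/2-1)}}.
#'     This is the layout that actually spans the stated wavelength range
#'     and is the default for trained models.}
#' }
#'
#' @param d embedding dimension (even, positive)
#' @param lambda_min,lambda_max wavelength bounds in m/z units
#'   (defaults 0.001 and 10000)
#' @param scheme \code{"literal"} or \code{"paired"}
#' @param top_k peak-list truncation: keep the top_k most intense peaks
#' @param scale_stride ordering of the paired sin/cos scale pairs along
#'   the channel axis: with stride s, consecutive channel blocks hold
#'   scales s apart, so a model with s attention heads gives every head
#'   scale pairs spread across the whole wavelength range (a sharp
#'   multi-resolution mass-matching kernel per head) instead of one
#'   narrow band each. 1 keeps the plain geometric order.
#' @return object of class \code{embedding_config}
#' @export
embedding_config <- function(d = 64L, lambda_min = 0.001, lambda_max = 10000,
                             scheme = c("literal", "paired"), top_k = 300L,
                             scale_stride = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(d > 0L, d %% 2L == 0L, lambda_min < lambda_max, lambda_min > 0)
  structure(list(d = as.integer(d), lambda_min = lambda_min,
                 lambda_max = lambda_max, scheme = scheme,
                 top_k = as.integer(top_k),
                 scale_stride = as.integer(scale_stride)),
            class = "embedding_config")
}

#' Sinusoidal m/z encoding
#'
#' Maps m/z values to d-dimensional vectors with an equal number of sine
#' and cosine components; frequency layout per the configuration (see
#' \code{\link{embedding_config}}).
#'
#' @param mz_values numeric vector of m/z values (>= 0)
#' @param cfg an \code{embedding_config}
#' @return numeric matrix, \code{length(mz_values)} x \code{cfg$d}
#' @export
encode_mz <- function(mz_values, cfg) {
  stopifnot(all(mz_values >= 0))
  d <- cfg$d
  half <- d %/% 2L
  if (cfg$scheme == "literal") {
    i <- seq_len(d)
    denom <- (cfg$lambda_max / cfg$lambda_min) *
      (cfg$lambda_max / (2 * pi))^(2 * i / d)
    arg <- outer(mz_values, 1 / denom)
    cbind(sin(arg[, seq_len(half), drop = FALSE]),
          cos(arg[, (half + 1L):d, drop = FALSE]))
  } else {
    k <- seq_len(half)
    expo <- if (half > 1L) (k - 1) / (half - 1) else 0
    scale <- (cfg$lambda_min / (2 * pi)) *
      (cfg$lambda_max / cfg$lambda_min)^expo
    arg <- outer(mz_values, 1 / scale)
    # sin/cos pairs interleaved, so any contiguous block of channels
    # (e.g. one attention head) holds complete pairs; scale_stride > 1
    # spreads the scales so each block spans the whole wavelength range
    stride <- if (is.null(cfg$scale_stride)) 1L else max(1L, cfg$scale_stride)
    ord <- unlist(lapply(seq_len(stride), function(h)
      seq(h, half, by = stride)))
    out <- matrix(0, length(mz_values), d)
    out[, 2 * seq_len(half) - 1] <- sin(arg[, ord, drop = FALSE])
    out[, 2 * seq_len(half)] <- cos(arg[, ord, drop = FALSE])
    out
  }
}

#' Intensity projection
#'
#' Affine map of scalar peak intensities to d dimensions (the learned
#' linear layer of the model). Weights live in the model; pass them
#' explicitly here.
#'
#' @param intensities numeric vector (pre-normalised; see
#'   \code{\link{normalize_intensity}})
#' @param W,b weight (length d) and bias (length d) of the affine map
#' @return matrix \code{length(intensities)} x d
#' @export
encode_intensity <- function(intensities, W, b) {
  outer(intensities, W) + .bcast_rows(b, length(intensities))
}

#' Max-normalise peak intensities
#'
#' Divides by the maximum intensity of the spectrum so peak intensities lie
#' in [0, 1] regardless of instrument scale. All-zero spectra are returned
#' unchanged.
#' @param intensities numeric vector
#' @return normalised vector
#' @export
normalize_intensity <- function(intensities) {
  m <- max(intensities, 0)
  if (m > 0) intensities / m else intensities
}

#' Spectral input embedding
#'
#' Elementwise sum of the sinusoidal m/z encoding and the intensity
#' projection: one row per peak, no padding. Intensities are
#' max-normalised first. When the spectrum has more than \code{cfg$top_k}
#' peaks, only the top_k most intense are kept (m/z order preserved).
#'
#' @param spec a \code{\link{spectrum}}
#' @param cfg an \code{embedding_config}
#' @inheritParams encode_intensity
#' @return matrix N x d (N = number of retained peaks)
#' @export
spectrum_embedding <- function(spec, cfg, W, b) {
  mz <- spec$mz
  int <- spec$intensity
  if (length(mz) > cfg$top_k) {
    keep <- sort(order(int, decreasing = TRUE)[seq_len(cfg$top_k)])
    mz <- mz[keep]; int <- int[keep]
  }
  encode_mz(mz, cfg) + encode_intensity(normalize_intensity(int), W, b)
}

#' Precursor encoding
#'
#' Two extra encoder tokens: the first fuses the precursor neutral mass
#' and m/z (their sinusoidal encodings summed), the second is a learned
#' per-charge embedding. Charges beyond the table are clamped to the last
#' row with a warning.
#'
#' @param neutral_mass,mz,charge precursor fields
#' @param cfg an \code{embedding_config}
#' @param charge_table matrix (max charge x d) of learned charge embeddings
#' @return matrix 2 x d (mass+mz token, charge token)
#' @export
encode_precursor <- function(neutral_mass, mz, charge, cfg, charge_table) {
  if (charge > nrow(charge_table)) {
    warning("precursor charge ", charge, " clamped to ", nrow(charge_table))
    charge <- nrow(charge_table)
  }
  rbind(encode_mz(neutral_mass, cfg) + encode_mz(mz, cfg),
        charge_table[charge, , drop = FALSE])
}
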