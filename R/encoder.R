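# Fixed toy encoder.  The shared trunk is a mean-pooling pyramid that
# reduces resolution while preserving the color planes.  Each finding
# branch applies its lesion's linear spectral-unmixing filter (nulling the
# other lesion colors), then — after frozen normalization calibrated on
# probe images (background subtraction and scale, the role batch
# normalization plays in a trained network) — a bank of threshold-detection
# channels.  Branches are therefore specialized for their finding the way
# trained branches would be, and the feature block of one finding carries
# no information about the others.  The encoder is frozen; only the linear
# heads downstream are trained.

# 2x2 mean pooling on an H x W x C array (H, W even).
.meanPool2 <- function(a) {
  d <- dim(a)
  a <- (a[seq(1L, d[1], 2L), , , drop = FALSE] +
          a[seq(2L, d[1], 2L), , , drop = FALSE]) / 2
  (a[, seq(1L, d[2], 2L), , drop = FALSE] +
     a[, seq(2L, d[2], 2L), , drop = FALSE]) / 2
}

# 1x1 convolution (channel mix) + leaky ReLU on an H x W x Cin array.
.mixChannels <- function(a, W, slope = 0.1) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3]) %*% W
  neg <- m < 0
  m[neg] <- slope * m[neg]
  array(m, c(d[1], d[2], ncol(W)))
}

# raw (pre-normalization) branch map: H' x W' x K
.branchRaw <- function(a, branch) {
  if (!is.null(branch$unmix)) {
    d <- dim(a)
    array(matrix(a, d[1] * d[2], d[3]) %*% branch$unmix, c(d[1], d[2], 1L))
  } else {
    ab <- a
    for (W in branch$mixes) ab <- .mixChannels(ab, W)
    ab
  }
}

#' Build the frozen toy encoder
#'
#' Instantiates the encoder described by an \code{\link{EncoderSpec}}.
#' The shared trunk is \code{sharedDepth} stages of 2x2 mean pooling
#' (resolution falls by \code{2^sharedDepth}; color planes are preserved).
#' When lesion color \code{signatures} are supplied, each finding branch
#' applies that finding's linear spectral-unmixing filter — the
#' pseudo-inverse row that responds to its own lesion color and nulls the
#' others — and expands the (normalized) unmixing map into \code{channels}
#' detection channels: the map itself plus rectified copies thresholded at
#' an increasing ladder, so lesion-bearing cells light up channel by
#' channel.  Without signatures the branch is \code{branchDepth} seeded
#' random channel-mixing stages with leaky-ReLU activations.  Use
#' \code{\link{calibrateEncoder}} to freeze the normalization statistics
#' before encoding a cohort.
#'
#' @param spec an \code{\link{EncoderSpec}}.
#' @param findings character vector of finding names (one branch each).
#' @param signatures optional named list giving, per finding, a length-3
#'   lesion color direction (see \code{\link{lesionSignatures}}).
#' @param seed integer seed for the random weight draw (generic branches).
#' @param inputChannels image channel count (default 3, RGB).
#' @return an encoder object (list) for \code{\link{encodeImage}}.
#' @export
buildEncoder <- function(spec, findings, signatures = NULL, seed = 1L,
                         inputChannels = 3L) {
  stopifnot(is(spec, "EncoderSpec"), length(findings) >= 1L)
  set.seed(as.integer(seed))
  C <- spec@channels
  drawW <- function(cin, cout)
    matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
  unmix <- NULL
  if (!is.null(signatures)) {
    S <- vapply(findings, function(f) {
      sig <- as.numeric(signatures[[f]])
      if (length(sig) != inputChannels)
        stop("signature for '", f, "' must have length ", inputChannels,
             call. = FALSE)
      sig
    }, numeric(inputChannels))
    # spectral unmixing: row f of the pseudo-inverse responds with 1 to its
    # own lesion color and (for F <= inputChannels) 0 to the others
    sv <- svd(S)
    pos <- sv$d > max(sv$d) * 1e-10
    unmix <- sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
    rownames(unmix) <- findings
  }
  branches <- lapply(stats::setNames(findings, findings), function(f) {
    if (!is.null(unmix)) list(unmix = unmix[f, ], mixes = NULL)
    else list(unmix = NULL,
              mixes = c(list(drawW(inputChannels, C)),
                        lapply(seq_len(spec@branchDepth - 1L),
                               function(s) drawW(C, C) + diag(C))))
  })
  # amplitude band edges for the detection bank (normalized-unmix scale);
  # disjoint bands keep the within-block channels well conditioned
  edges <- c(0.5, 1, 1.5, 2, 3, 5, 8, 12, 20)
  structure(list(spec = spec, inputChannels = inputChannels,
                 branches = branches,
                 bandEdges = edges[seq_len(max(C - 1L, 1L))],
                 calibration = NULL, seed = as.integer(seed)),
            class = "toyEncoder")
}

#' Freeze the encoder's normalization on probe images
#'
#' Computes, per branch channel, the pixelwise mean map (background
#' subtraction: the deterministic disc shading cancels exactly) and a
#' global scale (standard deviation of the centered values), and stores
#' them in the encoder.  This is the frozen analogue of batch
#' normalization: statistics are estimated once on probe (training) images
#' and never updated, keeping the encoder a fixed function.
#'
#' @param encoder object from \code{\link{buildEncoder}}.
#' @param images list of probe H x W x 3 arrays (a few hundred suffice).
#' @return the calibrated encoder.
#' @export
calibrateEncoder <- function(encoder, images) {
  stopifnot(inherits(encoder, "toyEncoder"), length(images) >= 2L)
  raws <- lapply(images, function(im) {
    a <- .sharedTrunk(im, encoder)
    lapply(encoder$branches, function(br) .branchRaw(a, br))
  })
  encoder$calibration <- lapply(stats::setNames(names(encoder$branches),
                                                names(encoder$branches)),
                                function(f) {
    stack <- lapply(raws, `[[`, f)
    ctr <- Reduce(`+`, stack) / length(stack)
    dev <- vapply(stack, function(a) mean((a - ctr)^2), numeric(1))
    scl <- sqrt(mean(dev))
    if (scl == 0) scl <- 1
    list(center = ctr, scale = scl)
  })
  encoder
}

.sharedTrunk <- function(image, encoder) {
  spec <- encoder$spec
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  d <- dim(image)
  if (d[1] != spec@inputSize || d[2] != spec@inputSize ||
      d[3] != encoder$inputChannels)
    stop("image must be ", spec@inputSize, " x ", spec@inputSize, " x ",
         encoder$inputChannels, "; got ", paste(d, collapse = " x "),
         call. = FALSE)
  a <- image
  for (s in seq_len(spec@sharedDepth)) a <- .meanPool2(a)
  a
}

#' Encode an image into per-finding latent features
#'
#' Runs the frozen encoder on one image, returning the spatial feature map
#' \eqn{g_f(x)} and pooled vector \eqn{\bar z_f} of every finding branch.
#'
#' @param image numeric H x W x 3 array in [0, 1] with H = W =
#'   \code{inputSize} of the encoder's spec.
#' @param encoder a (preferably calibrated) encoder from
#'   \code{\link{buildEncoder}}.
#' @return a \code{\link{LatentFeatures}}.
#' @export
encodeImage <- function(image, encoder) {
  stopifnot(inherits(encoder, "toyEncoder"))
  a <- .sharedTrunk(image, encoder)
  C <- encoder$spec@channels
  maps <- lapply(stats::setNames(names(encoder$branches),
                                 names(encoder$branches)), function(f) {
    br <- encoder$branches[[f]]
    raw <- .branchRaw(a, br)
    cal <- encoder$calibration[[f]]
    if (!is.null(cal)) raw <- (raw - cal$center) / cal$scale
    if (!is.null(br$unmix)) {
      u <- raw[, , 1L]
      ed <- c(encoder$bandEdges, Inf)
      out <- array(0, c(dim(u), C))
      out[, , 1L] <- u
      for (k in seq_len(C - 1L))    # band energy in [ed_k, ed_{k+1})
        out[, , k + 1L] <- pmin(pmax(u - ed[k], 0), ed[k + 1L] - ed[k])
      raw <- out
    }
    aperm(raw, c(3L, 1L, 2L))           # C x H' x W'
  })
  latentFeatures(maps = maps)
}

#' Encode a set of images to pooled feature matrices
#'
#' @param images list of H x W x 3 arrays.
#' @param encoder a calibrated encoder from \code{\link{buildEncoder}}.
#' @return named list (one entry per finding) of n x C pooled-feature
#'   matrices, the input format of the head trainers.
#' @export
encodeImages <- function(images, encoder) {
  feats <- lapply(images, function(im) {
    lf <- encodeImage(im, encoder)
    vapply(pooledFeatures(lf), identity,
           numeric(encoder$spec@channels))
  })
  findings <- names(encoder$branches)
  out <- lapply(stats::setNames(findings, findings), function(f)
    t(vapply(feats, function(m) m[, f], numeric(encoder$spec@channels))))
  out
}

#' Lesion color signatures of a generator spec
#'
#' Convenience extractor: the per-finding color \code{intensity} directions
#' of a \code{\link{GeneratorSpec}}, in the form \code{\link{buildEncoder}}
#' accepts as unmixing signatures.
#'
#' @param spec a \code{\link{GeneratorSpec}}.
#' @return named list of length-3 numeric vectors.
#' @export
lesionSignatures <- function(spec) {
  stopifnot(is(spec, "GeneratorSpec"))
  lapply(spec@signatures, function(s) as.numeric(s$intensity))
}
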