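#' Convert an RGB image to optical density
#'
#' `OD = -log((I + 1) / I0)` per channel; the +1 guards `log(0)` and
#' makes [odToRGB()] an exact inverse over the 8-bit range. Values
#' above `I0` clamp to OD 0.
#'
#' @param image an [ImageField-class] or a `[row, col, 3]` array.
#' @param I0 background intensity, scalar or length 3; for an
#'   `ImageField` defaults to the render background, else 255.
#' @return numeric array `[row, col, 3]` of optical densities.
#' @export
rgbToOD <- function(image, I0 = NULL) {
  rgb <- if (is(image, "ImageField")) image@rgb else image
  if (is.null(I0)) I0 <- 255
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  if (any(I0 <= 0)) stop("I0 must be > 0")
  od <- rgb
  for (ch in 1:3) od[, , ch] <- -log((rgb[, , ch] + 1) / I0[ch])
  pmax(od, 0)
}

#' Invert [rgbToOD()]
#'
#' @param od numeric OD array `[row, col, 3]`.
#' @param I0 background intensity, scalar or length 3.
#' @param round8 round to integer intensity levels (default TRUE).
#' @return intensity array clipped to `[0, I0]`.
#' @export
odToRGB <- function(od, I0 = 255, round8 = TRUE) {
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  rgb <- od
  for (ch in 1:3) {
    v <- I0[ch] * exp(-od[, , ch]) - 1
    if (round8) v <- round(v)
    rgb[, , ch] <- pmin(I0[ch], pmax(0, v))
  }
  rgb
}

#' Construct a stain model
#'
#' @param stainMatrix 3x2 OD matrix, columns haematoxylin then DAB;
#'   columns are normalised.
#' @param maxConcentrations robust per-stain maximum concentrations.
#' @param backgroundIntensity I0, scalar or length 3.
#' @return a [StainModel-class].
#' @export
stainModel <- function(stainMatrix, maxConcentrations = c(1, 1),
                       backgroundIntensity = 255) {
  stainMatrix <- sweep(stainMatrix, 2L, sqrt(colSums(stainMatrix^2)), "/")
  if (length(backgroundIntensity) == 1L)
    backgroundIntensity <- rep(backgroundIntensity, 3L)
  new("StainModel", stainMatrix = stainMatrix,
      maxConcentrations = as.numeric(maxConcentrations),
      backgroundIntensity = as.numeric(backgroundIntensity))
}

## Flatten an OD array to an n x 3 matrix of pixels.
odPixelMatrix <- function(od) {
  matrix(od, ncol = 3L, dimnames = list(NULL, c("R", "G", "B")))
}

weightedQuantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[pmin(length(x), findInterval(p, cw) + 1L)]
}

#' Estimate the stain matrix by the Macenko procedure
#'
#' Tissue pixels (those with `||OD|| > beta`) are projected onto the
#' plane spanned by the top two eigenvectors of the OD covariance; the
#' `alpha`-th and `(100 - alpha)`-th percentile angles in that plane
#' are back-projected to two unit stain vectors. The column whose red
#' OD component is larger is labelled haematoxylin (haematoxylin is a
#' blue dye, so it absorbs red most strongly); ties break on the angle
#' sign. Robust per-stain maximum concentrations are the 99th
#' percentile of non-negative concentration fits over tissue pixels.
#'
#' @param image an [ImageField-class], RGB array, or an OD array (pass
#'   `isOD = TRUE`).
#' @param beta OD-norm threshold separating tissue from background.
#' @param alpha percentile (in percent) for the extreme angles.
#' @param I0 background intensity used for the OD transform.
#' @param isOD set TRUE when `image` is already optical density.
#' @param smoothSigma sigma (px) of the Gaussian denoise applied to
#'   the OD image before angle estimation; 0 disables. Weakly stained
#'   pixels dominate the angle extremes on sparse fields, so the
#'   percentiles are additionally weighted by OD norm.
#' @return a [StainModel-class].
#' @export
estimateStainMatrix <- function(image, beta = 0.15, alpha = 1,
                                I0 = NULL, isOD = FALSE,
                                smoothSigma = 2) {
  if (is.null(I0)) I0 <- 255
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  od <- if (isOD) image else rgbToOD(image, I0)
  odS <- od
  if (smoothSigma > 0)
    for (ch in 1:3)
      odS[, , ch] <- EBImage::gblur(od[, , ch], sigma = smoothSigma)
  px <- odPixelMatrix(odS)
  nrm <- sqrt(rowSums(px^2))
  tissue <- px[nrm > beta, , drop = FALSE]
  if (nrow(tissue) < 100L)
    stop("too few tissue pixels above the OD-norm threshold beta = ",
         beta, " (", nrow(tissue), " found); cannot estimate stains")
  tnrm <- nrm[nrm > beta]

  ev <- eigen(stats::cov(tissue), symmetric = TRUE)
  basis <- ev$vectors[, 1:2, drop = FALSE]
  ## orient the basis so projections land in a consistent half-plane
  for (k in 1:2) if (sum(basis[, k]) < 0) basis[, k] <- -basis[, k]
  proj <- tissue %*% basis
  phi <- atan2(proj[, 2L], proj[, 1L])
  phis <- weightedQuantile(phi, tnrm, c(alpha, 100 - alpha) / 100)
  vecs <- sapply(phis, function(p) basis %*% c(cos(p), sin(p)))
  ## unit, non-negative orientation
  vecs <- apply(vecs, 2L, function(v) {
    if (sum(v) < 0) v <- -v
    v / sqrt(sum(v^2))
  })
  ## haematoxylin = larger red OD component; tie on angle sign
  hFirst <- if (abs(vecs[1L, 1L] - vecs[1L, 2L]) > 1e-12)
    vecs[1L, 1L] > vecs[1L, 2L] else phis[1L] < phis[2L]
  S <- if (hFirst) vecs else vecs[, 2:1]
  colnames(S) <- c("haematoxylin", "DAB")

  conc <- fitConcentrations(od, stainModel(S, c(1, 1), I0))
  maxC <- apply(matrix(conc, ncol = 2L), 2L, function(co) {
    q <- stats::quantile(co[co > 0], 0.99, names = FALSE)
    if (!is.finite(q) || q <= 0) 1 else q
  })
  stainModel(S, maxC, I0)
}

#' Fit per-pixel stain concentrations
#'
#' Solves `OD = S %*% c` per pixel. The default is the Macenko
#' pseudo-inverse with negative concentrations clipped to zero;
#' `method = "nnls"` solves the 2-variable non-negative least-squares
#' problem exactly (closed form for a 3x2 system).
#'
#' @param od OD array `[row, col, 3]`.
#' @param stain a [StainModel-class].
#' @param method `"pinv"` (default) or `"nnls"`.
#' @return array `[row, col, 2]` of (haematoxylin, DAB) concentrations.
#' @export
fitConcentrations <- function(od, stain, method = c("pinv", "nnls")) {
  method <- match.arg(method)
  S <- stain@stainMatrix
  px <- odPixelMatrix(od)
  ## tolerance pseudo-inverse: degenerate (near-parallel) stain pairs
  ## collapse onto the common direction instead of erroring
  sv <- svd(S)
  keep <- sv$d > max(sv$d) * 1e-8
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  cc <- px %*% t(pinv)
  if (method == "pinv") {
    cc[cc < 0] <- 0
  } else {
    neg <- which(cc[, 1L] < 0 | cc[, 2L] < 0)
    if (length(neg)) {
      ## fix each negative coordinate at 0 and refit the other stain
      s1 <- S[, 1L]; s2 <- S[, 2L]
      c2only <- pmax(0, px[neg, , drop = FALSE] %*% s2 / sum(s2^2))
      c1only <- pmax(0, px[neg, , drop = FALSE] %*% s1 / sum(s1^2))
      r2 <- rowSums((px[neg, , drop = FALSE] -
                       tcrossprod(c2only, s2))^2)
      r1 <- rowSums((px[neg, , drop = FALSE] -
                       tcrossprod(c1only, s1))^2)
      use1 <- r1 <= r2
      cc[neg, 1L] <- ifelse(use1, c1only, 0)
      cc[neg, 2L] <- ifelse(use1, 0, c2only)
    }
  }
  array(cc, dim = c(dim(od)[1:2], 2L))
}

#' Normalise an image to a reference stain model
#'
#' Concentrations are fitted against the source model, rescaled by the
#' ratio of reference to source robust maximum concentrations, and
#' re-rendered through the reference stain matrix and background. With
#' `source = reference` and an in-gamut image the operation is the
#' identity up to one intensity level.
#'
#' @param image [ImageField-class] or RGB array.
#' @param source,reference [StainModel-class] objects.
#' @param method concentration fit method, see [fitConcentrations()].
#' @return object of the same kind as `image`, normalised.
#' @export
normalizeToReference <- function(image, source, reference,
                                 method = c("pinv", "nnls")) {
  method <- match.arg(method)
  if (abs(det(crossprod(source@stainMatrix))) < 1e-12)
    stop("source stain matrix is singular")
  isField <- is(image, "ImageField")
  rgb <- if (isField) image@rgb else image
  od <- rgbToOD(rgb, source@backgroundIntensity)
  conc <- fitConcentrations(od, source, method)
  scale <- reference@maxConcentrations / source@maxConcentrations
  h <- dim(conc)[1L]; w <- dim(conc)[2L]
  cc <- matrix(conc, ncol = 2L) %*% diag(scale)
  odNew <- array(cc %*% t(reference@stainMatrix), dim = c(h, w, 3L))
  out <- odToRGB(odNew, reference@backgroundIntensity)
  if (isField) {
    image@rgb <- out
    image@provenance <- c(image@provenance, list(normalised = TRUE))
    image
  } else out
}

#' Angular distance between stain vectors
#'
#' @param a,b unit 3-vectors (or 3x2 matrices compared columnwise).
#' @return angle(s) in degrees.
#' @export
stainAngle <- function(a, b) {
  if (is.matrix(a)) {
    sapply(seq_len(ncol(a)), function(k) stainAngle(a[, k], b[, k]))
  } else {
    ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    acos(pmin(1, pmax(-1, ca))) * 180 / pi
  }
}

#' Serialise / restore a stain model as YAML
#'
#' @param model a [StainModel-class].
#' @param path file path.
#' @return `readStainModel` returns a [StainModel-class];
#'   `writeStainModel` returns `path` invisibly.
#' @export
writeStainModel <- function(model, path) {
  yaml::write_yaml(list(
    stain_matrix_rows = lapply(seq_len(3L), function(i)
      as.numeric(model@stainMatrix[i, ])),
    max_concentrations = as.numeric(model@maxConcentrations),
    background_intensity = as.numeric(model@backgroundIntensity)), path)
  invisible(path)
}

#' @rdname writeStainModel
#' @export
readStainModel <- function(path) {
  y <- yaml::read_yaml(path)
  S <- do.call(rbind, lapply(y$stain_matrix_rows, as.numeric))
  stainModel(S, as.numeric(y$max_concentrations),
             as.numeric(y$background_intensity))
}
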