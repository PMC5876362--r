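#' Per-category pixel fractions of a label map
#'
#' @param map character matrix of per-pixel tags (category names or
#'   \code{"background"}).
#' @param categories character vector of category names.
#' @return named numeric vector of pixel-count fractions of the image area.
#' @export
pixelFractions <- function(map, categories) {
    n <- length(map)
    vapply(categories, function(cat) sum(map == cat) / n, numeric(1))
}

#' Apply the 20\% pixel-label rule and build the clear sample set
#'
#' A stimulus is tentatively labeled positive for every category whose pixel
#' fraction meets the threshold (default 20\% of the image area).  The clear
#' sample set for a given category's task consists of stimuli
#' tentative-positive for exactly that category (clear positives) plus
#' stimuli tentative-positive for no category (clear negatives);
#' multi-category stimuli belong to no clear set and later receive activity
#' weight 0.
#'
#' @param maps named list of pixel-label maps (character matrices).  If the
#'   list carries a \code{"vocabulary"} attribute it is used to validate the
#'   requested category names; otherwise the union of observed tags is used.
#' @param categories character vector of category names to label against.
#' @param threshold pixel fraction in (0, 1); default 0.2.
#' @return A \linkS4class{CategoryLabeling}.
#' @examples
#' m <- matrix("background", 10, 10); m[1:5, 1:5] <- "humans"  # 25% humans
#' lab <- assignCategoryLabels(list(s1 = m), c("humans", "animals"))
#' clearSampleSet(lab, "humans")  # "s1", a clear positive
#' @export
assignCategoryLabels <- function(maps, categories, threshold = 0.2) {
    stopifnot2(length(maps) > 0, "maps must be nonempty")
    stopifnot2(threshold > 0 && threshold < 1, "threshold must lie in (0, 1)")
    vocab <- attr(maps, "vocabulary")
    if (is.null(vocab)) vocab <- unique(unlist(lapply(maps, unique)))
    missing <- setdiff(categories, vocab)
    stopifnot2(length(missing) == 0,
        paste0("category name(s) absent from the map vocabulary: ",
            paste(missing, collapse = ", ")))
    if (is.null(names(maps)))
        names(maps) <- sprintf("stim%04d", seq_along(maps))
    frac <- do.call(rbind, lapply(maps, pixelFractions,
        categories = categories))
    dimnames(frac) <- list(names(maps), categories)
    tentative <- lapply(seq_len(nrow(frac)), function(i)
        categories[frac[i, ] >= threshold])
    names(tentative) <- names(maps)
    clear <- vapply(tentative, length, 1L) <= 1L
    methods::new("CategoryLabeling", fractions = frac,
        tentative = tentative, clear = stats::setNames(clear, names(maps)),
        threshold = threshold)
}

#' Clear sample set and binary labels for one category's task
#'
#' \code{clearSampleSet} returns the ids of the unambiguous stimuli for a
#' category's binary task: clear positives (tentative-positive for exactly
#' that category) together with the clear negatives -- stimuli that are
#' single-category examples of \emph{another} category, plus stimuli
#' tentative-positive for no category at all.  Multi-category stimuli (for
#' example a person with a pet animal) belong to no clear set; they are
#' excluded from training labels and later carry activity weight 0.
#' \code{binaryLabels} returns the +1/-1 labels for ids inside the set.
#' \code{clarity} returns the dominant-category pixel fraction per stimulus
#' (0 for background-only stimuli).
#'
#' @param labeling a \linkS4class{CategoryLabeling}.
#' @param category a category name present in the labeling.
#' @param ids stimulus ids; must belong to the category's clear sample set.
#' @return character ids, named numeric labels, or named numeric clarities.
#' @export
clearSampleSet <- function(labeling, category) {
    stopifnot2(category %in% colnames(labeling@fractions),
        "unknown category")
    rownames(labeling@fractions)[labeling@clear]
}

#' @rdname clearSampleSet
#' @export
binaryLabels <- function(labeling, category, ids = clearSampleSet(labeling, category)) {
    cs <- clearSampleSet(labeling, category)
    stopifnot2(all(ids %in% cs),
        "ids must lie inside the category's clear sample set")
    pos <- vapply(labeling@tentative[ids], function(t)
        length(t) == 1L && t == category, logical(1))
    stats::setNames(ifelse(pos, 1, -1), ids)
}

#' @rdname clearSampleSet
#' @export
clarity <- function(labeling) {
    f <- labeling@fractions
    stats::setNames(apply(f, 1L, max), rownames(f))
}

setMethod("show", "CategoryLabeling", function(object) {
    n <- nrow(object@fractions)
    cat("CategoryLabeling:", n, "stimuli,",
        ncol(object@fractions), "categories, threshold",
        object@threshold, "\n")
    nTent <- vapply(object@tentative, length, 1L)
    cat(sprintf("  clear positives: %d  clear negatives: %d  mixed: %d\n",
        sum(nTent == 1L), sum(nTent == 0L), sum(nTent > 1L)))
})

#' Preprocess a raw image into a stimulus
#'
#' Converts to grayscale, rescales intensities to [0, 1], downsamples to
#' \code{targetSide} x \code{targetSide} (bilinear), adds a layer of
#' zero-mean Gaussian noise of the requested variance, and clips to [0, 1].
#' Non-square inputs are resized with aspect distortion and a warning.
#'
#' @param raw numeric matrix (grayscale) or H x W x 3 array (RGB, converted
#'   by luminance weights 0.2126/0.7152/0.0722).  Intensities above 1 are
#'   assumed to be 8-bit and divided by 255.
#' @param targetSide output side length in pixels (default 250).
#' @param noiseVariance variance of the additive Gaussian noise layer
#'   (default 0.01).
#' @param seed integer seed for the noise draw.
#' @return numeric \code{targetSide} x \code{targetSide} matrix in [0, 1].
#' @export
preprocessImage <- function(raw, targetSide = 250L, noiseVariance = 0.01,
    seed = 1L) {
    stopifnot2(length(raw) > 0, "raw image is empty")
    if (is.array(raw) && length(dim(raw)) == 3L)
        raw <- 0.2126 * raw[, , 1L] + 0.7152 * raw[, , 2L] +
            0.0722 * raw[, , 3L]
    raw <- as.matrix(raw)
    if (max(raw) > 1) raw <- raw / 255
    raw[raw < 0] <- 0; raw[raw > 1] <- 1
    if (nrow(raw) != ncol(raw))
        warning("non-square input resized with aspect distortion",
            call. = FALSE)
    img <- EBImage::resize(raw, w = targetSide, h = targetSide)
    img <- matrix(as.numeric(img), targetSide, targetSide)
    if (noiseVariance > 0)
        img <- img + withLocalSeed(deriveSeed(seed, "pixel-noise"),
            matrix(rnorm(targetSide^2, 0, sqrt(noiseVariance)),
                targetSide, targetSide))
    img[img < 0] <- 0; img[img > 1] <- 1
    img
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Dense HOG over a square grid of non-overlapping cells: central-difference
#' gradients, unsigned orientation quantized into \code{bins} bins in
#' [0, pi) with linear interpolation between adjacent bins, magnitudes
#' accumulated per cell, each cell histogram L2-normalized (zero cells stay
#' zero).  The descriptor is the row-major concatenation of the cell
#' histograms, so a 64 x 64 image at cell size 32 yields a
#' 2 x 2 x \code{bins} = 36-dimensional vector.  The dialect is recorded in
#' the \code{"hog"} attribute of the result; downstream logic is
#' feature-agnostic.
#'
#' @param image numeric matrix in [0, 1]; side must be at least
#'   \code{cellSize}.
#' @param cellSize cell side in pixels (default 32).
#' @param bins orientation bins (default 9).
#' @return numeric descriptor vector.
#' @export
extractHOG <- function(image, cellSize = 32L, bins = 9L) {
    image <- as.matrix(image)
    h <- nrow(image); w <- ncol(image)
    stopifnot2(min(h, w) >= cellSize, "image side smaller than cellSize")
    # central differences with replicated borders
    gx <- image[, c(2:w, w)] - image[, c(1, 1:(w - 1))]
    gy <- image[c(2:h, h), ] - image[c(1, 1:(h - 1)), ]
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% pi                # unsigned orientation [0, pi)
    pos <- ang / pi * bins                    # continuous bin position
    b0 <- floor(pos) %% bins
    fracb <- pos - floor(pos)
    b1 <- (b0 + 1L) %% bins
    nr <- floor(h / cellSize); nc <- floor(w / cellSize)
    cellRow <- pmin(nr - 1L, (row(image) - 1L) %/% cellSize)
    cellCol <- pmin(nc - 1L, (col(image) - 1L) %/% cellSize)
    desc <- numeric(nr * nc * bins)
    idx0 <- (cellRow * nc + cellCol) * bins + b0 + 1L
    idx1 <- (cellRow * nc + cellCol) * bins + b1 + 1L
    inc0 <- tapply(mag * (1 - fracb), idx0, sum)
    inc1 <- tapply(mag * fracb, idx1, sum)
    desc[as.integer(names(inc0))] <- desc[as.integer(names(inc0))] + inc0
    desc[as.integer(names(inc1))] <- desc[as.integer(names(inc1))] + inc1
    # per-cell L2 normalization; all-zero cells (constant image) stay zero
    for (cell in seq_len(nr * nc)) {
        sl <- ((cell - 1L) * bins + 1L):(cell * bins)
        nrm <- sqrt(sum(desc[sl]^2))
        if (nrm > 0) desc[sl] <- desc[sl] / nrm
    }
    attr(desc, "hog") <- list(
        variant = "dense unsigned cell histograms, L2 cell normalization",
        cellSize = as.integer(cellSize), bins = as.integer(bins),
        cells = c(nr, nc))
    desc
}

#' Extract HOG features for a set of stimuli
#'
#' @param stimuli named list of intensity matrices.
#' @param cellSize,bins see \code{\link{extractHOG}}.
#' @return numeric matrix (stimuli x descriptor length) with attribute
#'   \code{featureType = "hog"}.
#' @export
hogFeatureMatrix <- function(stimuli, cellSize = 32L, bins = 9L) {
    vecs <- lapply(stimuli, extractHOG, cellSize = cellSize, bins = bins)
    x <- do.call(rbind, lapply(vecs, as.numeric))
    rownames(x) <- names(stimuli)
    colnames(x) <- sprintf("hog%03d", seq_len(ncol(x)))
    attr(x, "featureType") <- "hog"
    attr(x, "hog") <- attr(vecs[[1L]], "hog")
    x
}
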