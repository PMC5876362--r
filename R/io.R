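#' Read and write the package's delimited interchange formats
#'
#' All tabular artifacts are tab-delimited text with header rows; metadata
#' travels in JSON sidecars.  \code{writeVoxelTable} emits the amplitude
#' matrix (stimulus-id row labels, voxel-id column headers) plus a
#' two-column \code{(voxel_id, roi)} map; \code{readVoxelTable} reverses
#' it.  \code{writeFeatureMatrix}/\code{readFeatureMatrix} carry the
#' feature-type tag and parameters in a \code{.meta.json} sidecar.
#' \code{writeActivityWeights}/\code{readActivityWeights} store
#' \code{(stimulus_id, c_x)} rows and the provenance sidecar.
#' \code{writeAccuracyTable}/\code{readAccuracyTable} store the tidy
#' accuracy records.
#'
#' @param x object to write.
#' @param path file path of the main table; sidecars derive from it.
#' @param roiPath path of the voxel-to-ROI map (default:
#'   \code{<path>.rois.tsv}).
#' @return the read functions return the reconstructed object; the write
#'   functions return \code{path} invisibly.
#' @name neuroweight-io
NULL

sidecarPath <- function(path, suffix) paste0(path, suffix)

#' @rdname neuroweight-io
#' @export
writeVoxelTable <- function(x, path, roiPath = sidecarPath(path, ".rois.tsv")) {
    m <- voxelMatrix(x)
    df <- data.frame(stimulus_id = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(voxel_id = names(voxelROIs(x)),
        roi = unname(voxelROIs(x))), roiPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' @rdname neuroweight-io
#' @export
readVoxelTable <- function(path, roiPath = sidecarPath(path, ".rois.tsv")) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$stimulus_id
    rois <- read.delim(roiPath, stringsAsFactors = FALSE)
    VoxelTable(m, stats::setNames(rois$roi, rois$voxel_id))
}

#' @rdname neuroweight-io
#' @export
writeFeatureMatrix <- function(x, path) {
    df <- data.frame(stimulus_id = rownames(x), x, check.names = FALSE,
        stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(feature_type = attr(x, "featureType"))
    if (!is.null(attr(x, "hog"))) meta$hog <- attr(x, "hog")
    jsonlite::write_json(meta, sidecarPath(path, ".meta.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname neuroweight-io
#' @export
readFeatureMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$stimulus_id
    metaPath <- sidecarPath(path, ".meta.json")
    if (file.exists(metaPath)) {
        meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
        attr(m, "featureType") <- meta$feature_type
    }
    m
}

#' @rdname neuroweight-io
#' @export
writeActivityWeights <- function(x, path) {
    write.table(data.frame(stimulus_id = names(x@weights),
        c_x = unname(x@weights)), path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    prov <- x@provenance
    prov$folds <- NULL
    jsonlite::write_json(prov, sidecarPath(path, ".meta.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname neuroweight-io
#' @export
readActivityWeights <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    metaPath <- sidecarPath(path, ".meta.json")
    prov <- if (file.exists(metaPath))
        jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
    methods::new("ActivityWeights",
        weights = stats::setNames(df$c_x, df$stimulus_id),
        provenance = as.list(prov))
}

#' @rdname neuroweight-io
#' @export
writeAccuracyTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname neuroweight-io
#' @export
readAccuracyTable <- function(path)
    read.delim(path, stringsAsFactors = FALSE)

#' Serialize and restore a trained kernel SVM model
#'
#' The model travels as a JSON container (kernel parameters, bias, dual
#' coefficients, support-vector ids, loss multipliers) plus a tab-delimited
#' support-vector matrix.  Numbers are written with 17 significant digits,
#' so the round trip is lossless to full double precision.
#'
#' @param model a \linkS4class{KernelSVMModel}.
#' @param path path of the JSON container; the support-vector matrix lives
#'   in \code{<path>.sv.tsv}.
#' @return \code{readSVMModel} returns the reconstructed model.
#' @export
writeSVMModel <- function(model, path) {
    # doubles travel as %.17g strings: decimal JSON printing is otherwise
    # not guaranteed to round-trip the last bit
    num <- function(x) sprintf("%.17g", x)
    meta <- list(loss = model@loss, gamma = num(model@gamma),
        cost = num(model@cost), bias = num(model@bias),
        coef = num(model@coef), svIds = model@svIds,
        multiplierIds = names(model@multipliers),
        multipliers = num(model@multipliers),
        objective = num(model@objective), iterations = model@iterations,
        converged = model@converged, tol = num(model@tol))
    sv <- model@sv
    if (!is.null(colnames(sv))) meta$svColnames <- colnames(sv)
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
    df <- data.frame(id = model@svIds,
        matrix(sprintf("%.17g", sv), nrow(sv), ncol(sv)),
        check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", sprintf("V%03d", seq_len(ncol(sv))))
    write.table(df, sidecarPath(path, ".sv.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSVMModel
#' @export
readSVMModel <- function(path) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- read.delim(sidecarPath(path, ".sv.tsv"), check.names = FALSE,
        colClasses = "character", stringsAsFactors = FALSE)
    sv <- as.matrix(df[, -1L, drop = FALSE])
    sv <- matrix(as.numeric(sv), nrow(df), ncol(df) - 1L,
        dimnames = list(df$id, meta$svColnames))
    methods::new("KernelSVMModel", sv = sv,
        coef = as.numeric(meta$coef), bias = as.numeric(meta$bias),
        gamma = as.numeric(meta$gamma), cost = as.numeric(meta$cost),
        multipliers = stats::setNames(as.numeric(meta$multipliers),
            meta$multiplierIds),
        svIds = as.character(meta$svIds), loss = meta$loss,
        objective = as.numeric(meta$objective),
        iterations = as.integer(meta$iterations),
        converged = meta$converged, tol = as.numeric(meta$tol))
}

#' Write stimuli as lossless grayscale PNG files
#'
#' @param stimuli named list of intensity matrices in [0, 1].
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
writeStimuliPNG <- function(stimuli, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(stimuli), function(id) {
        p <- file.path(dir, paste0(id, ".png"))
        png::writePNG(stimuli[[id]], p)
        p
    }, character(1))
    invisible(paths)
}

#' Write pixel-label maps as tab-delimited text
#'
#' One file per map: a header row of column indices, then one row of
#' category tags per pixel row.
#'
#' @param maps named list of character matrices.
#' @param dir output directory.
#' @return invisible character vector of file paths.
#' @export
writeLabelMaps <- function(maps, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(maps), function(id) {
        p <- file.path(dir, paste0(id, ".labels.tsv"))
        write.table(maps[[id]], p, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = TRUE)
        p
    }, character(1))
    invisible(paths)
}
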