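#' Construct a VoxelTable
#'
#' @param amplitudes numeric matrix of response amplitudes, stimuli in rows
#'   (rownames = stimulus ids) and voxels in columns (colnames = voxel ids).
#' @param rois character vector of ROI names, one per voxel (recycled names
#'   are not allowed); voxels outside every named ROI should be
#'   \code{"unlabeled"}.  May be named by voxel id.
#' @return A \linkS4class{VoxelTable} (unscaled).
#' @examples
#' amp <- matrix(rnorm(12), 3, 4,
#'     dimnames = list(paste0("s", 1:3), paste0("v", 1:4)))
#' vt <- VoxelTable(amp, rois = c("EBA", "EBA", "FFA", "FFA"))
#' voxelMatrix(vt)
#' @export
VoxelTable <- function(amplitudes, rois) {
    amplitudes <- as.matrix(amplitudes)
    stopifnot2(!is.null(rownames(amplitudes)) && !is.null(colnames(amplitudes)),
        "amplitude matrix needs stimulus rownames and voxel colnames")
    stopifnot2(length(rois) == ncol(amplitudes),
        "one ROI annotation per voxel is required")
    if (!is.null(names(rois)))
        rois <- rois[colnames(amplitudes)]
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(amplitude = t(amplitudes)),
        rowData = S4Vectors::DataFrame(roi = as.character(rois),
            row.names = colnames(amplitudes)))
    methods::new("VoxelTable", se, scaled = FALSE, degenerateVoxels = 0L)
}

#' Accessors for VoxelTable
#'
#' \code{voxelMatrix} returns the stimuli-by-voxels amplitude matrix;
#' \code{voxelROIs} the per-voxel ROI annotation (named by voxel id);
#' \code{stimulusIds} the stimulus ids; \code{isScaled} whether min--max
#' scaling has been applied.
#'
#' @param x a \linkS4class{VoxelTable}.
#' @return See description.
#' @name voxelMatrix
#' @export
voxelMatrix <- function(x) t(SummarizedExperiment::assay(x, "amplitude"))

#' @rdname voxelMatrix
#' @export
voxelROIs <- function(x) {
    r <- SummarizedExperiment::rowData(x)$roi
    names(r) <- rownames(x)
    r
}

#' @rdname voxelMatrix
#' @export
stimulusIds <- function(x) colnames(x)

#' @rdname voxelMatrix
#' @export
isScaled <- function(x) isTRUE(x@scaled)

setMethod("show", "VoxelTable", function(object) {
    cat("VoxelTable:", ncol(object), "stimuli x", nrow(object), "voxels\n")
    tab <- table(voxelROIs(object))
    cat("  ROIs:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    cat("  scaled:", object@scaled,
        if (object@degenerateVoxels > 0)
            sprintf(" (%d degenerate voxels set to 0)", object@degenerateVoxels)
        else "", "\n")
})

#' Min-max scale voxel amplitudes against a reference stimulus set
#'
#' Rescales every voxel (column) of the table to
#' \deqn{x'_{ij} = (x_{ij} - \min_j x_{ij}) / (\max_j x_{ij} - \min_j x_{ij}),}
#' where the per-voxel minimum and maximum are computed over the
#' \emph{reference} rows only (typically the training stimuli, so that test
#' rows cannot leak range information) and then applied to all rows.  Values
#' that fall outside [0, 1] because a non-reference row exceeds the reference
#' range are clipped.  Voxels constant over the reference rows are degenerate
#' and mapped to 0 everywhere; their count is recorded and a warning is
#' emitted.
#'
#' @param table a \linkS4class{VoxelTable} (unscaled or scaled).
#' @param referenceIds stimulus ids over which per-voxel min and max are
#'   computed; must be nonempty and present in the table.
#' @return A scaled \linkS4class{VoxelTable}.
#' @examples
#' amp <- matrix(c(2, 4, 6), 3, 1, dimnames = list(paste0("s", 1:3), "v1"))
#' vt <- minmaxScale(VoxelTable(amp, "EBA"), paste0("s", 1:3))
#' voxelMatrix(vt)  # 0, 0.5, 1
#' @export
minmaxScale <- function(table, referenceIds = stimulusIds(table)) {
    stopifnot2(length(referenceIds) > 0, "referenceIds must be nonempty")
    stopifnot2(all(referenceIds %in% stimulusIds(table)),
        "all referenceIds must be present in the table")
    m <- voxelMatrix(table)
    ref <- m[referenceIds, , drop = FALSE]
    lo <- apply(ref, 2L, min)
    hi <- apply(ref, 2L, max)
    rng <- hi - lo
    degen <- rng <= 0
    rng[degen] <- 1
    out <- sweep(sweep(m, 2L, lo, "-"), 2L, rng, "/")
    out[, degen] <- 0
    out[out < 0] <- 0
    out[out > 1] <- 1
    if (any(degen))
        warning(sum(degen), " voxel(s) constant over the reference rows; ",
            "set to 0 everywhere", call. = FALSE)
    res <- VoxelTable(out, voxelROIs(table))
    res@scaled <- TRUE
    res@degenerateVoxels <- as.integer(sum(degen))
    methods::validObject(res)
    res
}

#' Restrict a VoxelTable to the voxels of an ROI combination
#'
#' @param table a \linkS4class{VoxelTable}.
#' @param combo character vector of ROI names (an ROI combination).
#' @return A \linkS4class{VoxelTable} containing exactly the voxels annotated
#'   with the listed ROIs; stimulus order is preserved.
#' @export
restrictToROIs <- function(table, combo) {
    combo <- as.character(combo)
    ann <- unique(voxelROIs(table))
    missing <- setdiff(combo, ann)
    stopifnot2(length(missing) == 0,
        paste0("unknown ROI(s): ", paste(missing, collapse = ", ")))
    keep <- voxelROIs(table) %in% combo
    stopifnot2(any(keep), "combination has no voxels")
    table[keep, ]
}

#' Canonical key for an ROI combination
#'
#' ROI names sorted alphabetically and joined with \code{"+"}; used as the
#' stable identifier for joining accuracy records across modules.
#'
#' @param combo character vector of ROI names.
#' @return character scalar key.
#' @export
roiKey <- function(combo) paste(sort(unique(as.character(combo))), collapse = "+")

#' Enumerate all non-empty ROI combinations
#'
#' For the seven higher-level visual ROIs this yields the 127 ways the
#' regions can be combined; 64 of them contain any one fixed ROI.
#' Combinations are returned in a deterministic canonical order: by subset
#' size, then alphabetically by key.
#'
#' @param rois character vector of ROI names, duplicate-free and nonempty.
#' @return Named list of character vectors; names are canonical keys
#'   (\code{\link{roiKey}}).
#' @examples
#' length(enumerateROICombinations(c("EBA", "FFA", "PPA")))  # 7
#' @export
enumerateROICombinations <- function(rois) {
    rois <- as.character(rois)
    stopifnot2(length(rois) > 0, "ROI universe must be nonempty")
    stopifnot2(!anyDuplicated(rois), "ROI names must be duplicate-free")
    rois <- sort(rois)
    k <- length(rois)
    combos <- list()
    for (size in seq_len(k)) {
        idx <- utils::combn(k, size, simplify = FALSE)
        cc <- lapply(idx, function(i) rois[i])
        keys <- vapply(cc, roiKey, character(1))
        cc <- cc[order(keys)]
        combos <- c(combos, cc)
    }
    names(combos) <- vapply(combos, roiKey, character(1))
    combos
}
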