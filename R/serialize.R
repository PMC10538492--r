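INDEX_FORMAT <- "docarray-index"
INDEX_VERSION <- "1"

.indexContent <- function(index) {
    list(format = INDEX_FORMAT, version = index@version,
         labels = index@labels,
         alphabet = index@structures@concat@alphabet,
         widthCap = if (is.na(index@widthCap)) NULL else index@widthCap,
         text = index@structures@concat@text,
         docStart = index@structures@concat@docStart,
         runStart = index@runs@start, runEnd = index@runs@end,
         runChar = index@runs@char,
         saStart = index@saStart, saEnd = index@saEnd,
         profStart = unname(index@profStart),
         profEnd = unname(index@profEnd))
}

#' Content hash of an index
#'
#' MD5 over the canonical JSON serialization of the index content
#' (text, labels, runs, samples, profiles, cap, format version); stable
#' across sessions and independent of any build seed.
#'
#' @param index a [DocProfileIndex-class].
#' @return hex string.
#' @export
indexHash <- function(index) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(.indexContent(index), tmp, auto_unbox = TRUE,
                         digits = NA)
    unname(tools::md5sum(tmp))
}

#' Save an index to a versioned JSON container
#'
#' The container stores the concatenated text, labels, run-length BWT,
#' SA samples, sampled profiles, truncation cap, a format-version field
#' and a content hash.  [loadIndex()] rebuilds the suffix structures from
#' the text (deterministically) and restores the stored profiles, so a
#' save/load round trip reproduces the index content exactly.
#'
#' @param index a [DocProfileIndex-class].
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
saveIndex <- function(index, path) {
    stopifnot(is(index, "DocProfileIndex"))
    validObject(index)
    obj <- .indexContent(index)
    obj$contentHash <- indexHash(index)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Load an index saved by [saveIndex()]
#'
#' @param path file written by [saveIndex()].
#' @return a [DocProfileIndex-class].
#' @export
loadIndex <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, INDEX_FORMAT))
        stop("not a ", INDEX_FORMAT, " file: ", path)
    if (!identical(obj$version, INDEX_VERSION))
        stop("unsupported index format version: ", obj$version)
    labels <- as.character(obj$labels)
    d <- length(labels)
    ct <- new("ConcatenatedText", text = obj$text,
              docStart = as.integer(obj$docStart),
              n = nchar(obj$text), labels = labels,
              alphabet = as.character(obj$alphabet))
    ss <- buildSuffixStructures(ct)
    runs <- new("BWTRuns", start = as.integer(obj$runStart),
                end = as.integer(obj$runEnd),
                char = as.character(obj$runChar))
    pS <- obj$profStart; pE <- obj$profEnd
    if (d == 1L) { pS <- matrix(pS, nrow = 1L); pE <- matrix(pE, nrow = 1L) }
    storage.mode(pS) <- "integer"
    storage.mode(pE) <- "integer"
    rownames(pS) <- rownames(pE) <- labels
    idx <- new("DocProfileIndex", structures = ss, runs = runs,
               saStart = as.integer(obj$saStart),
               saEnd = as.integer(obj$saEnd),
               profStart = pS, profEnd = pE,
               widthCap = if (is.null(obj$widthCap)) NA_integer_
                          else as.integer(obj$widthCap),
               labels = labels, version = as.character(obj$version),
               cache = new.env(parent = emptyenv()))
    validObject(idx)
    if (!is.null(obj$contentHash) &&
        !identical(indexHash(idx), obj$contentHash))
        stop("index content hash mismatch: file corrupted?")
    idx
}
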