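#' Number of documents (classes) in an object
#' @param x a DocumentCollection, ConcatenatedText or DocProfileIndex.
#' @return integer d.
#' @export
setGeneric("nDocs", function(x) standardGeneric("nDocs"))

#' Document class labels
#' @param x a DocumentCollection, ConcatenatedText or DocProfileIndex.
#' @return character vector of length d.
#' @export
setGeneric("docLabels", function(x) standardGeneric("docLabels"))

#' Total length of the indexed text (documents plus separators)
#' @param x an object carrying a concatenated text.
#' @return integer n.
#' @export
setGeneric("textLength", function(x) standardGeneric("textLength"))

#' Number of maximal equal-letter BWT runs
#' @param x a BWTRuns or DocProfileIndex.
#' @return integer r.
#' @export
setGeneric("runCount", function(x) standardGeneric("runCount"))

#' Profile truncation cap
#' @param x a DocProfileIndex.
#' @return integer cap, or NA if the index is untruncated.
#' @export
setGeneric("widthCap", function(x) standardGeneric("widthCap"))

#' @describeIn nDocs number of documents in a collection
#' @export
setMethod("nDocs", "DocumentCollection", function(x) length(x@docs))
#' @describeIn nDocs number of documents behind a concatenation
#' @export
setMethod("nDocs", "ConcatenatedText", function(x) length(x@labels))
#' @describeIn nDocs number of document classes in an index
#' @export
setMethod("nDocs", "DocProfileIndex", function(x) length(x@labels))

#' @describeIn docLabels labels of a collection
#' @export
setMethod("docLabels", "DocumentCollection", function(x) x@labels)
#' @describeIn docLabels labels behind a concatenation
#' @export
setMethod("docLabels", "ConcatenatedText", function(x) x@labels)
#' @describeIn docLabels labels of an index
#' @export
setMethod("docLabels", "DocProfileIndex", function(x) x@labels)

#' @describeIn textLength length of a concatenation
#' @export
setMethod("textLength", "ConcatenatedText", function(x) x@n)
#' @describeIn textLength length of the text behind suffix structures
#' @export
setMethod("textLength", "SuffixStructures", function(x) x@concat@n)
#' @describeIn textLength length of the text behind an index
#' @export
setMethod("textLength", "DocProfileIndex", function(x) x@structures@concat@n)

#' @describeIn runCount run count of a run-length BWT
#' @export
setMethod("runCount", "BWTRuns", function(x) length(x@start))
#' @describeIn runCount run count of an index
#' @export
setMethod("runCount", "DocProfileIndex", function(x) length(x@runs@start))

#' @describeIn widthCap cap of an index (NA if untruncated)
#' @export
setMethod("widthCap", "DocProfileIndex", function(x) x@widthCap)

setMethod("show", "DocumentCollection", function(object) {
    cat(sprintf("DocumentCollection: %d document(s), alphabet {%s}\n",
                nDocs(object), paste(object@alphabet, collapse = ",")))
    len <- nchar(object@docs)
    for (i in seq_len(min(6L, nDocs(object))))
        cat(sprintf("  [%d] %s (%d chars)\n", i, object@labels[i], len[i]))
    if (nDocs(object) > 6L) cat(sprintf("  ... and %d more\n",
                                        nDocs(object) - 6L))
})

setMethod("show", "ConcatenatedText", function(object) {
    cat(sprintf("ConcatenatedText: n = %d, d = %d document(s)\n",
                object@n, nDocs(object)))
})

setMethod("show", "SuffixStructures", function(object) {
    cat(sprintf("SuffixStructures over n = %d positions, d = %d document(s)\n",
                textLength(object), nDocs(object@concat)))
})

setMethod("show", "BWTRuns", function(object) {
    cat(sprintf("BWTRuns: r = %d run(s) over %d positions\n",
                runCount(object), object@end[runCount(object)]))
})

setMethod("show", "DocProfileIndex", function(object) {
    cat(sprintf(paste0("DocProfileIndex: n = %d, d = %d, r = %d ",
                       "(%d sampled profiles)\n"),
                textLength(object), nDocs(object), runCount(object),
                2L * runCount(object)))
    cap <- widthCap(object)
    cat(sprintf("  width cap: %s\n", if (is.na(cap)) "none" else cap))
    cat(sprintf("  classes: %s\n",
                paste(utils::head(docLabels(object), 8L), collapse = ", ")))
})
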