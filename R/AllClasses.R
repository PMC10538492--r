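#' Collection of documents over a common alphabet
#'
#' A \code{DocumentCollection} holds the d documents (one string per class:
#' a strain genome, or a concatenated group of related genomes) to be
#' indexed, together with human-readable class labels.  Documents must be
#' nonempty, drawn from \code{alphabet}, and free of the separator
#' character \code{"#"}.
#'
#' @slot docs character vector of d document strings.
#' @slot labels character vector of d unique class labels.
#' @slot alphabet character vector of allowed symbols (default A, C, G, T, N).
#'
#' @seealso [DocumentCollection()], [readDocumentCollection()],
#'   [concatenateDocs()]
#' @export
setClass("DocumentCollection",
    representation(docs = "character", labels = "character",
                   alphabet = "character"))

setValidity("DocumentCollection", function(object) {
    d <- length(object@docs)
    if (d < 1L) return("need at least one document")
    if (length(object@labels) != d) return("labels must match documents")
    if (anyDuplicated(object@labels)) return("duplicate document labels")
    if (any(!nzchar(object@docs))) return("empty document")
    if (any(grepl(DOC_SEP, object@docs, fixed = TRUE)))
        return(sprintf("documents must not contain the separator '%s'",
                       DOC_SEP))
    used <- unique(unlist(strsplit(object@docs, "", fixed = TRUE)))
    bad <- setdiff(used, object@alphabet)
    if (length(bad))
        return(sprintf("characters outside the alphabet: %s",
                       paste(bad, collapse = ", ")))
    TRUE
})

#' Concatenation of a document collection
#'
#' The documents joined in order, each followed by one separator, plus the
#' document boundary map.  Separators compare lexicographically smaller
#' than all alphabet symbols; separators at distinct positions compare by
#' position (earlier smaller), so all suffixes of the concatenation are
#' distinct.
#'
#' @slot text the concatenated string of length n.
#' @slot docStart 1-based start offset of each document in \code{text}.
#' @slot n total length (sum of document lengths plus d separators).
#' @slot labels,alphabet inherited from the collection.
#' @export
setClass("ConcatenatedText",
    representation(text = "character", docStart = "integer", n = "integer",
                   labels = "character", alphabet = "character"))

setValidity("ConcatenatedText", function(object) {
    if (length(object@text) != 1L) return("text must be a single string")
    if (nchar(object@text) != object@n) return("n does not match text")
    chars <- strsplit(object@text, "", fixed = TRUE)[[1L]]
    d <- length(object@labels)
    if (length(object@docStart) != d) return("docStart must have d entries")
    if (chars[object@n] != DOC_SEP) return("text must end with a separator")
    ends <- c(object@docStart[-1L] - 1L, object@n)
    if (any(chars[ends] != DOC_SEP))
        return("each document must end with one separator")
    TRUE
})

#' Classical suffix structures over a concatenated collection
#'
#' Suffix array, inverse suffix array, LCP array, BWT, LF-mapping and
#' document array of the concatenation, built once and shared by the
#' profile constructions and the query engine.  \code{codes} is the
#' integer-mapped text realising the separator ordering (separator at the
#' k-th document boundary gets code k, alphabet symbol j gets d + j).
#'
#' @slot concat the [ConcatenatedText-class] the structures cover.
#' @slot sa,isa,lcp,lf,da integer vectors of length n (all 1-based).
#' @slot bwt the Burrows-Wheeler transform as a single string; all
#'   separators are printed as \code{"#"}.
#' @slot codes integer-mapped text used for suffix comparisons.
#' @export
setClass("SuffixStructures",
    representation(concat = "ConcatenatedText", sa = "integer",
                   isa = "integer", lcp = "integer", bwt = "character",
                   lf = "integer", da = "integer", codes = "integer"))

setValidity("SuffixStructures", function(object) {
    n <- object@concat@n
    for (nm in c("sa", "isa", "lcp", "lf", "da", "codes"))
        if (length(slot(object, nm)) != n)
            return(sprintf("%s must have length n", nm))
    if (!identical(object@sa[object@isa], seq_len(n)))
        return("isa is not the inverse of sa")
    if (object@lcp[1L] != 0L) return("LCP[1] must be 0")
    TRUE
})

#' Maximal equal-letter runs of a BWT
#'
#' @slot start,end 1-based first and last position of each run.
#' @slot char the run character (separators unified as \code{"#"}).
#' @export
setClass("BWTRuns",
    representation(start = "integer", end = "integer", char = "character"))

setValidity("BWTRuns", function(object) {
    r <- length(object@start)
    if (length(object@end) != r || length(object@char) != r)
        return("start, end and char must have equal length")
    if (r == 0L) return("need at least one run")
    if (any(object@end < object@start)) return("run end before run start")
    if (r > 1L) {
        if (any(object@start[-1L] != object@end[-r] + 1L))
            return("runs must be consecutive and covering")
        if (any(object@char[-1L] == object@char[-r]))
            return("adjacent runs must differ (runs not maximal)")
    }
    TRUE
})

#' Queryable document array profile index
#'
#' The run-length BWT together with SA samples and document array profiles
#' stored at the 2r run boundaries: for a run BWT[s..e], the profiles at
#' LF(s) and LF(e).  After a backward search, thresholding the maintained
#' profile at the match length yields the full document listing in d
#' comparisons.  With \code{widthCap} set, stored values are truncated to
#' the cap (listings remain exact for match lengths up to the cap).
#'
#' @slot structures the underlying [SuffixStructures-class] (plain arrays;
#'   kept for the locate baseline and MEM extraction).
#' @slot runs the [BWTRuns-class] of the BWT.
#' @slot saStart,saEnd SA samples at run starts / run ends.
#' @slot profStart,profEnd d x r integer matrices: the profile at LF(s)
#'   (resp. LF(e)) for each run, one column per run, rows named by label.
#' @slot widthCap positive integer truncation cap, or NA for none.
#' @slot labels document class labels.
#' @slot version serialization format version.
#' @slot cache environment holding derived query tables (not serialized).
#' @seealso [buildDocProfileIndex()], [queryWithProfiles()],
#'   [truncateIndex()], [saveIndex()]
#' @export
setClass("DocProfileIndex",
    representation(structures = "SuffixStructures", runs = "BWTRuns",
                   saStart = "integer", saEnd = "integer",
                   profStart = "matrix", profEnd = "matrix",
                   widthCap = "integer", labels = "character",
                   version = "character", cache = "environment"))

setValidity("DocProfileIndex", function(object) {
    d <- length(object@labels)
    r <- length(object@runs@start)
    if (!identical(dim(object@profStart), c(d, r)) ||
        !identical(dim(object@profEnd), c(d, r)))
        return("profile matrices must be d x r")
    if (length(object@saStart) != r || length(object@saEnd) != r)
        return("need one SA sample per run boundary")
    if (anyNA(object@profStart) || anyNA(object@profEnd))
        return("profile matrices contain missing values")
    cap <- object@widthCap
    if (!is.na(cap)) {
        if (cap < 1L) return("widthCap must be >= 1")
        if (max(object@profStart) > cap || max(object@profEnd) > cap)
            return("stored profile values exceed widthCap")
    }
    TRUE
})
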