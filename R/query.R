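.engine <- function(index) {
    stopifnot(is(index, "DocProfileIndex"))
    if (!is.null(index@cache$eng)) return(index@cache$eng)
    ss <- index@structures
    core <- .engineCore(ss)
    runs <- index@runs
    r <- runCount(runs)
    runCls <- match(runs@char, ss@concat@alphabet)
    runCls[is.na(runCls)] <- 0L
    runIdOfPos <- rep.int(seq_len(r), runs@end - runs@start + 1L)
    sigma <- core$sigma
    cStartPos <- cEndPos <- cStartRid <- cEndRid <- vector("list", sigma)
    for (c in seq_len(sigma)) {
        w <- which(runCls == c)
        cStartPos[[c]] <- runs@start[w]
        cStartRid[[c]] <- w
        cEndPos[[c]] <- runs@end[w]
        cEndRid[[c]] <- w
    }
    pS <- index@profStart; storage.mode(pS) <- "integer"
    pE <- index@profEnd; storage.mode(pE) <- "integer"
    eng <- c(core, list(runCls = as.integer(runCls),
                        runIdOfPos = as.integer(runIdOfPos),
                        cStartPos = cStartPos, cStartRid = cStartRid,
                        cEndPos = cEndPos, cEndRid = cEndRid,
                        profStart = unname(pS), profEnd = unname(pE)))
    index@cache$eng <- eng
    eng
}

.patternClasses <- function(pattern, alphabet) {
    match(.chars(toupper(pattern)), alphabet)
}

#' Backward search with profile maintenance
#'
#' Processes the pattern right to left.  At each step, if the current SA
#' interval contains a run boundary of the next character, the profile
#' sample stored at that boundary is adopted (the lowest-position boundary,
#' start sample on ties); if the interval is strictly inside a run of that
#' character, all d profile entries are incremented.  The final profile
#' P satisfies: P[j] >= m if and only if the pattern occurs in document j,
#' so [listDocuments()] with the pattern length yields the listing with d
#' comparisons, independent of the number of occurrences.
#'
#' @param index a [DocProfileIndex-class].
#' @param pattern single nonempty string over the alphabet.  Characters
#'   outside the alphabet make the pattern absent (empty result), not an
#'   error; an empty pattern is rejected.
#' @return list with \code{found} (logical), \code{interval} \code{c(s, e)}
#'   or \code{integer(0)}, \code{profile} (named d-vector, NULL when
#'   absent) and \code{matchedLength} (the pattern length m).
#' @examples
#' idx <- buildDocProfileIndex(
#'     DocumentCollection(c(a = "GATTACA", b = "GATA", c = "TAGA")))
#' q <- queryWithProfiles(idx, "GAT")
#' listDocuments(q$profile, q$matchedLength)
#' @export
queryWithProfiles <- function(index, pattern) {
    stopifnot(is(index, "DocProfileIndex"), length(pattern) == 1L)
    m <- nchar(pattern)
    if (m < 1L) stop("empty pattern: the empty string occurs everywhere")
    eng <- .engine(index)
    cls <- .patternClasses(pattern, index@structures@concat@alphabet)
    res <- query_profiles_cpp(as.integer(cls), eng)
    if (!res$found)
        return(list(found = FALSE, interval = integer(0), profile = NULL,
                    matchedLength = m))
    prof <- res$prof
    names(prof) <- index@labels
    list(found = TRUE, interval = c(res$s, res$e), profile = prof,
         matchedLength = m)
}

#' Document listing from a profile
#'
#' A pattern of length \code{ell} with final profile \code{profile} occurs
#' in document j exactly when \code{profile[j] >= ell}: one comparison per
#' document, O(d) total.
#'
#' @param profile d-vector of profile values.
#' @param ell match length (>= 1).
#' @return sorted integer document indices (named if the profile is);
#'   attribute \code{"ops"} records the d comparisons performed.
#' @examples
#' listDocuments(c(1, 2, 4), 2)  # documents 2 and 3
#' @export
listDocuments <- function(profile, ell) {
    stopifnot(ell >= 1L, length(profile) >= 1L)
    out <- which(profile >= ell)
    attr(out, "ops") <- length(profile)
    out
}

#' Document listing via locate queries (baseline)
#'
#' Backward-searches the pattern, enumerates all occ occurrences through
#' the SA interval, maps each to its document and returns the distinct
#' set.  The work grows with occ; used as the comparison baseline and as a
#' second oracle for [queryWithProfiles()] + [listDocuments()].
#'
#' @param index a [DocProfileIndex-class].
#' @param pattern single nonempty string.
#' @return sorted integer document indices; attributes \code{"occ"} (number
#'   of occurrences) and \code{"ops"} (per-occurrence operations, = occ).
#' @export
listDocumentsViaLocate <- function(index, pattern) {
    stopifnot(is(index, "DocProfileIndex"), nchar(pattern) >= 1L)
    ss <- index@structures
    eng <- .engine(index)
    iv <- c(1L, eng$n)
    cls <- .patternClasses(pattern, ss@concat@alphabet)
    for (cl in rev(cls)) {
        iv <- .stepEng(eng, cl, iv)
        if (!length(iv)) {
            out <- integer(0)
            attr(out, "occ") <- 0L
            attr(out, "ops") <- 0L
            return(out)
        }
    }
    hits <- ss@da[iv[1L]:iv[2L]]
    out <- sort(unique(hits))
    attr(out, "occ") <- length(hits)
    attr(out, "ops") <- length(hits)
    out
}

#' One containing document for a match interval (baseline lookup)
#'
#' The sampled-document-array baseline reports a single document per exact
#' match: the document of the first run start inside the SA interval; if
#' the interval contains no run start, the interval's last position when it
#' is a run end; otherwise the document of the interval's first position
#' (the toehold a run-length index carries through backward search).  The
#' returned document always contains the match.
#'
#' @param index a [DocProfileIndex-class].
#' @param interval \code{c(s, e)} SA interval of a match.
#' @return single integer document index.
#' @export
sampledDaLookup <- function(index, interval) {
    stopifnot(is(index, "DocProfileIndex"), length(interval) == 2L,
              interval[1L] >= 1L, interval[1L] <= interval[2L])
    runs <- index@runs
    s <- interval[1L]; e <- interval[2L]
    da <- index@structures@da
    w <- which(runs@start >= s & runs@start <= e)
    if (length(w)) return(da[runs@start[w[1L]]])
    if (any(runs@end == e)) return(da[e])
    da[s]
}

#' Matching statistics of a read against the indexed text
#'
#' For each read position p, the length of the longest prefix of
#' \code{read[p..]} occurring anywhere in the text (matches never cross a
#' document separator).  Characters outside the alphabet match nothing.
#'
#' @param index a [DocProfileIndex-class].
#' @param read single read string.
#' @return integer vector of per-position match lengths.
#' @export
matchingStatistics <- function(index, read) {
    stopifnot(is(index, "DocProfileIndex"), nchar(read) >= 1L)
    ss <- index@structures
    d <- nDocs(index)
    cls <- .patternClasses(read, ss@concat@alphabet)
    codes <- ifelse(is.na(cls), -1L, d + cls)
    matching_stats_cpp(as.integer(codes), ss@codes, ss@sa)
}

#' Maximal exact matches of a read, with intervals and profiles
#'
#' Extracts all maximal exact matches (MEMs) of length at least
#' \code{minLen} between the read and the indexed text: right-maximal by
#' the matching statistics, left-maximal where the previous position's
#' match does not cover the current one.  Each MEM carries its SA interval
#' and its final document array profile, so its listing is
#' \code{which(profile >= length)}.
#'
#' @param index a [DocProfileIndex-class].
#' @param read single read string.
#' @param minLen minimum MEM length to report (default 15).
#' @return list with \code{mems}, a data.frame of \code{start} (1-based
#'   offset in the read), \code{len}, \code{s}, \code{e}; \code{profiles},
#'   a d x nrow(mems) matrix (rows named by label); and \code{ms}, the
#'   matching statistics.
#' @export
findMems <- function(index, read, minLen = 15L) {
    stopifnot(is(index, "DocProfileIndex"), nchar(read) >= 1L, minLen >= 1L)
    ss <- index@structures
    cls <- .patternClasses(read, ss@concat@alphabet)
    out <- read_mems_cpp(as.integer(cls), as.integer(minLen), .engine(index),
                         ss@codes, ss@sa)
    prof <- out$prof
    rownames(prof) <- index@labels
    list(mems = data.frame(start = out$start, len = out$len,
                           s = out$s, e = out$e),
         profiles = prof, ms = out$ms)
}
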