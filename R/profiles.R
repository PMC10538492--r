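#' Full document array profile matrix, by definition (quadratic oracle)
#'
#' Evaluates, for every BWT position i and document j, the maximum
#' longest-common-prefix between the suffix at SA[i] and all suffixes of
#' document j, by direct pairwise comparison.  The self-match makes
#' \code{P[i, DA[i]]} equal the length of the suffix at SA[i] (including
#' its separator).  This is the ground truth the other constructions are
#' checked against; it is quadratic and intended for small inputs.
#'
#' @param ss a [SuffixStructures-class].
#' @return n x d integer matrix, columns named by document label.
#' @seealso [profilesTwoPass()], [buildDocProfileIndex()]
#' @export
profilesNaive <- function(ss) {
    stopifnot(is(ss, "SuffixStructures"))
    P <- profiles_naive_cpp(ss@codes, ss@sa, ss@da,
                            length(ss@concat@labels))
    colnames(P) <- ss@concat@labels
    P
}

#' Full document array profile matrix via predecessor/successor passes
#'
#' For each row, the best lcp with a document comes from the nearest
#' preceding or nearest following suffix of that document in SA order, so
#' two linear scans chaining running minima of the LCP array reproduce the
#' defining maximum exactly.
#'
#' @inheritParams profilesNaive
#' @return n x d integer matrix, equal to [profilesNaive()].
#' @export
profilesTwoPass <- function(ss) {
    stopifnot(is(ss, "SuffixStructures"))
    P <- profiles_two_pass_cpp(ss@sa, ss@lcp, ss@da,
                               length(ss@concat@labels))
    colnames(P) <- ss@concat@labels
    P
}

#' Streaming construction of the run-boundary profile samples
#'
#' Single left-to-right scan over (BWT, SA, LCP, DA) maintaining the Pred
#' table, the queue of pending positions with their incomplete profiles,
#' and the per-(document, character) counters that detect when a pending
#' profile can no longer improve.  Emits, for every BWT run (s, e), the
#' profiles at LF(s) and LF(e).
#'
#' @param ss a [SuffixStructures-class].
#' @param runs optional precomputed [BWTRuns-class].
#' @param check when TRUE, re-derive the queue counters from the queue at
#'   every step and record that they matched (instrumentation used by the
#'   tests; slows the scan down).
#' @return list with d x r matrices \code{profStart}, \code{profEnd}, and
#'   scan statistics \code{maxQueue} (peak pending-queue length),
#'   \code{flushed} (profiles completed only by the end-of-scan flush) and
#'   \code{lqcOk} (counter invariant held at every step; TRUE trivially
#'   when \code{check = FALSE}).
#' @export
profilesStreaming <- function(ss, runs = bwtRuns(ss), check = FALSE) {
    stopifnot(is(ss, "SuffixStructures"), is(runs, "BWTRuns"))
    n <- ss@concat@n
    d <- length(ss@concat@labels)
    sigma <- length(ss@concat@alphabet)
    r <- runCount(runs)
    runId <- rep.int(seq_len(r), runs@end - runs@start + 1L)
    isStart <- isEnd <- logical(n)
    isStart[runs@start] <- TRUE
    isEnd[runs@end] <- TRUE
    chars <- .chars(ss@bwt)
    bwtcls <- match(chars, ss@concat@alphabet)
    bwtcls[is.na(bwtcls)] <- 0L
    daLF <- ss@da[ss@lf]
    out <- profiles_streaming_cpp(ss@sa, ss@lcp, as.integer(bwtcls), daLF,
                                  as.integer(runId), isStart, isEnd,
                                  d, sigma, r, check)
    rownames(out$profStart) <- rownames(out$profEnd) <- ss@concat@labels
    out
}

#' Sample a full profile matrix at the run boundaries
#'
#' Reference sampler: for every run (s, e) takes the rows LF(s) and LF(e)
#' of a full profile matrix.  Used to cross-check the streaming
#' construction against [profilesNaive()] / [profilesTwoPass()].
#'
#' @param P n x d full profile matrix.
#' @param runs a [BWTRuns-class].
#' @param lf the LF-mapping of the same text.
#' @return list of d x r matrices \code{profStart}, \code{profEnd}.
#' @export
sampleProfiles <- function(P, runs, lf) {
    stopifnot(is(runs, "BWTRuns"), nrow(P) == length(lf))
    list(profStart = t(P[lf[runs@start], , drop = FALSE]),
         profEnd = t(P[lf[runs@end], , drop = FALSE]))
}

#' Build the queryable document array profile index
#'
#' Runs the streaming construction over the suffix structures and packages
#' the run-length BWT, the SA samples and the 2r sampled profiles into a
#' [DocProfileIndex-class].
#'
#' @param x a [DocumentCollection-class], [ConcatenatedText-class] or
#'   [SuffixStructures-class].
#' @param cap optional truncation cap (e.g. 255); stored values are
#'   truncated to \code{min(value, cap)}.  NA keeps full width.
#' @param selfcheck when TRUE, additionally build the profiles by the
#'   definitional (small n) or two-pass construction and stop if the
#'   sampled values disagree anywhere.
#' @return a [DocProfileIndex-class].
#' @examples
#' idx <- buildDocProfileIndex(
#'     DocumentCollection(c(a = "GATTACA", b = "GATA", c = "TAGA")))
#' idx
#' @export
buildDocProfileIndex <- function(x, cap = NA, selfcheck = FALSE) {
    ss <- if (is(x, "SuffixStructures")) x else buildSuffixStructures(x)
    runs <- bwtRuns(ss)
    st <- profilesStreaming(ss, runs)
    if (selfcheck) {
        P <- if (ss@concat@n <= 1000L) profilesNaive(ss)
             else profilesTwoPass(ss)
        ref <- sampleProfiles(P, runs, ss@lf)
        if (!identical(unname(st$profStart), unname(ref$profStart)) ||
            !identical(unname(st$profEnd), unname(ref$profEnd)))
            stop("selfcheck failed: streaming profiles differ from the ",
                 "definitional construction")
    }
    idx <- new("DocProfileIndex", structures = ss, runs = runs,
               saStart = ss@sa[runs@start], saEnd = ss@sa[runs@end],
               profStart = st$profStart, profEnd = st$profEnd,
               widthCap = NA_integer_, labels = ss@concat@labels,
               version = "1", cache = new.env(parent = emptyenv()))
    if (!is.na(cap)) idx <- truncateIndex(idx, cap) else validObject(idx)
    idx
}

#' Truncate stored profile widths
#'
#' Replaces every stored profile value v by min(v, cap), so each entry
#' fits in ceiling(log2(cap + 1)) bits (8 bits for the default cap 255).
#' Document listings are unchanged for match lengths up to the cap.
#'
#' @param index a [DocProfileIndex-class].
#' @param cap positive integer cap (default 255).
#' @return the truncated index.
#' @export
truncateIndex <- function(index, cap = 255L) {
    stopifnot(is(index, "DocProfileIndex"))
    cap <- as.integer(cap)
    if (is.na(cap) || cap < 1L) stop("cap must be a positive integer")
    index@profStart[] <- pmin(index@profStart, cap)
    index@profEnd[] <- pmin(index@profEnd, cap)
    index@widthCap <- cap
    index@cache <- new.env(parent = emptyenv())
    validObject(index)
    index
}

#' Minimal substring length confined to a run interval
#'
#' For a maximal equal-letter run BWT[s..e], the length of the smallest
#' substring whose occurrences all fall inside SA[s..e] is
#' \code{max(LCP[s], LCP[e + 1]) + 1}, with \code{LCP[n + 1] = 0} by
#' convention.
#'
#' @param lcp the LCP array.
#' @param s,e run boundaries (1-based).
#' @return integer length.
#' @examples
#' minRunSubstringLength(c(0, 0, 1, 0, 2, 1), 4, 5)  # max(0, 1) + 1 = 2
#' @export
minRunSubstringLength <- function(lcp, s, e) {
    stopifnot(s >= 1L, e >= s, e <= length(lcp))
    lcpNext <- if (e + 1L <= length(lcp)) lcp[e + 1L] else 0L
    as.integer(max(lcp[s], lcpNext) + 1L)
}

#' Guaranteed profile update under an LF step within a run
#'
#' When every occurrence of a length-\code{ell} substring lies inside the
#' run, profile entries at least \code{ell} grow by exactly one under the
#' LF step, while the remaining entries may not grow by more than one.
#' This applies the guaranteed part: +1 to entries >= \code{ell}.
#'
#' @param profile integer profile vector.
#' @param ell minimal confined substring length of the run.
#' @return updated profile vector.
#' @examples
#' incrementConfined(c(1, 2, 4), 2)  # c(1, 3, 5)
#' @export
incrementConfined <- function(profile, ell) {
    stopifnot(ell >= 1L)
    ifelse(profile >= ell, profile + 1L, profile)
}

#' Check the LF-step bounds on a pair of profiles
#'
#' Verifies, for a profile before and after one LF step taken from inside
#' a run with confined length \code{ell}, the monotone bound
#' \code{after[j] <= before[j] + 1} for all j and the exact increment
#' \code{after[j] == before[j] + 1} for all j with \code{before[j] >= ell}.
#'
#' @param before,after profile vectors of equal length.
#' @param ell confined substring length (omit to check only the bound).
#' @return TRUE if the applicable conditions hold, else FALSE.
#' @export
checkLfStepBounds <- function(before, after, ell = NULL) {
    stopifnot(length(before) == length(after))
    if (any(after > before + 1L)) return(FALSE)
    if (!is.null(ell)) {
        idx <- which(before >= ell)
        if (any(after[idx] != before[idx] + 1L)) return(FALSE)
    }
    TRUE
}
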