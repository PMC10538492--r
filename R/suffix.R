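.chars <- function(text) strsplit(text, "", fixed = TRUE)[[1L]]

# integer-mapped text: k-th separator -> k, alphabet symbol j -> d + j
.textCodes <- function(chars, alphabet, d) {
    codes <- match(chars, alphabet) + d
    sep <- which(chars == DOC_SEP)
    stopifnot(length(sep) == d)
    codes[sep] <- seq_len(d)
    storage.mode(codes) <- "integer"
    codes
}

#' Build suffix array, LCP, BWT, LF and document array
#'
#' Constructs the classical suffix structures over the concatenation with
#' distinct-separator semantics: the suffix array sorts all n (distinct)
#' suffixes, the LCP array never extends across a separator, the BWT is
#' given by \code{BWT[i] = text[SA[i] - 1]} (wrapping at position 1), the
#' LF-mapping by \code{LF[i] = ISA[(SA[i] - 2) mod n + 1]}, and the
#' document array by the document containing \code{SA[i]}.
#'
#' @param x a [ConcatenatedText-class] or [DocumentCollection-class].
#' @return a [SuffixStructures-class].
#' @examples
#' ss <- buildSuffixStructures(DocumentCollection("A"))
#' ss@sa   # c(2, 1): "#" sorts before "A#"
#' @export
buildSuffixStructures <- function(x) {
    if (is(x, "DocumentCollection")) x <- concatenateDocs(x)
    stopifnot(is(x, "ConcatenatedText"))
    chars <- .chars(x@text)
    d <- length(x@labels)
    n <- x@n
    codes <- .textCodes(chars, x@alphabet, d)
    sa <- sa_build_cpp(codes)
    isa <- integer(n); isa[sa] <- seq_len(n)
    lcp <- lcp_kasai_cpp(codes, sa)
    prev <- ifelse(sa == 1L, n, sa - 1L)
    bwt <- paste0(chars[prev], collapse = "")
    lf <- isa[(sa - 2L) %% n + 1L]
    da <- findInterval(sa, x@docStart)
    new("SuffixStructures", concat = x, sa = sa, isa = isa, lcp = lcp,
        bwt = bwt, lf = lf, da = as.integer(da), codes = codes)
}

#' Maximal equal-letter runs of the BWT
#'
#' All separator characters count as the same run character \code{"#"}, so
#' consecutive separators form a single run (the "run of separators" whose
#' positions are the only ones where \code{DA[i] != DA[LF(i)]}).
#'
#' @param x a [SuffixStructures-class] or a plain BWT string.
#' @return a [BWTRuns-class].
#' @export
bwtRuns <- function(x) {
    bwt <- if (is(x, "SuffixStructures")) x@bwt else as.character(x)
    stopifnot(nzchar(bwt))
    rl <- rle(.chars(bwt))
    e <- as.integer(cumsum(rl$lengths))
    s <- as.integer(e - rl$lengths + 1L)
    new("BWTRuns", start = s, end = e, char = rl$values)
}

#' One step of backward search
#'
#' Maps the SA interval of the current pattern to the interval of
#' \code{c . pattern}.  With \code{interval = NULL} the full range is used,
#' so the first step returns the interval of the single character \code{c}.
#' A character outside the alphabet, or one absent from the interval,
#' yields an empty result (\code{integer(0)}), not an error.
#'
#' @param x a [SuffixStructures-class] or [DocProfileIndex-class].
#' @param char single character to prepend.
#' @param interval integer vector \code{c(s, e)} or NULL for the full range.
#' @return \code{c(s, e)} of the extended pattern, or \code{integer(0)}.
#' @export
backwardStep <- function(x, char, interval = NULL) {
    ss <- if (is(x, "DocProfileIndex")) x@structures else x
    stopifnot(is(ss, "SuffixStructures"))
    eng <- .engineCore(ss)
    n <- eng$n
    if (is.null(interval)) interval <- c(1L, n)
    stopifnot(length(interval) == 2L, interval[1L] >= 1L,
              interval[1L] <= interval[2L], interval[2L] <= n)
    cls <- match(char, ss@concat@alphabet)
    .stepEng(eng, cls, interval)
}

# one backward step over prebuilt rank tables; empty interval = integer(0)
.stepEng <- function(eng, cls, interval) {
    if (is.na(cls) || eng$cnt[cls] == 0L) return(integer(0))
    pos <- eng$posC[[cls]]
    r1 <- findInterval(interval[1L] - 1L, pos)
    r2 <- findInterval(interval[2L], pos)
    s <- eng$Coff[cls] + r1 + 1L
    e <- eng$Coff[cls] + r2
    if (s > e) integer(0) else c(s, e)
}

# core query tables shared by backwardStep and the profile query engine
.engineCore <- function(ss) {
    chars <- .chars(ss@bwt)
    alphabet <- ss@concat@alphabet
    d <- length(ss@concat@labels)
    sigma <- length(alphabet)
    bwtcls <- match(chars, alphabet)
    bwtcls[is.na(bwtcls)] <- 0L
    textCls <- pmax(ss@codes - d, 0L)          # 0 = separator
    cnt <- tabulate(textCls, nbins = sigma)
    Coff <- d + c(0L, cumsum(cnt))[seq_len(sigma)]
    posC <- lapply(seq_len(sigma), function(c) which(bwtcls == c))
    list(n = ss@concat@n, d = d, sigma = sigma, bwtcls = as.integer(bwtcls),
         cnt = as.integer(cnt), Coff = as.integer(Coff), posC = posC)
}
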