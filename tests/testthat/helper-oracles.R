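# Fixture builders and independent brute-force oracles.  The oracles work
# on the integer-mapped text directly (distinct separator codes), so they
# realise the same separator semantics as the implementation while sharing
# none of its code paths.

randomCollection <- function(d = sample(1:6, 1), sigma = sample(c(2L, 4L), 1),
                             minLen = 3L, maxLen = 40L) {
    ab <- c("A", "C", "G", "T")[seq_len(sigma)]
    docs <- vapply(seq_len(d), function(i)
        paste0(sample(ab, sample(minLen:maxLen, 1), replace = TRUE),
               collapse = ""), character(1))
    DocumentCollection(docs)
}

# integer-mapped suffixes as vectors, for direct comparisons
suffixCodes <- function(ss, i) ss@codes[i:length(ss@codes)]

# brute-force suffix sort: map codes to an increasing character alphabet
# and sort the explicit suffix strings in C collation
bruteSuffixArray <- function(ss) {
    codes <- ss@codes
    stopifnot(max(codes) <= length(letters))  # byte order must follow codes
    mapped <- paste0(letters[codes], collapse = "")
    sufs <- substring(mapped, seq_len(nchar(mapped)), nchar(mapped))
    order(sufs, method = "radix")
}

bruteLcp <- function(a, b) {
    m <- min(length(a), length(b))
    if (m == 0L) return(0L)
    neq <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(neq)) neq[1L] - 1L else m
}

bruteLcpArray <- function(ss) {
    n <- length(ss@codes)
    out <- integer(n)
    for (i in 2:n)
        out[i] <- bruteLcp(suffixCodes(ss, ss@sa[i - 1L]),
                           suffixCodes(ss, ss@sa[i]))
    out
}

# defining maximum of the profile, re-implemented with explicit loops
bruteProfiles <- function(ss) {
    n <- length(ss@codes)
    d <- length(ss@concat@labels)
    P <- matrix(0L, n, d)
    for (i in seq_len(n)) {
        si <- suffixCodes(ss, ss@sa[i])
        for (k in seq_len(n)) {
            l <- bruteLcp(si, suffixCodes(ss, ss@sa[k]))
            j <- ss@da[k]
            if (l > P[i, j]) P[i, j] <- l
        }
    }
    P
}

docsContaining <- function(docs, pat)
    which(vapply(docs, function(x) grepl(pat, x, fixed = TRUE), logical(1)))

# all (overlapping) occurrences of pat in the concatenation; patterns are
# plain ACGTN/# so no regex escaping is needed for the lookahead
bruteOccurrences <- function(text, pat) {
    hits <- gregexpr(paste0("(?=", pat, ")"), text, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

bruteMatchingStats <- function(docs, read) {
    L <- nchar(read)
    out <- integer(L)
    for (p in seq_len(L)) {
        best <- 0L
        for (len in (L - p + 1L):1L) {
            pat <- substr(read, p, p + len - 1L)
            if (length(docsContaining(docs, pat))) { best <- len; break }
        }
        out[p] <- best
    }
    out
}

# distinct substrings of the documents up to a maximum length
allSubstrings <- function(docs, maxLen) {
    unique(unlist(lapply(docs, function(s) {
        n <- nchar(s)
        unlist(lapply(seq_len(min(maxLen, n)), function(L)
            substring(s, 1:(n - L + 1L), L:n)))
    })))
}

# LF computed independently via counts and rank over the distinct-code BWT
bruteLF <- function(ss) {
    n <- length(ss@codes)
    prev <- ifelse(ss@sa == 1L, n, ss@sa - 1L)
    bwtCodes <- ss@codes[prev]
    C <- vapply(bwtCodes, function(v) sum(ss@codes < v), integer(1))
    rk <- integer(n)
    seen <- integer(max(ss@codes))
    for (i in seq_len(n)) {
        v <- bwtCodes[i]
        seen[v] <- seen[v] + 1L
        rk[i] <- seen[v]
    }
    C + rk
}

smallIndex <- function(docs, ...) buildDocProfileIndex(
    DocumentCollection(docs), ...)
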