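#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so that library functions do not disturb
#' user-level reproducibility.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of \code{code}
#' @keywords internal
withSeed <- function(seed, code) {
    genv <- globalenv()
    old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
        get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(as.integer(seed))
    code
}

# Derived sub-stream seed: keeps all seeds inside 32-bit integer range.
deriveSeed <- function(seed, stage, index = 0L) {
    stages <- c(plan = 11L, schedule = 23L, events = 37L, traces = 53L,
                dummy = 71L, shuffle = 89L, misc = 97L)
    off <- stages[[stage]]
    as.integer((as.numeric(seed) + 9973 * off + 104729 * as.numeric(index)) %%
               2147483629)
}

# Largest-remainder apportionment of n into round(p * n) with sum n.
apportion <- function(p, n) {
    raw <- p * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

# Causal (trailing) boxcar smoother; leading partial windows use the
# available samples only, so no data are fabricated at the start.
causalBoxcar <- function(x, width) {
    width <- as.integer(width)
    if (width <= 1L) return(x)
    cs <- cumsum(x)
    n <- length(x)
    if (n <= width) return(cs / seq_len(n))
    out <- numeric(n)
    head_idx <- seq_len(width)
    out[head_idx] <- cs[head_idx] / head_idx
    idx <- (width + 1L):n
    out[idx] <- (cs[idx] - cs[idx - width]) / width
    out
}

# Pearson r plus two-sided parametric p for a matrix of traces (rows)
# against one reference series; vectorized across rows.
rowCorTest <- function(mat, ref) {
    n <- ncol(mat)
    refc <- ref - mean(ref)
    sref <- sqrt(sum(refc^2))
    mc <- mat - rowMeans(mat)
    sx <- sqrt(rowSums(mc^2))
    r <- as.numeric(mc %*% refc) / (sx * sref)
    r[!is.finite(r)] <- NA_real_
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    list(r = r, p = p)
}
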