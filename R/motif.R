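#' Fragment long transcript sequences into overlapping windows
#'
#' Each sequence of length `M` is split into windows of length `L` with step
#' `s`: starts `0, s, 2s, ...`, plus a final window anchored at `M - L` so
#' the last fragment is full length. Sequences no longer than `L` are
#' emitted whole. Fragment count is `1` if `M <= L`, otherwise
#' `ceiling((M - L)/s) + 1`, and every base is covered by at least one
#' fragment. Fragment ids are `parentid:start-end` with 0-based half-open
#' intervals.
#'
#' @param records named character vector of sequences.
#' @param L window length in nt (default 100).
#' @param s step in nt, `1 <= s <= L` (default 50, i.e. 50% overlap).
#' @return named character vector of fragments.
#' @export
fragment_sequences <- function(records, L = 100, s = 50) {
  stopifnot(L >= 1, s >= 1, s <= L, !is.null(names(records)))
  out <- character(0)
  for (id in names(records)) {
    seqc <- records[[id]]
    M <- nchar(seqc)
    if (M <= L) {
      starts <- 0L
      ends <- M
    } else {
      k <- ceiling((M - L) / s)
      starts <- unique(c(seq(0L, by = s, length.out = k), M - L))
      ends <- starts + L
    }
    frags <- substring(seqc, starts + 1, ends)
    names(frags) <- sprintf("%s:%d-%d", id, starts, ends)
    out <- c(out, frags)
  }
  out
}

#' Scan sequences with a PWM log-odds model
#'
#' Slides the PWM over each sequence (single strand; RNA has no reverse
#' complement) and scores every offset in bits:
#' \deqn{score(o) = \sum_j \log_2\!\left(
#'   \frac{(f_j(s_{o+j}) + c) / (1 + 4c)}{b}\right)}
#' with pseudocount `c` and scalar background `b`. `N` bases contribute 0
#' (scored as background). Offsets scoring at least the PWM threshold are
#' reported as hits. Sequences shorter than the motif yield no hits.
#'
#' @param records named character vector of sequences over `A, C, G, U`
#'   (`T` is accepted and treated as `U`; `N` allowed).
#' @param pwm a `pwm` object (see [make_pwm()], [read_pwm()]).
#' @param pseudocount non-negative pseudocount (default 1e-3).
#' @param threshold log-odds cutoff in bits; defaults to the PWM's own
#'   threshold (conventionally 6).
#' @return data frame with columns `seq_id`, `offset` (0-based), `end`
#'   (half-open), `score`.
#' @export
scan_pwm <- function(records, pwm, pseudocount = 1e-3,
                     threshold = pwm$threshold) {
  stopifnot(inherits(pwm, "pwm"), pseudocount >= 0)
  w <- pwm$width
  b <- pwm$background
  # per-position log-odds over A, C, G, U; row 5 = N scored as background (0)
  lods <- log2(((t(pwm$mat) + pseudocount) / (1 + 4 * pseudocount)) / b)
  lods <- rbind(lods, N = 0) # 5 x width; column-major lookup below
  hits_id <- character(0); hits_off <- integer(0); hits_score <- numeric(0)
  for (id in names(records)) {
    seqc <- chartr("T", "U", toupper(records[[id]]))
    M <- nchar(seqc)
    if (M < w) next
    code <- match(strsplit(seqc, "")[[1]], c("A", "C", "G", "U", "N"))
    if (anyNA(code)) {
      stop("scan_pwm: sequence '", id, "' contains characters outside ",
           "A/C/G/U/N")
    }
    n_off <- M - w + 1
    score <- numeric(n_off)
    for (j in seq_len(w)) {
      score <- score + lods[code[j:(j + n_off - 1)] + (j - 1) * 5]
    }
    keep <- which(score >= threshold)
    if (length(keep)) {
      hits_id <- c(hits_id, rep(id, length(keep)))
      hits_off <- c(hits_off, keep - 1L)
      hits_score <- c(hits_score, score[keep])
    }
  }
  data.frame(seq_id = hits_id, offset = hits_off, end = hits_off + w,
             score = hits_score, stringsAsFactors = FALSE)
}
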