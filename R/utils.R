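# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# byte -> base code lookup: A/C/G/T -> 0:3, N -> NA, anything else -> -1
.base_code <- local({
  lk <- rep(-1L, 256L)
  lk[utf8ToInt("A")] <- 0L
  lk[utf8ToInt("C")] <- 1L
  lk[utf8ToInt("G")] <- 2L
  lk[utf8ToInt("T")] <- 3L
  lk[utf8ToInt("N")] <- NA_integer_
  lk
})

# Encode a nucleotide string as integer codes (0:3, NA for N).
seq_to_int <- function(seq, what = "sequence") {
  x <- .base_code[utf8ToInt(seq)]
  bad <- which(!is.na(x) & x < 0L)
  if (length(bad)) {
    ch <- substr(seq, bad[1L], bad[1L])
    stop(sprintf("non-nucleotide character '%s' at position %d in %s",
                 ch, bad[1L], what), call. = FALSE)
  }
  x
}

int_to_seq <- function(x) {
  codes <- c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"), utf8ToInt("T"))
  y <- ifelse(is.na(x), utf8ToInt("N"), codes[x + 1L])
  intToUtf8(y)
}

# Run expr with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zgene_version <- function() {
  as.character(utils::packageVersion("zgene"))
}
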