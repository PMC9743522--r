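# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# sortable numeric rank for chromosome names: chr1 < chr2 < chr10 < chrX < chrY
chrom_rank <- function(chrom) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(base))
  special <- match(toupper(base), c("X", "Y", "M", "MT"))
  out <- ifelse(!is.na(num), num,
                ifelse(!is.na(special), 1000 + special, NA_real_))
  # fall back to alphabetical rank for arbitrary names (e.g. chr7s, chrB)
  if (anyNA(out)) {
    alpha <- as.numeric(factor(base, levels = sort(unique(base))))
    out[is.na(out)] <- 2000 + alpha[is.na(out)]
  }
  out
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

format_count <- function(x) {
  ifelse(is.finite(x) & x == floor(x), sprintf("%.0f", x), sprintf("%.10g", x))
}

as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    stats::setNames(as.numeric(x$length), as.character(x$chrom))
  } else {
    stopifnot(!is.null(names(x)), all(nzchar(names(x))))
    stats::setNames(as.numeric(x), names(x))
  }
}
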